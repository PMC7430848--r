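#' Build an exact-match word index over a reference sequence
#'
#' Indexes every k-length word (k-mer) of the forward strand of one
#' reference sequence, mapping each distinct word to the ascending list of
#' its 0-based start positions. Words containing N are never indexed.
#' Words occurring more than `occurrence_cap` times are masked: they stay in
#' the index but answer no positions, which bounds anchor collection on
#' repeats. Reverse-complement handling lives entirely in the mapper (the
#' reverse-complemented read is queried against this forward index).
#'
#' Internally words are packed into 2-bit integer codes (A=0, C=1, G=2,
#' T=3), so lookups never materialize per-word strings; this caps `k` at 15
#' (codes must fit a 31-bit integer), which covers the default k = 14.
#'
#' @param reference a length-1 `DNAStringSet`, a single `DNAString`, or a
#'   character scalar (optionally named with the reference id).
#' @param k word length in bases, 1--15 (default 14).
#' @param occurrence_cap mask words with more genome occurrences than this
#'   (default 512); `Inf` disables masking.
#' @return an object of class `word_index` with fields `k`, `ref_id`,
#'   `ref_length`, `occurrence_cap`.
#' @export
#' @examples
#' idx <- build_index(c(chr = "ACGTACGTAC"), k = 4)
#' locate_word(idx, "ACGT")
build_index <- function(reference, k = 14L, occurrence_cap = 512L) {
  seq1 <- extract_single_sequence(reference)
  bases <- seq1$bases
  n <- nchar(bases)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > 15L) stop("k must be <= 15 (2-bit packed words)", call. = FALSE)
  if (n < k) {
    stop(sprintf("reference '%s' (length %d) is shorter than k = %d",
                 seq1$id, n, k), call. = FALSE)
  }
  codes <- kmer_codes(bases, k)            # NA where the window contains N
  keep <- !is.na(codes)
  if (any(keep)) {
    by_code <- split(which(keep) - 1L, codes[keep])  # 0-based positions
    masked <- unname(lengths(by_code) > occurrence_cap)
    positions <- unname(by_code)
    positions[masked] <- list(integer(0))
    code_keys <- as.integer(names(by_code))
  } else {
    positions <- list()
    code_keys <- integer(0)
  }
  structure(
    list(k = k, ref_id = seq1$id, ref_length = n,
         occurrence_cap = occurrence_cap,
         codes = code_keys, positions = positions),
    class = "word_index"
  )
}

# internal: 2-bit rolling codes of every k-mer of `bases`; NA when a window
# holds a non-ACGT character. Vectorized: k shifted adds over a base-value
# vector, no per-word strings.
kmer_codes <- function(bases, k) {
  vals <- integer(128)
  vals[] <- NA_integer_
  vals[utf8ToInt("A")] <- 0L; vals[utf8ToInt("C")] <- 1L
  vals[utf8ToInt("G")] <- 2L; vals[utf8ToInt("T")] <- 3L
  b <- vals[utf8ToInt(bases)]
  n <- length(b)
  if (n < k) return(integer(0))
  m <- n - k + 1L
  codes <- numeric(m)            # accumulate in double, exact below 2^31
  for (j in seq_len(k)) {
    codes <- codes + b[j:(j + m - 1L)] * 4^(k - j)
  }
  as.integer(codes)
}

# internal: coerce the accepted reference representations to (id, bases)
extract_single_sequence <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) {
    if (length(reference) != 1L) {
      stop("expected a single reference sequence; use one index per sequence",
           call. = FALSE)
    }
    return(list(id = names(reference) %||% "ref", bases = as.character(reference[[1L]])))
  }
  if (methods::is(reference, "DNAString")) {
    return(list(id = "ref", bases = as.character(reference)))
  }
  stopifnot(is.character(reference), length(reference) == 1L)
  id <- names(reference) %||% "ref"
  list(id = unname(id), bases = toupper(unname(reference)))
}

#' @export
print.word_index <- function(x, ...) {
  cat(sprintf("word_index: ref '%s' (%d bp), k = %d, %d distinct words, cap = %s\n",
              x$ref_id, x$ref_length, x$k, length(x$codes),
              format(x$occurrence_cap)))
  invisible(x)
}

#' Locate all occurrences of a word on the forward reference strand
#'
#' @param index a `word_index` from [build_index()].
#' @param word character scalar of length `index$k`.
#' @return ascending integer vector of 0-based start positions; empty for
#'   absent, masked, or N-containing words.
#' @export
locate_word <- function(index, word) {
  stopifnot(inherits(index, "word_index"))
  if (nchar(word) != index$k) {
    stop(sprintf("query word has length %d, index k is %d", nchar(word), index$k),
         call. = FALSE)
  }
  code <- kmer_codes(toupper(word), index$k)
  if (length(code) != 1L || is.na(code)) return(integer(0))
  hit <- match(code, index$codes)
  if (is.na(hit)) integer(0) else index$positions[[hit]]
}

# internal: vectorized lookup used by the anchor locator. Takes integer
# word codes (NA allowed) and returns a list of position vectors.
locate_codes <- function(index, codes) {
  hits <- match(codes, index$codes)
  out <- vector("list", length(codes))
  found <- !is.na(hits)
  out[found] <- index$positions[hits[found]]
  out[!found] <- list(integer(0))
  out
}

#' Save a word index to disk
#'
#' Binary serialization (RDS) with a format sentinel checked on load.
#'
#' @param index a `word_index`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
save_index <- function(index, path) {
  saveRDS(index_payload(index), path)
  invisible(path)
}

# internal: serializable form of a word_index
index_payload <- function(index) {
  stopifnot(inherits(index, "word_index"))
  list(
    format = "bandmap_word_index", version = 2L,
    k = index$k, ref_id = index$ref_id, ref_length = index$ref_length,
    occurrence_cap = index$occurrence_cap,
    codes = index$codes,
    positions = index$positions
  )
}

#' Load a word index saved by [save_index()]
#'
#' @param path path to the serialized index.
#' @return a `word_index` answering every locate query identically to the
#'   saved object.
#' @export
load_index <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e) {
    stop(sprintf("cannot load index from %s: %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  if (!is.list(payload) || !identical(payload$format, "bandmap_word_index")) {
    stop(sprintf("%s is not a bandmap word index", path), call. = FALSE)
  }
  if (!identical(payload$version, 2L)) {
    stop(sprintf("unsupported index version: %s", format(payload$version)), call. = FALSE)
  }
  structure(
    list(k = payload$k, ref_id = payload$ref_id, ref_length = payload$ref_length,
         occurrence_cap = payload$occurrence_cap,
         codes = payload$codes, positions = payload$positions),
    class = "word_index"
  )
}
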