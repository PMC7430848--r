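#' Mapper configuration
#'
#' Aggregates the defaults of the whole pipeline: word length k = 14,
#' every-offset word sampling, credibility window L(r) = 0.2 read length,
#' band coefficient alpha = 0.1 (half-width `ceiling(0.1 l_r)`), scores
#' match/mismatch/gap = 2/-2/2, repeat-word cap 512.
#'
#' @param k word length.
#' @param word_step read-offset sampling step.
#' @param tolerance_coefficient credibility window coefficient.
#' @param alpha band width coefficient.
#' @param slope genome/read segment ratio and band slope.
#' @param match,mismatch,gap alignment scores.
#' @param occurrence_cap repetitive-word masking cap.
#' @param threads accepted for interface compatibility; the implementation
#'   is single-threaded and `threads` never changes output content.
#' @return a list of class `mapper_config`.
#' @export
mapper_config <- function(k = 14L, word_step = 1L, tolerance_coefficient = 0.2,
                          alpha = 0.1, slope = 1.2, match = 2L, mismatch = -2L,
                          gap = 2L, occurrence_cap = 512L, threads = 1L) {
  stopifnot(k >= 1L, threads >= 1L)
  structure(list(
    k = as.integer(k), word_step = as.integer(word_step),
    tolerance_coefficient = tolerance_coefficient, alpha = alpha, slope = slope,
    match = as.integer(match), mismatch = as.integer(mismatch),
    gap = as.integer(gap), occurrence_cap = occurrence_cap,
    threads = as.integer(threads)
  ), class = "mapper_config")
}

#' Build one word index per reference sequence
#'
#' Anchoring and alignment never cross sequence boundaries; multi-sequence
#' references get one index each.
#'
#' @param references named `DNAStringSet` or named character vector.
#' @param config a [mapper_config()].
#' @return named list of `word_index` objects (references shorter than k are
#'   skipped with a warning).
#' @export
build_indexes <- function(references, config = mapper_config()) {
  if (is.character(references)) references <- Biostrings::DNAStringSet(references)
  if (is.null(names(references))) {
    stop("reference sequences must be named", call. = FALSE)
  }
  out <- list()
  for (i in seq_along(references)) {
    if (Biostrings::width(references)[i] < config$k) {
      warning(sprintf("reference '%s' shorter than k = %d; skipped",
                      names(references)[i], config$k), call. = FALSE)
      next
    }
    out[[names(references)[i]]] <-
      build_index(stats::setNames(as.character(references[[i]]), names(references)[i]),
                  k = config$k, occurrence_cap = config$occurrence_cap)
  }
  out
}

#' Map one read
#'
#' Anchors are scored on the forward read and its reverse complement against
#' every reference index; the strand/reference with the largest winning
#' credibility is aligned (ties prefer the forward strand, then the first
#' reference). The read is split at the anchor and both segment pairs are
#' aligned on low-column matrices with band half-width
#' `ceiling(alpha * read length)`, then combined into one end-to-end record.
#' Reads shorter than k, or without any indexed word match, are returned
#' unmapped (never an error).
#'
#' @param read character scalar, or a length-1 named `DNAStringSet`.
#' @param index a `word_index` or list of them (one per reference sequence).
#' @param reference the reference sequences the indexes were built from
#'   (named `DNAStringSet` or named character vector).
#' @param config a [mapper_config()].
#' @param read_id id used when `read` is an unnamed character scalar.
#' @return a one-row [mapping_records] table, with the aligned-orientation
#'   read sequence in `attr(, "seq")`.
#' @export
map_read <- function(read, index, reference, config = mapper_config(),
                     read_id = "read") {
  if (!is.character(read)) {
    read_id <- names(read) %||% read_id
    read <- as.character(read[[1L]])
  } else if (!is.null(names(read))) {
    read_id <- names(read)
    read <- unname(read)
  }
  read <- toupper(read)
  if (inherits(index, "word_index")) index <- stats::setNames(list(index), index$ref_id)
  if (is.character(reference)) reference <- Biostrings::DNAStringSet(reference)

  lconf <- locator_config(config$word_step, config$tolerance_coefficient)
  fwd <- read
  rc <- revcomp(read)

  best <- NULL
  for (ref_id in names(index)) {
    for (strand in c("+", "-")) {
      a <- anchor_read(if (strand == "+") fwd else rc, index[[ref_id]], lconf)
      if (is.null(a)) next
      if (is.null(best) || a$credibility > best$anchor$credibility) {
        best <- list(anchor = a, strand = strand, ref_id = ref_id)
      }
    }
  }

  lr <- nchar(read)
  if (is.null(best)) {
    rec <- mapping_records(read_id, FALSE, NA_character_, "+", NA_integer_,
                           "*", 0L, lr)
    attr(rec, "seq") <- stats::setNames(read, read_id)
    return(rec)
  }

  aligned <- if (best$strand == "+") fwd else rc   # genome-forward orientation
  ref_seq <- as.character(reference[[best$ref_id]])
  glen <- nchar(ref_seq)
  split <- split_segments(lr, best$anchor, glen, slope = config$slope)
  b <- max(1L, as.integer(ceiling(config$alpha * lr)))
  params <- band_params(match = config$match, mismatch = config$mismatch,
                        gap = config$gap, alpha = config$alpha,
                        slope = config$slope, b = b)

  r_u <- substring(aligned, split$r_u[1L] + 1L, split$r_u[2L])
  r_d <- substring(aligned, split$r_d[1L] + 1L, split$r_d[2L])
  g_u <- substring(ref_seq, split$g_u[1L] + 1L, split$g_u[2L])
  g_d <- substring(ref_seq, split$g_d[1L] + 1L, split$g_d[2L])

  up <- align_banded_low_column(str_reverse(r_u), str_reverse(g_u), params)
  down <- align_banded_low_column(r_d, g_d, params)
  frag <- combine_alignments(up, down, split, best$anchor)

  rec <- mapping_records(read_id, TRUE, best$ref_id, best$strand,
                         frag$ref_start, frag$cigar, frag$score, lr,
                         credibility = best$anchor$credibility)
  attr(rec, "seq") <- stats::setNames(aligned, read_id)
  rec
}

# internal: reverse a string (not complement)
str_reverse <- function(x) {
  if (nchar(x) <= 1L) return(x)
  paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Map a set of reads held in memory
#'
#' @param reads named `DNAStringSet` or named character vector.
#' @param references named `DNAStringSet` or named character vector.
#' @param config a [mapper_config()].
#' @param indexes optional prebuilt [build_indexes()] result (rebuilt when
#'   `NULL`).
#' @param quiet suppress per-1000-read progress on standard error.
#' @return a [mapping_records] table in input read order, with SAM-orientation
#'   read sequences in `attr(, "seqs")`.
#' @export
map_reads <- function(reads, references, config = mapper_config(),
                      indexes = NULL, quiet = TRUE) {
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  if (is.character(references)) references <- Biostrings::DNAStringSet(references)
  if (is.null(indexes)) indexes <- build_indexes(references, config)
  if (length(reads) == 0L) {
    out <- mapping_records(character(0), logical(0), character(0), character(0),
                           integer(0), character(0), integer(0), integer(0))
    attr(out, "seqs") <- stats::setNames(character(0), character(0))
    return(out)
  }
  rows <- vector("list", length(reads))
  seqs <- character(length(reads))
  ids <- names(reads) %||% paste0("read", seq_along(reads))
  for (i in seq_along(reads)) {
    rec <- map_read(as.character(reads[[i]]), indexes, references, config,
                    read_id = ids[i])
    seqs[i] <- attr(rec, "seq")
    attr(rec, "seq") <- NULL
    rows[[i]] <- rec
    if (!quiet && i %% 1000L == 0L) {
      message(sprintf("mapped %d/%d reads", i, length(reads)))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("mapping_records", "data.frame")
  attr(out, "seqs") <- stats::setNames(seqs, ids)
  out
}

#' Map a reads file against a reference file and write SAM
#'
#' Orchestrates the whole pipeline: read inputs, build one index per
#' reference sequence, map every read (one best record each, unmapped reads
#' flagged 0x4), and write a SAM file in input read order. Deterministic for
#' fixed inputs and configuration; `threads` never affects content.
#'
#' @param reads_path FASTA or FASTQ file of reads.
#' @param ref_path FASTA file of reference sequences.
#' @param config a [mapper_config()].
#' @param out_sam_path output SAM path.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with `n_reads`, `n_mapped`, `n_unmapped` and the
#'   `records` table.
#' @export
map_all <- function(reads_path, ref_path, config = mapper_config(),
                    out_sam_path, quiet = FALSE) {
  reads <- read_sequences(reads_path)
  references <- read_sequences(ref_path, format = "fasta")
  records <- map_reads(reads, references, config, quiet = quiet)
  write_sam(records, references, out_sam_path, seqs = attr(records, "seqs"))
  summary <- list(n_reads = nrow(records),
                  n_mapped = sum(records$mapped),
                  n_unmapped = sum(!records$mapped),
                  records = records)
  if (!quiet) {
    message(sprintf("%d reads: %d mapped, %d unmapped -> %s",
                    summary$n_reads, summary$n_mapped, summary$n_unmapped,
                    out_sam_path))
  }
  invisible(summary)
}
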