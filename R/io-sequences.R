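#' Read sequences from FASTA or FASTQ
#'
#' Returns the records in file order as a [Biostrings::DNAStringSet] with
#' record ids as names. Lowercase bases are uppercased; any character outside
#' `{A,C,G,T,N}` is rejected with an error naming the offending line. For
#' FASTQ input, per-base Phred quality scores (Sanger encoding) are attached
#' as a character vector in `mcols(x)$quality`.
#'
#' @param path path to an existing FASTA or FASTQ file.
#' @param format `"auto"` (sniff from the first non-empty character: `>` for
#'   FASTA, `@` for FASTQ), `"fasta"`, or `"fastq"`.
#' @return a named `DNAStringSet`; empty input yields a zero-length set.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">r1", "acgt", ">r2", "GGTTAA"), fa)
#' as.character(read_sequences(fa))
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    first <- ""
    con <- file(path, "r"); on.exit(close(con), add = TRUE)
    repeat {
      ln <- readLines(con, n = 1L)
      if (length(ln) == 0L) break
      if (nzchar(trimws(ln))) { first <- substr(trimws(ln), 1L, 1L); break }
    }
    if (first == "") {
      return(Biostrings::DNAStringSet())
    }
    format <- switch(first, ">" = "fasta", "@" = "fastq",
      stop(sprintf("%s: cannot determine format from leading character '%s'", path, first),
           call. = FALSE))
  }
  if (format == "fasta") read_fasta_checked(path) else read_fastq_checked(path)
}

# FASTA via Biostrings, then alphabet validation (Biostrings silently accepts
# IUPAC ambiguity codes; the mapper's alphabet is A/C/G/T/N only).
read_fasta_checked <- function(path) {
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop(sprintf("%s: FASTA parse error: %s", path, conditionMessage(e)),
                             call. = FALSE)
  )
  if (length(x) == 0L) return(x)
  if (any(is.na(names(x))) || any(!nzchar(names(x)))) {
    stop(sprintf("%s: FASTA record with empty id", path), call. = FALSE)
  }
  names(x) <- sub("\\s.*$", "", names(x))  # id = first whitespace-delimited token
  freq <- Biostrings::alphabetFrequency(x)
  extra <- rowSums(freq) - rowSums(freq[, c("A", "C", "G", "T", "N"), drop = FALSE])
  if (any(extra > 0L)) {
    bad_line <- find_bad_line(path)
    stop(sprintf("%s: line %d: character outside {A,C,G,T,N}", path, bad_line), call. = FALSE)
  }
  x
}

# locate the first sequence line holding a disallowed character, for diagnostics
find_bad_line <- function(path) {
  lines <- readLines(path)
  seq_lines <- !startsWith(lines, ">") & !startsWith(lines, "@") & !startsWith(lines, "+")
  bad <- seq_lines & grepl("[^ACGTNacgtn[:space:]]", lines)
  if (any(bad)) which(bad)[1L] else NA_integer_
}

# Validating 4-line-per-record FASTQ reader. Biostrings' quality-aware FASTQ
# reader does not check that quality length matches sequence length (it can
# return corrupt objects), and this reader must name line numbers on error.
read_fastq_checked <- function(path) {
  lines <- readLines(path)
  while (length(lines) && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0L) return(Biostrings::DNAStringSet())
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("%s: truncated FASTQ record at line %d", path,
                 4L * (length(lines) %/% 4L) + 1L), call. = FALSE)
  }
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- toupper(lines[seq(2L, by = 4L, length.out = n)])
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  for (i in seq_len(n)) {
    ln <- 4L * (i - 1L)
    if (!startsWith(hdr[i], "@") || nchar(hdr[i]) < 2L) {
      stop(sprintf("%s: line %d: expected '@<id>' header", path, ln + 1L), call. = FALSE)
    }
    if (grepl("[^ACGTN]", seqs[i])) {
      stop(sprintf("%s: line %d: character outside {A,C,G,T,N}", path, ln + 2L), call. = FALSE)
    }
    if (!startsWith(plus[i], "+")) {
      stop(sprintf("%s: line %d: expected '+' separator", path, ln + 3L), call. = FALSE)
    }
    if (nchar(qual[i]) != nchar(seqs[i])) {
      stop(sprintf("%s: line %d: quality length %d != sequence length %d", path,
                   ln + 4L, nchar(qual[i]), nchar(seqs[i])), call. = FALSE)
    }
  }
  ids <- sub("\\s.*$", "", substring(hdr, 2L))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  S4Vectors::mcols(x)$quality <- qual
  x
}

#' Write sequences as FASTA
#'
#' @param x named `DNAStringSet` or named character vector.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, filepath = path, format = "fasta")
  invisible(path)
}

#' Write sequences as FASTQ
#'
#' Uses qualities from `mcols(x)$quality` when present, otherwise a constant
#' `"I"` (Phred 40) per base.
#'
#' @inheritParams write_fasta
#' @return invisibly, `path`.
#' @export
write_fastq <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  seqs <- as.character(x)
  qual <- S4Vectors::mcols(x)$quality
  if (is.null(qual)) qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  out <- character(4L * length(seqs))
  out[seq(1L, by = 4L, length.out = length(seqs))] <- paste0("@", names(x))
  out[seq(2L, by = 4L, length.out = length(seqs))] <- seqs
  out[seq(3L, by = 4L, length.out = length(seqs))] <- "+"
  out[seq(4L, by = 4L, length.out = length(seqs))] <- qual
  writeLines(out, path)
  invisible(path)
}
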