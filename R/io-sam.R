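#' Construct a table of mapping records
#'
#' One row per read. `cigar` uses ops over `{M, I, D, S}`; soft clips (S)
#' appear only where a genome boundary truncated a segment. For mapped rows
#' the CIGAR must consume exactly `read_length` bases on the read side
#' (M + I + S) and `ref_start` plus the reference span must stay inside the
#' reference. Coordinates are 0-based half-open; `write_sam()` shifts to
#' 1-based POS.
#'
#' @param read_id,ref_id character vectors.
#' @param mapped logical vector.
#' @param strand `"+"` or `"-"` per row.
#' @param ref_start integer, 0-based leftmost reference coordinate.
#' @param cigar character CIGAR strings (`"*"` for unmapped rows).
#' @param score integer alignment scores.
#' @param read_length integer read lengths.
#' @param credibility optional integer anchor credibility per read.
#' @return a `data.frame` of class `mapping_records`.
#' @export
mapping_records <- function(read_id, mapped, ref_id, strand, ref_start, cigar,
                            score, read_length, credibility = NA_integer_) {
  if (length(credibility) == 1L && length(read_id) != 1L) {
    credibility <- rep(credibility, length(read_id))
  }
  df <- data.frame(
    read_id = as.character(read_id),
    mapped = as.logical(mapped),
    ref_id = as.character(ref_id),
    strand = as.character(strand),
    ref_start = as.integer(ref_start),
    cigar = as.character(cigar),
    score = as.integer(score),
    read_length = as.integer(read_length),
    credibility = as.integer(credibility),
    stringsAsFactors = FALSE
  )
  class(df) <- c("mapping_records", "data.frame")
  df
}

# internal: stop unless every mapped record satisfies CIGAR conservation
validate_mapping_records <- function(records, ref_lengths = NULL) {
  for (i in which(records$mapped)) {
    sp <- cigar_spans(records$cigar[i])
    if (sp$read != records$read_length[i]) {
      stop(sprintf("record '%s': CIGAR consumes %d read bases, read length is %d",
                   records$read_id[i], sp$read, records$read_length[i]), call. = FALSE)
    }
    if (records$ref_start[i] < 0L) {
      stop(sprintf("record '%s': negative ref_start", records$read_id[i]), call. = FALSE)
    }
    if (!is.null(ref_lengths)) {
      rl <- ref_lengths[[records$ref_id[i]]]
      if (is.null(rl)) {
        stop(sprintf("record '%s': unknown reference '%s'", records$read_id[i],
                     records$ref_id[i]), call. = FALSE)
      }
      if (records$ref_start[i] + sp$ref > rl) {
        stop(sprintf("record '%s': alignment ends at %d beyond reference length %d",
                     records$read_id[i], records$ref_start[i] + sp$ref, rl), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Write mapping records as SAM
#'
#' Emits a SAM v1.6 file with `@HD` and one `@SQ` line per reference.
#' POS is `ref_start + 1` (SAM is 1-based). Reverse-strand records set flag
#' 0x10 and store the read reverse-complemented (reference orientation);
#' the mapper already produces SEQ in that orientation. Unmapped records set
#' flag 0x4 with POS 0 and CIGAR `*`. The alignment score is written as the
#' `AS:i:` tag, anchor credibility (when present) as `XC:i:`, and MAPQ is 255
#' (unavailable).
#'
#' @param records a [mapping_records] table.
#' @param references named `DNAStringSet` (or named character vector) of
#'   reference sequences.
#' @param path output path.
#' @param seqs optional named character vector of read sequences in SAM
#'   orientation (reference-forward); `*` is written when absent.
#' @return invisibly, `path`.
#' @export
write_sam <- function(records, references, path, seqs = NULL) {
  if (is.character(references)) references <- Biostrings::DNAStringSet(references)
  ref_lengths <- as.list(stats::setNames(Biostrings::width(references), names(references)))
  validate_mapping_records(records, ref_lengths)
  hdr <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(references), Biostrings::width(references)),
    "@PG\tID:bandmap\tPN:bandmap"
  )
  n <- nrow(records)
  lines <- character(n)
  for (i in seq_len(n)) {
    seq_i <- if (!is.null(seqs)) seqs[[records$read_id[i]]] %||% "*" else "*"
    tags <- sprintf("AS:i:%d", records$score[i])
    if (!is.na(records$credibility[i])) {
      tags <- paste(tags, sprintf("XC:i:%d", records$credibility[i]), sep = "\t")
    }
    if (records$mapped[i]) {
      flag <- if (records$strand[i] == "-") 16L else 0L
      lines[i] <- paste(records$read_id[i], flag, records$ref_id[i],
                        records$ref_start[i] + 1L, 255L, records$cigar[i],
                        "*", 0L, 0L, seq_i, "*", tags, sep = "\t")
    } else {
      lines[i] <- paste(records$read_id[i], 4L, "*", 0L, 0L, "*",
                        "*", 0L, 0L, seq_i, "*", tags, sep = "\t")
    }
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a SAM file into mapping records
#'
#' Parses header-declared references and primary alignment lines back into a
#' [mapping_records] table (secondary/supplementary records, flags 0x100 and
#' 0x800, are skipped). `read_length` is recovered from the CIGAR, falling
#' back to SEQ length for unmapped rows.
#'
#' @param path SAM file path.
#' @return list with elements `records` ([mapping_records]) and `ref_lengths`
#'   (named integer vector from `@SQ` lines).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  sq <- hdr[startsWith(hdr, "@SQ")]
  ref_lengths <- integer(0)
  if (length(sq)) {
    fields_of <- function(line, tag) {
      f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
      sub(paste0("^", tag, ":"), "", grep(paste0("^", tag, ":"), f, value = TRUE)[1L])
    }
    sn <- vapply(sq, fields_of, "", tag = "SN", USE.NAMES = FALSE)
    ln <- as.integer(vapply(sq, fields_of, "", tag = "LN", USE.NAMES = FALSE))
    ref_lengths <- stats::setNames(ln, sn)
  }
  if (length(body) == 0L) {
    return(list(records = mapping_records(character(0), logical(0), character(0),
                                          character(0), integer(0), character(0),
                                          integer(0), integer(0)),
                ref_lengths = ref_lengths))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  parse_tag <- function(fl, tag) {
    hit <- grep(paste0("^", tag, ":i:"), fl[-(1:11)], value = TRUE)
    if (length(hit)) as.integer(sub(paste0("^", tag, ":i:"), "", hit[1L])) else NA_integer_
  }
  rows <- lapply(fields, function(fl) {
    if (length(fl) < 11L) stop("malformed SAM line (fewer than 11 fields)", call. = FALSE)
    flag <- as.integer(fl[2L])
    if (bitwAnd(flag, 0x100L) != 0L || bitwAnd(flag, 0x800L) != 0L) return(NULL)
    mapped <- bitwAnd(flag, 0x4L) == 0L
    cig <- fl[6L]
    rl <- if (cig != "*") cigar_spans(cig)$read else nchar(fl[10L]) * (fl[10L] != "*")
    list(read_id = fl[1L], mapped = mapped,
         ref_id = if (mapped) fl[3L] else NA_character_,
         strand = if (bitwAnd(flag, 0x10L) != 0L) "-" else "+",
         ref_start = if (mapped) as.integer(fl[4L]) - 1L else NA_integer_,
         cigar = cig, score = parse_tag(fl, "AS"), read_length = as.integer(rl),
         credibility = parse_tag(fl, "XC"))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  rec <- mapping_records(
    read_id = vapply(rows, `[[`, character(1), "read_id"),
    mapped = vapply(rows, `[[`, logical(1), "mapped"),
    ref_id = vapply(rows, `[[`, character(1), "ref_id"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    ref_start = vapply(rows, `[[`, integer(1), "ref_start"),
    cigar = vapply(rows, `[[`, character(1), "cigar"),
    score = vapply(rows, `[[`, integer(1), "score"),
    read_length = vapply(rows, `[[`, integer(1), "read_length"),
    credibility = vapply(rows, `[[`, integer(1), "credibility")
  )
  list(records = rec, ref_lengths = ref_lengths)
}
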