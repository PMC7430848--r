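#' Construct a table of truth records
#'
#' One row per simulated read, describing where the read's template lies on
#' the reference and how the read was derived from it. `ref_start`/`ref_end`
#' are 0-based half-open coordinates of the template on the forward strand,
#' for both `+` and `-` reads.
#'
#' The `edit_script` walks the template left-to-right (genome-forward) and
#' consumes the read in the same orientation; for `-` reads that orientation
#' is the reverse complement of the stored read. Tokens:
#' \describe{
#'   \item{`<n>M`}{run of `n` bases copied from the template}
#'   \item{`X<base>`}{one template base replaced by `<base>` in the read}
#'   \item{`I<base>`}{one read base `<base>` not present in the template}
#'   \item{`<n>D`}{run of `n` template bases absent from the read}
#' }
#' Substitutions and insertions carry the base so that applying the script to
#' the template reproduces the read exactly.
#'
#' @param read_id,ref_id character vectors.
#' @param read_length integer, total read length (bases the script consumes
#'   on the read side).
#' @param strand `"+"` or `"-"`.
#' @param ref_start,ref_end integer, 0-based half-open template interval.
#' @param edit_script character edit scripts (see above).
#' @return a `data.frame` of class `truth_records`.
#' @export
truth_records <- function(read_id, read_length, ref_id, strand, ref_start, ref_end,
                          edit_script) {
  df <- data.frame(
    read_id = as.character(read_id),
    read_length = as.integer(read_length),
    ref_id = as.character(ref_id),
    strand = as.character(strand),
    ref_start = as.integer(ref_start),
    ref_end = as.integer(ref_end),
    edit_script = as.character(edit_script),
    stringsAsFactors = FALSE
  )
  class(df) <- c("truth_records", "data.frame")
  validate_truth_records(df)
  df
}

# internal: tokenize an edit script
parse_edit_script <- function(s) {
  m <- gregexpr("(\\d+[MD])|([XI][ACGTN])", s, perl = TRUE)[[1L]]
  if (nchar(s) > 0L && (m[1L] == -1L || sum(attr(m, "match.length")) != nchar(s))) {
    stop(sprintf("malformed edit script: '%s'", s), call. = FALSE)
  }
  tok <- if (nchar(s) == 0L) character(0) else regmatches(s, list(m))[[1L]]
  counted <- grepl("^[0-9]", tok)
  op <- ifelse(counted, substring(tok, nchar(tok)), substring(tok, 1L, 1L))
  len <- rep(1L, length(tok))
  len[counted] <- as.integer(sub("[MD]$", "", tok[counted]))
  base <- ifelse(counted, NA_character_, substring(tok, 2L))
  data.frame(op = op, length = len, base = base, stringsAsFactors = FALSE)
}

# internal: (read, ref) bases consumed by an edit script
edit_script_spans <- function(s) {
  ops <- parse_edit_script(s)
  list(
    read = sum(ops$length[ops$op %in% c("M", "X", "I")]),
    ref = sum(ops$length[ops$op %in% c("M", "X", "D")])
  )
}

# internal: enforce the conservation invariants of truth records
validate_truth_records <- function(truths) {
  for (i in seq_len(nrow(truths))) {
    if (truths$ref_start[i] >= truths$ref_end[i]) {
      stop(sprintf("truth '%s': ref_start must be < ref_end", truths$read_id[i]),
           call. = FALSE)
    }
    sp <- edit_script_spans(truths$edit_script[i])
    if (sp$read != truths$read_length[i]) {
      stop(sprintf("truth '%s': edit script consumes %d read bases, read length is %d",
                   truths$read_id[i], sp$read, truths$read_length[i]), call. = FALSE)
    }
    span <- truths$ref_end[i] - truths$ref_start[i]
    if (sp$ref != span) {
      stop(sprintf("truth '%s': edit script consumes %d reference bases, interval spans %d",
                   truths$read_id[i], sp$ref, span), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Apply a truth edit script to its template
#'
#' Reconstructs the read from the reference template. The result is in the
#' genome-forward orientation; pass `strand = "-"` to obtain the stored
#' (sequenced) read.
#'
#' @param edit_script edit script string (see [truth_records]).
#' @param template character scalar, the reference bases
#'   `ref[ref_start:ref_end)`.
#' @param strand `"+"` or `"-"`.
#' @return character scalar, the read.
#' @export
apply_edit_script <- function(edit_script, template, strand = "+") {
  ops <- parse_edit_script(edit_script)
  tpl <- strsplit(template, "", fixed = TRUE)[[1L]]
  out <- character(0)
  g <- 0L
  for (j in seq_len(nrow(ops))) {
    len <- ops$length[j]
    switch(ops$op[j],
      M = { out <- c(out, tpl[(g + 1L):(g + len)]); g <- g + len },
      X = { out <- c(out, ops$base[j]); g <- g + 1L },
      I = { out <- c(out, ops$base[j]) },
      D = { g <- g + len }
    )
  }
  if (g != length(tpl)) {
    stop("edit script does not consume the whole template", call. = FALSE)
  }
  read <- paste(out, collapse = "")
  if (strand == "-") revcomp(read) else read
}

# internal: per-read-base truth reference coordinate (genome-forward read
# orientation); NA for inserted bases.
truth_base_coords <- function(edit_script, ref_start) {
  ops <- parse_edit_script(edit_script)
  reads <- ops$op %in% c("M", "X", "I")
  n_read <- sum(ops$length[reads])
  out <- rep(NA_integer_, n_read)
  r <- 0L; g <- ref_start
  for (j in seq_len(nrow(ops))) {
    len <- ops$length[j]
    switch(ops$op[j],
      M = { out[(r + 1L):(r + len)] <- g:(g + len - 1L); r <- r + len; g <- g + len },
      X = { out[r + 1L] <- g; r <- r + 1L; g <- g + 1L },
      I = { r <- r + 1L },
      D = { g <- g + len }
    )
  }
  out
}

#' Write truth records as a TSV sidecar
#'
#' Tab-separated, one record per line, with a header row. Columns follow a
#' PAF-like order: `read_id`, `read_length`, `ref_id`, `strand`, `ref_start`,
#' `ref_end`, `edit_script`.
#'
#' @param truths a [truth_records] table.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_truth <- function(truths, path) {
  validate_truth_records(truths)
  utils::write.table(truths, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a truth TSV sidecar
#'
#' @param path path written by [write_truth()].
#' @return a [truth_records] table; conservation invariants are re-validated
#'   on load (a script that does not consume the stated read length or
#'   reference interval is a parse error).
#' @export
read_truth <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "character", "character",
                                         "integer", "integer", "character"))
  truth_records(df$read_id, df$read_length, df$ref_id, df$strand,
                df$ref_start, df$ref_end, df$edit_script)
}
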