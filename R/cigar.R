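#' Parse a CIGAR string into ops
#'
#' @param cigar character scalar like `"10M2I3D5M"`, or `"*"`.
#' @return data.frame with integer `length` and character `op` columns,
#'   zero rows for `"*"` or the empty string.
#' @export
cigar_parse <- function(cigar) {
  stopifnot(is.character(cigar), length(cigar) == 1L)
  if (is.na(cigar) || cigar == "*" || cigar == "") {
    return(data.frame(length = integer(0), op = character(0), stringsAsFactors = FALSE))
  }
  m <- gregexpr("(\\d+)([MIDSH=X])", cigar, perl = TRUE)[[1L]]
  if (m[1L] == -1L || sum(attr(m, "match.length")) != nchar(cigar)) {
    stop(sprintf("malformed CIGAR string: '%s'", cigar), call. = FALSE)
  }
  tok <- regmatches(cigar, list(m))[[1L]]
  data.frame(
    length = as.integer(sub("[MIDSH=X]$", "", tok)),
    op = sub("^\\d+", "", tok),
    stringsAsFactors = FALSE
  )
}

#' Format ops into a CIGAR string
#'
#' Adjacent runs of the same op are merged; zero-length runs are dropped.
#'
#' @param lengths integer vector of run lengths.
#' @param ops character vector of op codes, same length as `lengths`.
#' @return character scalar; `"*"` when no ops remain.
#' @export
cigar_string <- function(lengths, ops) {
  stopifnot(length(lengths) == length(ops))
  keep <- lengths > 0L
  lengths <- lengths[keep]; ops <- ops[keep]
  if (length(ops) == 0L) return("*")
  # merge adjacent equal ops
  grp <- cumsum(c(TRUE, ops[-1L] != ops[-length(ops)]))
  lengths <- as.integer(tapply(lengths, grp, sum))
  ops <- ops[!duplicated(grp)]
  paste0(lengths, ops, collapse = "")
}

# internal: bases consumed on the read and on the reference by a CIGAR
cigar_spans <- function(cigar) {
  ops <- cigar_parse(cigar)
  list(
    read = sum(ops$length[ops$op %in% c("M", "I", "S", "=", "X")]),
    ref = sum(ops$length[ops$op %in% c("M", "D", "=", "X")])
  )
}

# internal: per-read-base reference coordinate implied by a CIGAR walk.
# Returns an integer vector of length (read bases consumed); NA for bases in
# I or S ops. `ref_start` is 0-based; read base i (0-based, in the stored /
# genome-forward orientation) maps to entry i + 1.
cigar_base_coords <- function(cigar, ref_start) {
  ops <- cigar_parse(cigar)
  n_read <- sum(ops$length[ops$op %in% c("M", "I", "S")])
  out <- rep(NA_integer_, n_read)
  r <- 0L          # read bases consumed
  g <- ref_start   # next reference coordinate
  for (j in seq_len(nrow(ops))) {
    len <- ops$length[j]
    switch(ops$op[j],
      M = { out[(r + 1L):(r + len)] <- g:(g + len - 1L); r <- r + len; g <- g + len },
      I = ,
      S = { r <- r + len },
      D = { g <- g + len },
      stop(sprintf("unsupported CIGAR op '%s'", ops$op[j]), call. = FALSE)
    )
  }
  out
}

# internal: is each read base inside an M op? logical vector over read bases.
cigar_matched_mask <- function(cigar) {
  ops <- cigar_parse(cigar)
  reps <- ops$length[ops$op %in% c("M", "I", "S")]
  vals <- ops$op[ops$op %in% c("M", "I", "S")] == "M"
  rep(vals, reps)
}
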