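#' Evaluation configuration
#'
#' @param p_coeff a read is correctly aligned when its reference interval
#'   overlaps the truth interval by at least `p = p_coeff * read length`
#'   (default 0.9).
#' @param base_tolerance a matched base is correct when its reference
#'   coordinate lies within `T` bases of its truth coordinate, inclusive
#'   (default 5).
#' @param cover_fraction alignment x covers alignment y when their
#'   reference-interval overlap is at least this fraction of y's interval
#'   (default 0.9, boundary inclusive).
#' @return a list of class `eval_config`.
#' @export
eval_config <- function(p_coeff = 0.9, base_tolerance = 5L, cover_fraction = 0.9) {
  stopifnot(p_coeff > 0, p_coeff <= 1, base_tolerance >= 0,
            cover_fraction > 0, cover_fraction <= 1)
  structure(list(p_coeff = p_coeff, base_tolerance = as.integer(base_tolerance),
                 cover_fraction = cover_fraction),
            class = "eval_config")
}

# internal: 0-based half-open reference interval of a mapped record
record_interval <- function(record) {
  sp <- cigar_spans(record$cigar)
  c(record$ref_start, record$ref_start + sp$ref)
}

#' Is a read correctly aligned?
#'
#' True iff the record is mapped to the truth's reference and strand and the
#' overlap between its reference interval and the truth interval is at least
#' `p = p_coeff * read_length`.
#'
#' @param record one-row [mapping_records] slice (or equivalent list).
#' @param truth one-row [truth_records] slice for the same read.
#' @param config an [eval_config()].
#' @return logical scalar.
#' @export
classify_correct_read <- function(record, truth, config = eval_config()) {
  if (!isTRUE(record$mapped)) return(FALSE)
  if (record$ref_id != truth$ref_id || record$strand != truth$strand) return(FALSE)
  iv <- record_interval(record)
  overlap <- min(iv[2L], truth$ref_end) - max(iv[1L], truth$ref_start)
  overlap >= config$p_coeff * record$read_length
}

#' Count matched and correctly-matched bases of one record
#'
#' A matched base is a read base inside an M CIGAR op (mismatching M bases
#' included). It is correct when its reference coordinate, from the CIGAR
#' walk, lies within `base_tolerance` of the truth coordinate of the same
#' read base from the truth edit script; truth-inserted read bases are never
#' correct. Both walks are in the genome-forward read orientation, so the
#' comparison is strand-consistent.
#'
#' @inheritParams classify_correct_read
#' @return integer vector `c(matched, correct)`.
#' @export
count_correct_bases <- function(record, truth, config = eval_config()) {
  if (!isTRUE(record$mapped)) return(c(matched = 0L, correct = 0L))
  rec_coords <- cigar_base_coords(record$cigar, record$ref_start)
  matched <- cigar_matched_mask(record$cigar)
  if (length(rec_coords) != truth$read_length) {
    stop(sprintf("read '%s': CIGAR consumes %d bases, truth says %d",
                 record$read_id, length(rec_coords), truth$read_length),
         call. = FALSE)
  }
  tru_coords <- truth_base_coords(truth$edit_script, truth$ref_start)
  ok <- matched & !is.na(tru_coords) & !is.na(rec_coords) &
    abs(rec_coords - tru_coords) <= config$base_tolerance
  c(matched = sum(matched), correct = sum(ok))
}

#' Evaluation metrics on simulated data with truth
#'
#' Computes, as percentages: cFAR (fraction of correctly aligned reads),
#' cFAB (correct matched bases over all matched bases of correctly aligned
#' reads), cACR (mean per-correct-read ratio of correct to matched bases),
#' base sensitivity (correct matched bases over total read bases), and
#' precision (correct matched bases over matched bases of all mapped reads).
#'
#' @param records a [mapping_records] table.
#' @param truths a [truth_records] table covering every read id in `records`.
#' @param config an [eval_config()].
#' @return list of class `evaluation_report`.
#' @export
simulated_metrics <- function(records, truths, config = eval_config()) {
  idx <- match(records$read_id, truths$read_id)
  if (anyNA(idx)) {
    stop(sprintf("no truth record for read '%s'",
                 records$read_id[which(is.na(idx))[1L]]), call. = FALSE)
  }
  n <- nrow(records)
  correct_read <- logical(n)
  m_tau <- integer(n); m_tau_c <- integer(n)
  for (i in seq_len(n)) {
    tr <- truths[idx[i], ]
    rec <- records[i, ]
    correct_read[i] <- classify_correct_read(rec, tr, config)
    mc <- count_correct_bases(rec, tr, config)
    m_tau[i] <- mc[["matched"]]; m_tau_c[i] <- mc[["correct"]]
  }
  n_correct <- sum(correct_read)
  m_total_correct_reads <- sum(m_tau[correct_read])
  total_read_bases <- sum(records$read_length)
  total_mapped_bases <- sum(m_tau[records$mapped])
  structure(list(
    N = n, N_correct = n_correct,
    per_read = data.frame(read_id = records$read_id, correct = correct_read,
                          matched = m_tau, correct_matched = m_tau_c,
                          stringsAsFactors = FALSE),
    cFAR = 100 * n_correct / n,
    cFAB = if (m_total_correct_reads > 0)
      100 * sum(m_tau_c[correct_read]) / m_total_correct_reads else NA_real_,
    cACR = if (n_correct > 0)
      100 * mean(m_tau_c[correct_read] / m_tau[correct_read]) else NA_real_,
    sensitivity = 100 * sum(m_tau_c[records$mapped]) / total_read_bases,
    precision = if (total_mapped_bases > 0)
      100 * sum(m_tau_c[records$mapped]) / total_mapped_bases else NA_real_
  ), class = "evaluation_report")
}

#' Evaluation metrics without truth
#'
#' Computes FAR (fraction of aligned reads), FAB (matched bases of aligned
#' reads over the total bases of all query reads), ACR (mean per-aligned-read
#' ratio of matched bases to read length, as a percentage), and ACR_std (the
#' population standard deviation of those per-read ratios, on the ratio
#' scale).
#'
#' @param records a [mapping_records] table (one row per query read,
#'   unmapped reads included).
#' @param read_lengths optional integer vector of query read lengths; by
#'   default taken from `records$read_length`.
#' @return list of class `evaluation_report`.
#' @export
real_metrics <- function(records, read_lengths = records$read_length) {
  n <- length(read_lengths)
  aligned <- records$mapped
  m_a <- integer(nrow(records))
  for (i in which(aligned)) {
    ops <- cigar_parse(records$cigar[i])
    m_a[i] <- sum(ops$length[ops$op == "M"])
  }
  ratios <- m_a[aligned] / records$read_length[aligned]
  pop_sd <- function(x) if (length(x)) sqrt(mean((x - mean(x))^2)) else NA_real_
  structure(list(
    N = n, N_aligned = sum(aligned),
    FAR = 100 * sum(aligned) / n,
    FAB = 100 * sum(m_a) / sum(read_lengths),
    ACR = if (any(aligned)) 100 * mean(ratios) else NA_real_,
    ACR_std = pop_sd(ratios)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  fields <- c("N", "N_correct", "N_aligned", "cFAR", "cFAB", "cACR",
              "sensitivity", "precision", "FAR", "FAB", "ACR", "ACR_std")
  for (f in intersect(fields, names(x))) {
    val <- x[[f]]
    if (is.numeric(val) && length(val) == 1L) {
      cat(sprintf("%-12s %s\n", f, format(val, digits = 6)))
    }
  }
  invisible(x)
}

#' Does alignment x cover alignment y?
#'
#' True iff both records are mapped to the same reference and the overlap of
#' their reference intervals is at least `cover_fraction` of y's interval
#' (boundary inclusive). The denominator is the covered alignment y, which
#' is what makes inter-mapper agreement tables asymmetric.
#'
#' @param x,y one-row [mapping_records] slices for the same read.
#' @param cover_fraction overlap threshold (default 0.9).
#' @return logical scalar.
#' @export
covers <- function(x, y, cover_fraction = 0.9) {
  if (!isTRUE(x$mapped) || !isTRUE(y$mapped)) return(FALSE)
  if (x$ref_id != y$ref_id) return(FALSE)
  ix <- record_interval(x); iy <- record_interval(y)
  overlap <- max(0, min(ix[2L], iy[2L]) - max(ix[1L], iy[1L]))
  overlap >= cover_fraction * (iy[2L] - iy[1L])
}

#' Pairwise agreement matrix between mappers
#'
#' `agreement[A, B]` is the percentage of B's alignments, among reads aligned
#' by both A and B, that are covered by A's alignment of the same read.
#' The diagonal is 100 by construction; off-diagonal entries are generally
#' asymmetric because [covers()] normalises by the covered alignment.
#'
#' @param record_sets named list of [mapping_records] tables, one per mapper.
#' @param cover_fraction passed to [covers()].
#' @return numeric matrix of percentages (`NA` when two mappers share no
#'   aligned read).
#' @export
agreement_matrix <- function(record_sets, cover_fraction = 0.9) {
  methods_n <- names(record_sets)
  stopifnot(!is.null(methods_n))
  k <- length(record_sets)
  out <- matrix(NA_real_, k, k, dimnames = list(methods_n, methods_n))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    ra <- record_sets[[a]]; rb <- record_sets[[b]]
    shared <- intersect(ra$read_id[ra$mapped], rb$read_id[rb$mapped])
    if (!length(shared)) next
    hit <- vapply(shared, function(id) {
      covers(ra[ra$read_id == id, ][1L, ], rb[rb$read_id == id, ][1L, ],
             cover_fraction)
    }, logical(1))
    out[a, b] <- 100 * mean(hit)
  }
  out
}

#' Count aligned reads spanning structural-variant breakpoints
#'
#' A mapped read counts once if its alignment's reference interval strictly
#' brackets (`start < bp` and `bp < end`) at least one eligible breakpoint.
#' When `truths` is supplied, a breakpoint is eligible for a read only if the
#' read's truth interval contains it, so the count is over truth-spanning
#' reads that were mapped across their own breakpoints.
#'
#' @param records a [mapping_records] table.
#' @param breakpoints integer vector of breakpoint coordinates (on the genome
#'   the records are mapped to).
#' @param truths optional [truth_records] table restricting eligibility.
#' @return integer count of spanning reads.
#' @export
count_sv_spanning <- function(records, breakpoints, truths = NULL) {
  if (!length(breakpoints)) return(0L)
  count <- 0L
  tidx <- if (!is.null(truths)) match(records$read_id, truths$read_id) else NULL
  for (i in seq_len(nrow(records))) {
    if (!records$mapped[i]) next
    elig <- breakpoints
    if (!is.null(tidx)) {
      if (is.na(tidx[i])) next
      tr <- truths[tidx[i], ]
      elig <- breakpoints[breakpoints > tr$ref_start & breakpoints < tr$ref_end]
      if (!length(elig)) next
    }
    iv <- record_interval(records[i, ])
    if (any(iv[1L] < elig & elig < iv[2L])) count <- count + 1L
  }
  count
}

#' Reads whose truth interval contains a breakpoint
#'
#' The denominator of the SV-spanning evaluation: reads that genuinely
#' straddle a breakpoint according to the simulator's truth.
#'
#' @param truths a [truth_records] table.
#' @param breakpoints integer breakpoint coordinates.
#' @return character vector of read ids.
#' @export
truth_spanning_reads <- function(truths, breakpoints) {
  keep <- vapply(seq_len(nrow(truths)), function(i) {
    any(breakpoints > truths$ref_start[i] & breakpoints < truths$ref_end[i])
  }, logical(1))
  truths$read_id[keep]
}
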