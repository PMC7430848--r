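#' Banded alignment parameters
#'
#' @param match match score (default +2).
#' @param mismatch mismatch penalty (default -2).
#' @param gap linear gap penalty `d`, subtracted per gap base (default 2).
#' @param alpha band width coefficient; the band half-width is
#'   `b = ceiling(alpha * l_r)` with `l_r` the full read length
#'   (default 0.1).
#' @param slope genome-per-read length ratio of the band geometry and the
#'   segment split (default 1.2: genome segments are 1.2 times their read
#'   segments, and row `u`'s band starts at `floor(1.2 u - b)`).
#' @param b optional explicit band half-width; when `NULL`,
#'   [align_banded_low_column()] derives it from `alpha` and its read
#'   segment length (the mapper passes the full-read value explicitly).
#' @return a list of class `band_params`.
#' @export
band_params <- function(match = 2L, mismatch = -2L, gap = 2L, alpha = 0.1,
                        slope = 1.2, b = NULL) {
  stopifnot(match > 0, mismatch < 0, gap > 0, alpha > 0, slope > 0,
            is.null(b) || b >= 1)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap = as.integer(gap), alpha = alpha, slope = slope,
                 b = if (is.null(b)) NULL else as.integer(b)),
            class = "band_params")
}

#' Starting column index of a band row
#'
#' Row `u` of the low-column matrix holds genome columns
#' `sci(u) .. sci(u) + 2b`; this returns `sci(u) = max(floor(slope * u - b),
#' 0)` computed in real arithmetic.
#'
#' @param u row index (read prefix length), vectorized.
#' @param b band half-width.
#' @param slope band slope (default 1.2).
#' @return integer vector of starting column indices.
#' @export
#' @examples
#' band_start_column(c(0, 4, 10), b = 5)
band_start_column <- function(u, b, slope = 1.2) {
  stopifnot(all(u >= 0), b >= 1)
  as.integer(pmax(floor(slope * u - b), 0))
}

#' Split read and genome at the anchor
#'
#' The anchor divides the read into an upstream segment `r_u = [0, i)` and a
#' downstream segment `r_d = [i, l_r)`, and the genome into `g_u` ending and
#' `g_d` starting at the anchor genome position. Genome segments take
#' `ceiling(slope * |r segment|)` bases (slope 1.2), clipped at the genome
#' boundaries.
#'
#' @param read_length read length `l_r`.
#' @param anchor a `start_anchor` from [select_anchor()] (or any list with
#'   `read_offset` and `genome_position`).
#' @param genome_length reference sequence length.
#' @param slope genome/read length factor (default 1.2).
#' @return list of class `segment_split` with 0-based half-open intervals
#'   `r_u`, `r_d`, `g_u`, `g_d` (each `c(start, end)`).
#' @export
split_segments <- function(read_length, anchor, genome_length, slope = 1.2) {
  i <- anchor$read_offset
  p <- anchor$genome_position
  stopifnot(i >= 0, i <= read_length, p >= 0, p <= genome_length)
  i <- as.integer(i); p <- as.integer(p)
  read_length <- as.integer(read_length)
  gu_len <- as.integer(min(ceiling(slope * i), p))
  gd_len <- as.integer(min(ceiling(slope * (read_length - i)), genome_length - p))
  structure(list(
    r_u = c(0L, i), r_d = c(i, read_length),
    g_u = c(p - gu_len, p), g_d = c(p, p + gd_len)
  ), class = "segment_split")
}

#' Banded global-in-read alignment on the low-column matrix
#'
#' Aligns a read segment against a genome segment anchored at their common
#' origin. The score matrix holds `(|r_seg| + 1) x (2b + 1)` cells whatever
#' the genome segment length: row `u` stores genome columns
#' `sci(u) .. sci(u) + 2b` with `sci(u) = max(floor(slope*u - b), 0)`.
#' Row 0 is gap-penalized (leading genome deletions cost `gap` each); all
#' read bases must be consumed; genome bases beyond the best last-row cell
#' are free. When the genome segment ends before the band can reach the last
#' read row (a reference-boundary clip), the unaligned read tail is returned
#' in `read_clipped` instead of being forced into the alignment.
#'
#' @param r_seg,g_seg character scalars (may be empty).
#' @param params a [band_params()]; `params$b`, or `ceiling(alpha * nchar(r_seg))`
#'   when `params$b` is `NULL`, sets the band half-width.
#' @param return_matrix also return the score matrix (`NA` outside the
#'   reachable band) and the per-row `sci` vector, for inspection/testing.
#' @return list of class `segment_alignment`: `score`, `ops` (data.frame of
#'   `length`/`op` over M, I, D), `genome_consumed`, `read_clipped`,
#'   `edge_touch` (did the traceback touch a band clamp), and optionally
#'   `matrix`, `sci`.
#' @export
#' @examples
#' align_banded_low_column("ACGT", "AGT", band_params())
align_banded_low_column <- function(r_seg, g_seg, params = band_params(),
                                    return_matrix = FALSE) {
  stopifnot(is.character(r_seg), is.character(g_seg))
  b <- params$b %||% max(1L, as.integer(ceiling(params$alpha * nchar(r_seg))))
  res <- .cpp_banded_align(r_seg, g_seg, b, params$slope,
                           params$match, params$mismatch, params$gap,
                           return_matrix)
  out <- list(
    score = res$score,
    ops = data.frame(length = as.integer(res$op_lengths),
                     op = as.character(res$op_chars), stringsAsFactors = FALSE),
    genome_consumed = res$genome_consumed,
    read_clipped = res$read_clipped,
    edge_touch = res$edge_touch
  )
  if (return_matrix) { out$matrix <- res$matrix; out$sci <- res$sci }
  class(out) <- "segment_alignment"
  out
}

#' Combine upstream and downstream segment alignments
#'
#' The upstream alignment is computed on the reversed upstream segments, so
#' its ops are reversed here and prepended to the downstream ops; adjacent
#' runs of the same op merge. `ref_start` is the anchor genome position minus
#' the genome bases the upstream alignment consumed. Read bases left
#' unaligned by a boundary-clipped segment become soft clips (S) at the
#' corresponding read end, and unaligned-tail I runs adjacent to a clip are
#' folded into it.
#'
#' @param upstream `segment_alignment` of `reverse(r_u)` vs `reverse(g_u)`.
#' @param downstream `segment_alignment` of `r_d` vs `g_d`.
#' @param split the [split_segments()] result.
#' @param anchor the anchor the split was made at.
#' @return list with `ref_start`, `cigar`, `score`.
#' @export
combine_alignments <- function(upstream, downstream, split, anchor) {
  up_ops <- upstream$ops[rev(seq_len(nrow(upstream$ops))), , drop = FALSE]
  lengths <- c(upstream$read_clipped, up_ops$length, downstream$ops$length,
               downstream$read_clipped)
  ops <- c("S", up_ops$op, downstream$ops$op, "S")
  # fold I runs that sit against a terminal clip into the clip
  keep <- lengths > 0L
  lengths <- lengths[keep]; ops <- ops[keep]
  if (length(ops) >= 2L && ops[1L] == "S") {
    while (length(ops) >= 2L && ops[2L] == "I") {
      lengths[1L] <- lengths[1L] + lengths[2L]
      lengths <- lengths[-2L]; ops <- ops[-2L]
    }
  }
  nn <- length(ops)
  if (nn >= 2L && ops[nn] == "S") {
    while (length(ops) >= 2L && ops[length(ops) - 1L] == "I") {
      lengths[length(ops)] <- lengths[length(ops)] + lengths[length(ops) - 1L]
      lengths <- lengths[-(length(ops) - 1L)]; ops <- ops[-(length(ops) - 1L)]
    }
  }
  cigar <- cigar_string(lengths, ops)
  ref_start <- anchor$genome_position - upstream$genome_consumed
  sp <- cigar_spans(cigar)
  expected_read <- (split$r_u[2L] - split$r_u[1L]) + (split$r_d[2L] - split$r_d[1L])
  if (sp$read != expected_read) {
    stop(sprintf("internal: combined CIGAR consumes %d read bases, expected %d",
                 sp$read, expected_read), call. = FALSE)
  }
  list(ref_start = as.integer(ref_start), cigar = cigar,
       score = upstream$score + downstream$score)
}
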