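#' Anchor locator configuration
#'
#' @param word_step spacing between sampled read offsets (default 1: every
#'   offset is sampled; the modified position o = p - i is a read-coordinate
#'   quantity, so denser sampling only strengthens the credibility signal).
#' @param tolerance_coefficient the error-tolerant window is
#'   `L(r) = tolerance_coefficient * read_length` (default 0.2), used as a
#'   real number in the `|o_j - o_i| <= L(r)` comparison.
#' @return a list of class `locator_config`.
#' @export
locator_config <- function(word_step = 1L, tolerance_coefficient = 0.2) {
  stopifnot(word_step >= 1L, tolerance_coefficient > 0)
  structure(list(word_step = as.integer(word_step),
                 tolerance_coefficient = tolerance_coefficient),
            class = "locator_config")
}

#' Collect word matches between a read and the reference index
#'
#' Samples read offsets `i = 0, step, 2*step, ...` and queries each k-length
#' word against the index. One match set is returned per offset whose word is
#' N-free and has at least one unmasked genome occurrence. Each set carries
#' the genome positions `p` and the modified positions `o = p - i`, which are
#' constant along a gap-free alignment diagonal.
#'
#' @param read character scalar (read bases) or length-1 `DNAStringSet`.
#' @param index a `word_index` from [build_index()].
#' @param config a [locator_config()].
#' @return list of match sets, each a list with `read_offset` (0-based),
#'   `positions`, `modified_positions`, and `count`; empty list when the read
#'   is shorter than k.
#' @export
collect_word_matches <- function(read, index, config = locator_config()) {
  bases <- if (is.character(read)) read else as.character(read[[1L]])
  lr <- nchar(bases)
  k <- index$k
  if (lr < k) return(list())
  all_codes <- kmer_codes(bases, k)                           # NA: word has N
  offsets <- seq.int(0L, lr - k, by = config$word_step)       # 0-based
  codes <- all_codes[offsets + 1L]
  keep <- !is.na(codes)
  offsets <- offsets[keep]; codes <- codes[keep]
  if (!length(offsets)) return(list())
  hits <- locate_codes(index, codes)
  nonempty <- lengths(hits) > 0L
  mapply(function(i, p) {
    list(read_offset = i, positions = p, modified_positions = p - i,
         count = length(p))
  }, offsets[nonempty], hits[nonempty], SIMPLIFY = FALSE)
}

#' Credibility scores of candidate starting positions
#'
#' For every candidate (word occurrence) with modified position `o`, the
#' credibility `S(o)` counts all word-match modified positions, across all
#' match sets and including the candidate itself, that lie within the
#' error-tolerant window `|o' - o| <= L(r)`. A candidate therefore always
#' scores at least 1.
#'
#' The count is computed by sorting the pooled modified positions once and
#' counting each window with binary search; equality with the literal
#' double-loop definition is covered by the test suite.
#'
#' @param match_sets output of [collect_word_matches()].
#' @param read_length read length in bases (defines `L(r)`).
#' @param config a [locator_config()].
#' @return data.frame with one row per candidate: `read_offset`, `list_index`
#'   (position within its match set), `genome_position`, `modified_position`,
#'   `credibility`.
#' @export
credibility_scores <- function(match_sets, read_length, config = locator_config()) {
  if (!length(match_sets)) {
    return(data.frame(read_offset = integer(0), list_index = integer(0),
                      genome_position = integer(0), modified_position = integer(0),
                      credibility = integer(0)))
  }
  offs <- rep(vapply(match_sets, `[[`, integer(1), "read_offset"),
              vapply(match_sets, `[[`, integer(1), "count"))
  pos <- unlist(lapply(match_sets, `[[`, "positions"), use.names = FALSE)
  mods <- pos - offs
  lidx <- unlist(lapply(match_sets, function(s) seq_len(s$count)), use.names = FALSE)
  data.frame(read_offset = offs, list_index = lidx, genome_position = pos,
             modified_position = mods,
             credibility = window_counts(mods, read_length, config))
}

# internal: S(o) for each entry of `mods` (integer vector), by binary search
# over the sorted pool. L(r) is real; the integer window is
# [ceil(o - L), floor(o + L)].
window_counts <- function(mods, read_length, config) {
  L <- config$tolerance_coefficient * read_length
  v <- sort(mods)
  hi <- floor(mods + L)
  lo <- ceiling(mods - L)
  findInterval(hi, v) - findInterval(lo - 1L, v)
}

#' Select the alignment starting anchor from scored candidates
#'
#' Picks the candidate with maximal credibility. Ties are broken by (when
#' `read_length` is supplied) the read offset closest to the read midpoint,
#' then by smaller genome position, then by smaller read offset. Centring
#' the anchor keeps both alignment segments near half the read length, which
#' is what the low-column band geometry (band half-width 0.1 of the read
#' length around the corner diagonal of the read x 1.2-read matrix) is sized
#' for; see the methods vignette.
#'
#' @param candidates data.frame from [credibility_scores()].
#' @param read_length optional read length enabling the midpoint tie-break.
#' @return list with `read_offset`, `genome_position`, `credibility`
#'   (class `start_anchor`), or `NULL` when there are no candidates.
#' @export
select_anchor <- function(candidates, read_length = NULL) {
  if (is.null(candidates) || nrow(candidates) == 0L) return(NULL)
  best <- candidates[candidates$credibility == max(candidates$credibility), , drop = FALSE]
  if (!is.null(read_length)) {
    d <- abs(best$read_offset - read_length / 2)
    best <- best[order(d, best$genome_position, best$read_offset), , drop = FALSE]
  } else {
    best <- best[order(best$genome_position, best$read_offset), , drop = FALSE]
  }
  structure(list(read_offset = best$read_offset[1L],
                 genome_position = best$genome_position[1L],
                 credibility = best$credibility[1L]),
            class = "start_anchor")
}

# internal: best anchor of one read string against one index (single strand)
anchor_read <- function(bases, index, config) {
  sets <- collect_word_matches(bases, index, config)
  if (!length(sets)) return(NULL)
  cand <- credibility_scores(sets, nchar(bases), config)
  select_anchor(cand, read_length = nchar(bases))
}
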