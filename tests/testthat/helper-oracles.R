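# Independent oracles used to check the implementation. These deliberately
# use different algorithms/data layouts than the package code paths.

# Full-matrix global-in-read DP with linear gaps and a free genome suffix:
# score of the best alignment consuming all of `r` and a prefix of `g`.
# Row-vectorized; the within-row (left-gap) dependency is resolved with the
# running-max identity max_j<=c (M1[j] - d*(c-j)) = cummax(M1[j] + d*j) - d*c.
oracle_global_suffix_free <- function(r, g, match = 2, mismatch = -2, gap = 2) {
  n <- nchar(r); m <- nchar(g)
  rb <- strsplit(r, "", fixed = TRUE)[[1]]
  gb <- strsplit(g, "", fixed = TRUE)[[1]]
  if (n == 0) return(0)
  prev <- -gap * (0:m)
  for (u in 1:n) {
    sub <- ifelse(gb == rb[u] & rb[u] != "N", match, mismatch)
    m1 <- pmax(c(-Inf, prev[1:m] + sub), prev - gap)
    cur <- cummax(m1 + gap * (0:m)) - gap * (0:m)
    prev <- cur
  }
  max(prev)
}

# Full-matrix banded DP: same recurrence restricted to the band
# [sci(u), sci(u) + 2b] per row, cells outside the band -Inf. Returns the
# whole (n+1) x (m+1) matrix for cell-for-cell comparison.
oracle_banded_matrix <- function(r, g, b, slope = 1.2, match = 2, mismatch = -2,
                                 gap = 2) {
  n <- nchar(r); m <- nchar(g)
  rb <- strsplit(r, "", fixed = TRUE)[[1]]
  gb <- if (m > 0) strsplit(g, "", fixed = TRUE)[[1]] else character(0)
  sci <- pmax(floor(slope * (0:n) - b), 0)
  G <- matrix(-Inf, n + 1, m + 1)
  cols0 <- 0:min(2 * b, m)
  G[1, cols0 + 1] <- -gap * cols0
  for (u in seq_len(n)) {
    lo <- sci[u + 1]; hi <- min(sci[u + 1] + 2 * b, m)
    if (lo > m) break
    prev <- G[u, ]
    sub <- ifelse(gb == rb[u] & rb[u] != "N", match, mismatch)
    m1 <- pmax(c(-Inf, prev[1:m] + sub), prev - gap)      # diag / up into col c
    m1[setdiff(0:m, lo:hi) + 1] <- -Inf                   # only in-band cells exist
    cs <- lo:hi
    G[u + 1, cs + 1] <- cummax(m1[cs + 1] + gap * cs) - gap * cs
  }
  G
}

# Exhaustive alignment enumeration for tiny strings: every global-in-read
# alignment (read fully consumed, genome prefix consumed, suffix free).
# Returns best score and all op strings (M/I/D characters) achieving it.
oracle_enumerate <- function(r, g, match = 2, mismatch = -2, gap = 2) {
  n <- nchar(r); m <- nchar(g)
  best <- list(score = -Inf, paths = character(0))
  rec <- function(i, j, score, path) {
    if (i == n) {
      # genome suffix beyond j is free
      if (score > best$score) best <<- list(score = score, paths = character(0))
      if (score == best$score) best$paths <<- c(best$paths, path)
      return(invisible())
    }
    if (j < m) {
      s <- if (substr(r, i + 1, i + 1) == substr(g, j + 1, j + 1)) match else mismatch
      rec(i + 1, j + 1, score + s, paste0(path, "M"))
      rec(i, j + 1, score - gap, paste0(path, "D"))
    }
    rec(i + 1, j, score - gap, paste0(path, "I"))
  }
  rec(0, 0, 0, "")
  best
}

# Literal double-loop credibility of Eqs-style definition: for each candidate
# (i, l), count all (j, k) across all match sets with |o_j^k - o_i^l| <= L.
oracle_credibility <- function(match_sets, read_length, coeff = 0.2) {
  L <- coeff * read_length
  all_o <- unlist(lapply(match_sets, `[[`, "modified_positions"))
  out <- list()
  for (s in match_sets) {
    for (l in seq_along(s$modified_positions)) {
      o <- s$modified_positions[l]
      cnt <- 0L
      for (oo in all_o) if (abs(oo - o) <= L) cnt <- cnt + 1L
      out[[length(out) + 1L]] <- data.frame(read_offset = s$read_offset,
                                            list_index = l,
                                            modified_position = o,
                                            credibility = cnt)
    }
  }
  do.call(rbind, out)
}

# Brute-force word occurrence scan (index oracle)
oracle_locate <- function(genome, word) {
  k <- nchar(word)
  n <- nchar(genome)
  if (n < k) return(integer(0))
  starts <- 1:(n - k + 1)
  which(substring(genome, starts, starts + k - 1) == word) - 1L
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Apply `n_edits` random single-base edits (sub/ins/del) to a string
perturb_dna <- function(x, n_edits) {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  for (e in seq_len(n_edits)) {
    if (length(ch) == 0) break
    pos <- sample(length(ch), 1)
    kind <- sample(3, 1)
    if (kind == 1) ch[pos] <- sample(setdiff(c("A", "C", "G", "T"), ch[pos]), 1)
    else if (kind == 2) ch <- append(ch, sample(c("A", "C", "G", "T"), 1), after = pos)
    else ch <- ch[-pos]
  }
  paste(ch, collapse = "")
}

# Re-score an ops table against the aligned pair (independent of the DP)
score_of_ops <- function(r, g, ops, match = 2L, mismatch = -2L, gap = 2L) {
  i <- 0L; j <- 0L; sc <- 0L
  for (row in seq_len(nrow(ops))) {
    len <- ops$length[row]
    op <- ops$op[row]
    if (op == "M") {
      for (t in seq_len(len)) {
        sc <- sc + if (substr(r, i + t, i + t) == substr(g, j + t, j + t)) match else mismatch
      }
      i <- i + len; j <- j + len
    } else if (op == "I") { i <- i + len; sc <- sc - gap * len }
    else if (op == "D") { j <- j + len; sc <- sc - gap * len }
  }
  sc
}

# shared state between acceptance criteria (criterion 8 re-checks the records
# produced by criteria 4-6)
acceptance_cache <- new.env(parent = emptyenv())

# cell-for-cell comparison of a low-column result (with matrix) against the
# banded full-matrix oracle; one logical per pair keeps testthat fast
low_column_equals_banded <- function(lc, G, m) {
  W <- ncol(lc$matrix)
  for (u in seq_len(nrow(lc$matrix)) - 1L) {
    cc <- (0:(W - 1L)) + lc$sci[u + 1]
    ok <- cc <= m
    got <- as.numeric(lc$matrix[u + 1, ok])
    got[is.na(got)] <- -Inf
    want <- unname(G[u + 1, cc[ok] + 1])
    if (!identical(got, want)) return(FALSE)
  }
  # rows beyond the reachable depth must be entirely out of band in the oracle
  if (nrow(lc$matrix) < nrow(G)) {
    extra <- G[(nrow(lc$matrix) + 1):nrow(G), , drop = FALSE]
    if (any(is.finite(extra))) return(FALSE)
  }
  TRUE
}
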