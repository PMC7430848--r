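make_index6 <- function() build_index(c(chr = "ACGTACGT"), k = 4)

test_that("collect_word_matches gathers per-offset genome positions", {
  idx <- make_index6()
  sets <- collect_word_matches("ACGTAC", idx, locator_config())
  expect_length(sets, 3L)
  expect_identical(vapply(sets, `[[`, integer(1), "read_offset"), 0:2)
  expect_identical(sets[[1]]$positions, c(0L, 4L))
  expect_identical(sets[[1]]$modified_positions, c(0L, 4L))
  expect_identical(sets[[2]]$positions, 1L)
  expect_identical(sets[[2]]$modified_positions, 0L)
  expect_identical(sets[[3]]$modified_positions, 0L)
  # brute-force check of every set against a substring scan
  for (s in sets) {
    w <- substring("ACGTAC", s$read_offset + 1, s$read_offset + 4)
    expect_identical(s$positions, oracle_locate("ACGTACGT", w))
  }
})

test_that("short reads and fully-masked words yield no match sets", {
  idx <- make_index6()
  expect_identical(collect_word_matches("ACG", idx), list())
  rep_idx <- build_index(c(chr = strrep("A", 30)), k = 4, occurrence_cap = 5)
  expect_identical(collect_word_matches("AAAAAA", rep_idx), list())
  # word sampling honours the step
  sets2 <- collect_word_matches("ACGTAC", idx, locator_config(word_step = 2))
  expect_identical(vapply(sets2, `[[`, integer(1), "read_offset"), c(0L, 2L))
})

test_that("credibility matches the worked example and trivial cases", {
  idx <- make_index6()
  sets <- collect_word_matches("ACGTAC", idx)
  cand <- credibility_scores(sets, read_length = 6)
  # pooled modified positions {0, 4, 0, 0}; L(r) = 1.2
  expect_identical(cand$credibility[cand$modified_position == 0],
                   rep(3L, 3))
  expect_identical(cand$credibility[cand$modified_position == 4], 1L)

  single <- list(list(read_offset = 0L, positions = 10L,
                      modified_positions = 10L, count = 1L))
  expect_identical(credibility_scores(single, 100)$credibility, 1L)

  # all words on one diagonal: every candidate scores the total count
  diag <- list(
    list(read_offset = 0L, positions = c(5L, 5L), modified_positions = c(5L, 5L), count = 2L),
    list(read_offset = 3L, positions = 8L, modified_positions = 5L, count = 1L)
  )
  expect_identical(credibility_scores(diag, 10)$credibility, rep(3L, 3))
})

test_that("efficient credibility equals the double-loop definition", {
  set.seed(201)
  for (rep in 1:100) {
    n_sets <- sample(1:8, 1)
    read_length <- sample(20:200, 1)
    sets <- lapply(seq_len(n_sets), function(j) {
      cnt <- sample(1:6, 1)
      pos <- sort(sample(0:500, cnt))
      off <- sample(0:(read_length - 5), 1)
      list(read_offset = off, positions = pos, modified_positions = pos - off,
           count = cnt)
    })
    got <- credibility_scores(sets, read_length)
    want <- oracle_credibility(sets, read_length)
    expect_identical(got$credibility, want$credibility)
    expect_identical(got$modified_position, want$modified_position)
  }
})

test_that("select_anchor picks the maximal candidate with documented tie-breaks", {
  idx <- make_index6()
  cand <- credibility_scores(collect_word_matches("ACGTAC", idx), 6)
  a <- select_anchor(cand, read_length = 6)
  expect_s3_class(a, "start_anchor")
  expect_identical(a$credibility, 3L)
  expect_identical(a$genome_position - a$read_offset, 0L)  # winning diagonal

  expect_null(select_anchor(cand[0, ]))
  expect_null(select_anchor(NULL))

  # equal scores at the same offset: smaller genome position wins
  tie <- data.frame(read_offset = c(0L, 0L), list_index = 1:2,
                    genome_position = c(100L, 50L),
                    modified_position = c(100L, 50L), credibility = c(7L, 7L))
  expect_identical(select_anchor(tie)$genome_position, 50L)
  expect_identical(select_anchor(tie, read_length = 40)$genome_position, 50L)

  # equal scores on one diagonal: the offset nearest the read midpoint wins
  diag_tie <- data.frame(read_offset = c(0L, 48L, 96L), list_index = 1L,
                         genome_position = c(0L, 48L, 96L) + 1000L,
                         modified_position = 1000L, credibility = 9L)
  expect_identical(select_anchor(diag_tie, read_length = 100)$read_offset, 48L)
  # without a read length the spec's literal order applies
  expect_identical(select_anchor(diag_tie)$read_offset, 0L)
})

test_that("shifting the genome shifts the winner, not its credibility", {
  set.seed(202)
  for (rep in 1:20) {
    sets <- lapply(1:4, function(j) {
      cnt <- sample(1:4, 1)
      pos <- sort(sample(0:300, cnt))
      off <- sample(0:40, 1)
      list(read_offset = off, positions = pos, modified_positions = pos - off,
           count = cnt)
    })
    shift <- sample(10:500, 1)
    shifted <- lapply(sets, function(s) {
      s$positions <- s$positions + shift
      s$modified_positions <- s$modified_positions + shift
      s
    })
    a <- select_anchor(credibility_scores(sets, 50), read_length = 50)
    b <- select_anchor(credibility_scores(shifted, 50), read_length = 50)
    expect_identical(b$genome_position, a$genome_position + shift)
    expect_identical(b$credibility, a$credibility)
  }
})

test_that("error-free reads anchor on the true diagonal with full credibility", {
  set.seed(203)
  g <- random_dna(3000)
  idx <- build_index(c(chr = g), k = 14)
  for (rep in 1:5) {
    start <- sample(0:(3000 - 400), 1)
    read <- substring(g, start + 1, start + 400)
    sets <- collect_word_matches(read, idx)
    a <- select_anchor(credibility_scores(sets, 400), read_length = 400)
    expect_identical(a$genome_position - a$read_offset, start)
    # credibility counts every pooled occurrence within the window; on the
    # true diagonal that includes at least all sampled words
    expect_gte(a$credibility, length(sets))
  }
})
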