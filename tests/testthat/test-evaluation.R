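rec_row <- function(read_id = "r", mapped = TRUE, ref_id = "chr", strand = "+",
                    ref_start = 0L, cigar = "100M", score = 0L,
                    read_length = 100L) {
  mapping_records(read_id, mapped, ref_id, strand, ref_start, cigar, score,
                  read_length)
}
tru_row <- function(read_id = "r", read_length = 100L, ref_id = "chr",
                    strand = "+", ref_start = 0L, ref_end = 100L,
                    edit_script = "100M") {
  truth_records(read_id, read_length, ref_id, strand, ref_start, ref_end,
                edit_script)
}

test_that("classify_correct_read applies the 0.9-read-length overlap rule", {
  tr <- tru_row()
  expect_true(classify_correct_read(rec_row(ref_start = 5L, cigar = "5S95M",
                                            read_length = 100L), tr))  # overlap 95
  expect_true(classify_correct_read(rec_row(ref_start = 10L, cigar = "10S90M"), tr))
  expect_false(classify_correct_read(rec_row(ref_start = 11L, cigar = "11S89M"), tr))
  expect_false(classify_correct_read(rec_row(strand = "-"), tr))
  expect_false(classify_correct_read(rec_row(ref_id = "other"), tr))
  expect_false(classify_correct_read(rec_row(mapped = FALSE, ref_id = NA,
                                             ref_start = NA, cigar = "*"), tr))
})

test_that("count_correct_bases walks CIGAR vs truth with inclusive tolerance 5", {
  tr <- tru_row()
  exact <- count_correct_bases(rec_row(), tr)
  expect_identical(unname(exact), c(100L, 100L))

  # alignment shifted 5 everywhere: still correct (boundary inclusive)
  sh5 <- count_correct_bases(rec_row(ref_start = 5L, cigar = "100M"), tr)
  expect_identical(unname(sh5), c(100L, 100L))
  # shifted 6: nothing is correct
  sh6 <- count_correct_bases(rec_row(ref_start = 6L, cigar = "100M"), tr)
  expect_identical(unname(sh6), c(100L, 0L))

  # truth-inserted read bases are never correct; S/I record bases not matched
  tr_ins <- tru_row(read_length = 100L, ref_end = 99L,
                    edit_script = "50MIA49M")
  mixed <- count_correct_bases(rec_row(cigar = "50M1I49M",
                                       ref_start = 0L), tr_ins)
  expect_identical(unname(mixed), c(99L, 99L))
  forced <- count_correct_bases(rec_row(cigar = "100M", ref_start = 0L), tr_ins)
  expect_identical(unname(forced)[1], 100L)
  expect_lte(unname(forced)[2], 99L)
})

test_that("simulated_metrics reproduces the constructed toy exactly", {
  recs <- rbind(
    rec_row("a"),                                        # (100, 100), correct
    rec_row("b", cigar = "50M6D50M"),                    # (100, 50), correct
    rec_row("c", mapped = FALSE, ref_id = NA, ref_start = NA, cigar = "*")
  )
  class(recs) <- c("mapping_records", "data.frame")
  truths <- rbind(tru_row("a"), tru_row("b"), tru_row("c"))
  class(truths) <- c("truth_records", "data.frame")
  rep <- simulated_metrics(recs, truths)
  expect_equal(rep$cFAR, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(rep$cFAB, 75)
  expect_equal(rep$cACR, 75)
  expect_equal(rep$sensitivity, 100 * 150 / 300)
  expect_equal(rep$precision, 75)
  expect_identical(rep$N_correct, 2L)

  # 4 reads, 2 correct -> cFAR 50
  recs4 <- rbind(recs, rec_row("d", ref_start = 50L, cigar = "50S50M"))
  class(recs4) <- c("mapping_records", "data.frame")
  truths4 <- rbind(truths, tru_row("d"))
  expect_equal(simulated_metrics(recs4, truths4)$cFAR, 50)

  expect_error(simulated_metrics(rbind(recs, rec_row("zz")), truths),
               "no truth record for read 'zz'")
})

test_that("simulated_metrics equals an independent per-read recomputation", {
  g <- generate_genome(20000, seed = 601)
  sim <- simulate_reads(g, simulator_config(depth = 0.6, read_length_mean = 800,
                                            read_length_sd = 100,
                                            error_rate = 0.12, seed = 602))
  recs <- map_reads(sim$reads, g, mapper_config())
  rep <- simulated_metrics(recs, sim$truths)

  # double-entry bookkeeping with separate code paths
  cfg <- eval_config()
  n_c <- 0L; mc_sum <- 0L; m_sum <- 0L; acr_terms <- c()
  mc_all <- 0L; m_all <- 0L
  for (i in seq_len(nrow(recs))) {
    tr <- sim$truths[match(recs$read_id[i], sim$truths$read_id), ]
    if (!recs$mapped[i]) next
    rc <- bandmap:::cigar_base_coords(recs$cigar[i], recs$ref_start[i])
    tc <- bandmap:::truth_base_coords(tr$edit_script, tr$ref_start)
    mm <- bandmap:::cigar_matched_mask(recs$cigar[i])
    corr <- sum(mm & !is.na(tc) & abs(rc - tc) <= 5, na.rm = TRUE)
    mt <- sum(mm)
    mc_all <- mc_all + corr; m_all <- m_all + mt
    iv_lo <- recs$ref_start[i]
    iv_hi <- iv_lo + bandmap:::cigar_spans(recs$cigar[i])$ref
    ov <- min(iv_hi, tr$ref_end) - max(iv_lo, tr$ref_start)
    if (recs$strand[i] == tr$strand && ov >= 0.9 * recs$read_length[i]) {
      n_c <- n_c + 1L; mc_sum <- mc_sum + corr; m_sum <- m_sum + mt
      acr_terms <- c(acr_terms, corr / mt)
    }
  }
  expect_identical(rep$N_correct, n_c)
  expect_equal(rep$cFAR, 100 * n_c / nrow(recs))
  expect_equal(rep$cFAB, 100 * mc_sum / m_sum)
  expect_equal(rep$cACR, 100 * mean(acr_terms))
  expect_equal(rep$sensitivity, 100 * mc_all / sum(recs$read_length))
  expect_equal(rep$precision, 100 * mc_all / m_all)
})

test_that("real_metrics reproduces its toy and degenerate cases", {
  recs <- rbind(
    rec_row("a", cigar = "5S90M5I", ref_start = 10L),   # 90 matched of 100
    rec_row("b", cigar = "100M"),                       # 100 matched
    rec_row("c", mapped = FALSE, ref_id = NA, ref_start = NA, cigar = "*"),
    rec_row("d", mapped = FALSE, ref_id = NA, ref_start = NA, cigar = "*")
  )
  class(recs) <- c("mapping_records", "data.frame")
  rep <- real_metrics(recs)
  expect_equal(rep$FAR, 50)
  expect_equal(rep$FAB, 47.5)       # 190 / 400
  expect_equal(rep$ACR, 95)
  expect_equal(rep$ACR_std, stats::sd(c(0.9, 1)) * sqrt(1 / 2))  # population sd

  perfect <- rbind(rec_row("a"), rec_row("b"))
  class(perfect) <- c("mapping_records", "data.frame")
  repp <- real_metrics(perfect)
  expect_equal(repp$FAR, 100)
  expect_equal(repp$FAB, 100)
  expect_equal(repp$ACR, 100)
  expect_equal(repp$ACR_std, 0)
})

test_that("covers uses y's interval as denominator with an inclusive boundary", {
  x <- rec_row("r", cigar = "1000M", ref_start = 0L, read_length = 1000L)
  y <- rec_row("r", cigar = "900M", ref_start = 50L, read_length = 900L)
  expect_true(covers(x, y))    # 900/900
  expect_true(covers(y, x))    # 900/1000 = 0.9 exactly, inclusive
  z <- rec_row("r", cigar = "100M", ref_start = 5000L)
  expect_false(covers(x, z))
  expect_false(covers(z, x))
  expect_false(covers(x, rec_row("r", mapped = FALSE, ref_id = NA,
                                 ref_start = NA, cigar = "*")))
})

test_that("agreement_matrix is 100 on the diagonal and asymmetric off it", {
  a <- rbind(rec_row("r1", cigar = "1000M", ref_start = 0L, read_length = 1000L),
             rec_row("r2", cigar = "1000M", ref_start = 5000L, read_length = 1000L))
  b <- rbind(rec_row("r1", cigar = "800M", ref_start = 100L, read_length = 800L),
             rec_row("r2", mapped = FALSE, ref_id = NA, ref_start = NA, cigar = "*"))
  class(a) <- class(b) <- c("mapping_records", "data.frame")
  m <- agreement_matrix(list(A = a, B = b))
  expect_equal(m["A", "A"], 100)
  expect_equal(m["B", "B"], 100)
  expect_equal(m["A", "B"], 100)   # A's interval covers all of B's r1
  expect_equal(m["B", "A"], 0)     # 800/1000 < 0.9
})

test_that("count_sv_spanning brackets breakpoints strictly", {
  r <- rec_row("r", cigar = "4900M", ref_start = 100L, read_length = 4900L)
  class(r) <- c("mapping_records", "data.frame")
  expect_identical(count_sv_spanning(r, 2000L), 1L)
  expect_identical(count_sv_spanning(r, 5000L), 0L)  # half-open end
  expect_identical(count_sv_spanning(r, 100L), 0L)   # start not strict
  expect_identical(count_sv_spanning(r, integer(0)), 0L)
  un <- rec_row("r", mapped = FALSE, ref_id = NA, ref_start = NA, cigar = "*")
  class(un) <- c("mapping_records", "data.frame")
  expect_identical(count_sv_spanning(un, 2000L), 0L)

  # with truths, only breakpoints inside the read's truth interval count
  tr <- tru_row("r", read_length = 4900L, ref_end = 4900L,
                edit_script = "4900M", ref_start = 0L)
  expect_identical(count_sv_spanning(r, c(2000L, 50L), tr), 1L)
  tr_away <- tru_row("r", read_length = 4900L, ref_start = 6000L,
                     ref_end = 10900L, edit_script = "4900M")
  expect_identical(count_sv_spanning(r, 2000L, tr_away), 0L)
  expect_identical(truth_spanning_reads(tr, c(2000L, 9000L)), "r")
  expect_identical(truth_spanning_reads(tr_away, 2000L), character(0))
})
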