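test_that("generate_genome is reproducible and honours GC content", {
  g1 <- generate_genome(2000, seed = 501)
  g2 <- generate_genome(2000, seed = 501)
  expect_identical(as.character(g1), as.character(g2))
  expect_false(identical(as.character(generate_genome(2000, seed = 502)),
                         as.character(g1)))

  gc_only <- as.character(generate_genome(500, gc_content = 1, seed = 503)[[1]])
  expect_false(grepl("[AT]", gc_only))

  big <- as.character(generate_genome(1e5, gc_content = 0.5, seed = 504)[[1]])
  gc <- sum(strsplit(big, "")[[1]] %in% c("G", "C"))
  sd3 <- 3 * sqrt(1e5 * 0.25)
  expect_lt(abs(gc - 5e4), sd3)
})

test_that("error-free simulation copies templates with all-match truth", {
  g <- generate_genome(20000, seed = 505)
  gs <- as.character(g[[1]])
  sim <- simulate_reads(g, simulator_config(depth = 0.5, read_length_mean = 1000,
                                            read_length_sd = 100, error_rate = 0,
                                            seed = 506))
  expect_gt(nrow(sim$truths), 0L)
  for (i in seq_len(nrow(sim$truths))) {
    tr <- sim$truths[i, ]
    expect_match(tr$edit_script, "^[0-9]+M$")
    tpl <- substring(gs, tr$ref_start + 1, tr$ref_end)
    stored <- as.character(sim$reads[[i]])
    expect_identical(stored, if (tr$strand == "-") revcomp(tpl) else tpl)
  }
})

test_that("truth edit scripts reconstruct every simulated read exactly", {
  g <- generate_genome(30000, seed = 507)
  gs <- as.character(g[[1]])
  sim <- simulate_reads(g, simulator_config(depth = 0.5, read_length_mean = 800,
                                            read_length_sd = 200,
                                            error_rate = 0.2, seed = 508))
  for (i in seq_len(nrow(sim$truths))) {
    tr <- sim$truths[i, ]
    tpl <- substring(gs, tr$ref_start + 1, tr$ref_end)
    expect_identical(apply_edit_script(tr$edit_script, tpl, tr$strand),
                     as.character(sim$reads[[i]]))
    expect_identical(nchar(as.character(sim$reads[[i]])), tr$read_length)
  }
})

test_that("simulation is seed-stable and statistically calibrated", {
  g <- generate_genome(50000, seed = 509)
  cfg <- simulator_config(depth = 0.3, read_length_mean = 1000,
                          read_length_sd = 100, error_rate = 0.15, seed = 510)
  s1 <- simulate_reads(g, cfg)
  s2 <- simulate_reads(g, cfg)
  expect_identical(as.character(s1$reads), as.character(s2$reads))
  expect_identical(s1$truths$edit_script, s2$truths$edit_script)

  # realized error fraction across ~2e5 template bases within 3 binomial sd
  big <- simulate_reads(generate_genome(100000, seed = 511),
                        simulator_config(depth = 2, read_length_mean = 1000,
                                         read_length_sd = 100,
                                         error_rate = 0.15, seed = 512))
  n_err <- 0L; n_tpl <- 0L
  for (s in big$truths$edit_script) {
    ops <- bandmap:::parse_edit_script(s)
    n_err <- n_err + sum(ops$op %in% c("X", "I")) + sum(ops$length[ops$op == "D"])
    n_tpl <- n_tpl + sum(ops$length[ops$op %in% c("M", "X", "D")])
  }
  phat <- n_err / n_tpl
  expect_lt(abs(phat - 0.15), 3 * sqrt(0.15 * 0.85 / n_tpl))

  # strand balance at n >= 1000 reads
  many <- simulate_reads(generate_genome(5000, seed = 513),
                         simulator_config(depth = 12, read_length_mean = 60,
                                          read_length_sd = 5, error_rate = 0,
                                          seed = 514))
  n <- nrow(many$truths)
  expect_gte(n, 1000L)
  fwd <- sum(many$truths$strand == "+")
  expect_lt(abs(fwd - n / 2), 3 * sqrt(n * 0.25))
})

test_that("inject_svs edits the genome and reports variant-coordinate breakpoints", {
  g <- generate_genome(10000, seed = 515)
  gs <- as.character(g[[1]])

  del <- inject_svs(g, sv_specs("deletion", 4000L, 100L))
  expect_identical(nchar(as.character(del$genome[[1]])), 9900L)
  expect_identical(del$breakpoints, 4000L)
  expect_identical(substring(as.character(del$genome[[1]]), 3991, 4010),
                   paste0(substring(gs, 3991, 4000), substring(gs, 4101, 4110)))

  inv <- inject_svs(g, sv_specs("inversion", 2000L, 500L))
  vs <- as.character(inv$genome[[1]])
  expect_identical(nchar(vs), 10000L)
  expect_identical(substring(vs, 2001, 2500), revcomp(substring(gs, 2001, 2500)))
  expect_identical(inv$breakpoints, c(2000L, 2500L))

  ins <- inject_svs(g, sv_specs("insertion", 7000L, 300L), seed = 516)
  expect_identical(nchar(as.character(ins$genome[[1]])), 10300L)
  expect_identical(ins$breakpoints, c(7000L, 7300L))

  combo <- inject_svs(g, sv_specs(
    c("insertion", "deletion", "insertion", "inversion", "deletion",
      "insertion", "deletion"),
    c(500L, 1500L, 2500L, 4000L, 6000L, 7500L, 9000L),
    c(200L, 150L, 100L, 400L, 250L, 120L, 90L)), seed = 517)
  expect_identical(nrow(combo$svs), 7L)
  expect_identical(nchar(as.character(combo$genome[[1]])),
                   10000L + 200L + 100L + 120L - 150L - 250L - 90L)
  expect_true(all(nzchar(combo$svs$breakpoints)))

  expect_error(inject_svs(g, sv_specs(c("deletion", "inversion"),
                                      c(1000L, 1050L), c(100L, 100L))),
               "disjoint")
  expect_error(inject_svs(g, sv_specs("deletion", 9950L, 100L)), "beyond")
})

test_that("simulate_dataset writes coherent text files", {
  tmp <- withr::local_tempdir()
  prefix <- file.path(tmp, "sim")
  cfg <- simulator_config(depth = 0.5, read_length_mean = 500,
                          read_length_sd = 50, error_rate = 0.1, seed = 518)
  out <- simulate_dataset(20000, cfg, prefix,
                          svs = sv_specs("deletion", 10000L, 200L))
  expect_true(file.exists(paste0(prefix, ".fa")))
  reads <- read_sequences(paste0(prefix, ".reads.fq"))
  truths <- read_truth(paste0(prefix, ".truth.tsv"))
  expect_identical(length(reads), nrow(truths))
  genome <- read_sequences(paste0(prefix, ".fa"))
  gs <- as.character(genome[[1]])
  i <- 1L
  tr <- truths[i, ]
  expect_identical(apply_edit_script(tr$edit_script,
                                     substring(gs, tr$ref_start + 1, tr$ref_end),
                                     tr$strand),
                   as.character(reads[[i]]))
  bp <- utils::read.table(paste0(prefix, ".breakpoints.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  expect_identical(as.character(bp$breakpoints), "10000")
})
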