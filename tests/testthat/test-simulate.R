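test_that("zero substitution rate leaves the consensus untouched", {
  cons <- synthetic_alu_consensus()
  out <- mutate_consensus(cons, rate = 0, seed = 1)
  expect_identical(out$seq, cons)
  expect_equal(nrow(out$log), 0)
})

test_that("substitution counts follow the binomial expectation", {
  set.seed(19)
  L <- 10000
  cons <- random_dna(L, bases = c("A", "T")) # no CpG, pure background process
  out <- mutate_consensus(cons, rate = 0.1, cpg_multiplier = 1)
  n_mut <- nrow(out$log)
  ci <- qbinom(c(0.005, 0.995), L, 0.1)
  expect_gte(n_mut, ci[1])
  expect_lte(n_mut, ci[2])
  expect_true(all(out$log$ref != out$log$alt))
})

test_that("the mutation log reports exactly the changed positions", {
  cons <- synthetic_alu_consensus()
  out <- mutate_consensus(cons, rate = 0.2, cpg_multiplier = 4, seed = 20)
  v0 <- strsplit(cons, "")[[1]]
  v1 <- strsplit(out$seq, "")[[1]]
  expect_equal(which(v0 != v1), out$log$pos)
  expect_equal(v0[out$log$pos], out$log$ref)
  expect_equal(v1[out$log$pos], out$log$alt)
})

test_that("CpG positions mutate at the elevated deamination rate", {
  # one long CpG-rich template, many replicates at modest length
  set.seed(21)
  cons <- paste(rep("CGTA", 2500), collapse = "") # CpG C/G at known positions
  r <- 0.05; m <- 8
  out <- mutate_consensus(cons, rate = r, cpg_multiplier = m)
  v0 <- strsplit(cons, "")[[1]]
  v1 <- strsplit(out$seq, "")[[1]]
  is_c <- v0 == "C" # all Cs are CpG here
  frac_ct <- mean(v1[is_c] == "T")
  # P(C->T at CpG) = m * r = 0.4; central 99% binomial band
  n <- sum(is_c)
  band <- qbinom(c(0.005, 0.995), n, m * r) / n
  expect_gte(frac_ct, band[1])
  expect_lte(frac_ct, band[2])
})

test_that("the CpG multiplier is recovered from decayed elements", {
  cons <- synthetic_alu_consensus()
  set.seed(22)
  elements <- replicate(200, mutate_consensus(cons, rate = 0.05,
                                              cpg_multiplier = 8)$seq)
  est <- estimate_cpg_multiplier(elements, cons)
  expect_gt(est$cpg_rate, est$background_rate) # CpG transitions elevated
  expect_gte(8, est$ci[1])
  expect_lte(8, est$ci[2])
})

test_that("invalid mutation parameters are rejected", {
  expect_error(mutate_consensus("ACGT", rate = -0.1), "rate")
  expect_error(mutate_consensus("ACGT", rate = 0.5, cpg_multiplier = 0.5),
               "cpg_multiplier")
  expect_error(mutate_consensus("ACGT", rate = 0.3, cpg_multiplier = 4),
               "exceeds 1")
})

test_that("the same seed reproduces the genome byte for byte", {
  cfg <- synthetic_config(n_elements = 10, background_length = 8000, seed = 99)
  g1 <- build_synthetic_genome(cfg)
  g2 <- build_synthetic_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$annotations, g2$annotations)
  expect_identical(g1$truth, g2$truth)
})

test_that("elements are placed non-overlapping inside the background", {
  cfg <- synthetic_config(n_elements = 20, background_length = 20000, seed = 5)
  g <- build_synthetic_genome(cfg)
  a <- g$annotations[order(g$annotations$start), ]
  expect_equal(nrow(a), 20)
  expect_true(all(a$start >= 0 & a$end <= 20000))
  expect_true(all(utils::head(a$end, -1) <= utils::tail(a$start, -1)))
  expect_true(all(g$truth$start >= 0 & g$truth$end <= 20000))
  expect_error(build_synthetic_genome(
    synthetic_config(n_elements = 100, background_length = 5000)), "fit")
  g0 <- build_synthetic_genome(synthetic_config(n_elements = 0,
                                                background_length = 2000))
  expect_equal(nrow(g0$annotations), 0)
  expect_equal(nchar(unname(g0$genome)), 2000)
})

test_that("implanted perfect sites are fully recovered end to end at r = 0", {
  pwm <- p53_pwm(toy_training())
  site <- best_site(pwm)
  cfg <- synthetic_config(n_elements = 50, substitution_rate = 0,
                          background_length = 40000,
                          implant_spec = list(list(site = site, spacer = 0,
                                                   offset = 140)),
                          seed = 42)
  g <- build_synthetic_genome(cfg)
  hits <- scan_p53(pwm, g$genome, s_max = 14, cutoff = 70)
  rec <- recovery_metrics(hits, g$truth, tol = 0)
  expect_equal(rec$recall, 1.0)
  # mapped hotspots: site at offset 140, S=0 -> center 150 -> Box A'
  asg <- assign_sites(hits, g$annotations)
  exact <- asg$mapped[asg$mapped$start %in% g$truth$site_start &
                        asg$mapped$spacer == 0, ]
  truth_hits <- exact[!duplicated(exact$start), ]
  expect_equal(nrow(truth_hits), 50)
  expect_true(all(abs(truth_hits$consensus_center - 150) <= 2))
  expect_true(all(truth_hits$hotspot == "A'"))
})

test_that("minus-strand elements mirror the consensus center", {
  pwm <- p53_pwm(toy_training())
  site <- best_site(pwm)
  cfg <- synthetic_config(n_elements = 30, substitution_rate = 0,
                          background_length = 30000,
                          implant_spec = list(list(site = site, spacer = 0,
                                                   offset = 140)),
                          seed = 7)
  g <- build_synthetic_genome(cfg)
  hits <- scan_p53(pwm, g$genome, s_max = 14, cutoff = 99.9)
  asg <- assign_sites(hits, g$annotations)
  m <- asg$mapped[asg$mapped$start %in% g$truth$site_start, ]
  m <- merge(m, g$truth[, c("site_start", "strand")],
             by.x = "start", by.y = "site_start",
             suffixes = c("_site", "_element"))
  expect_true(all(c("+", "-") %in% m$strand_element))
  # the implant is placed symmetrically, so +/- centers agree after mirroring
  expect_true(all(abs(m$consensus_center - 150) <= 2))
})

test_that("recall decreases as the substitution rate grows", {
  pwm <- p53_pwm(toy_training())
  site <- best_site(pwm)
  recalls <- vapply(c(0, 0.05, 0.1, 0.2), function(r) {
    cfg <- synthetic_config(n_elements = 40, substitution_rate = r,
                            cpg_multiplier = 1, background_length = 30000,
                            implant_spec = list(list(site = site, spacer = 0,
                                                     offset = 140)),
                            seed = 11)
    g <- build_synthetic_genome(cfg)
    hits <- scan_p53(pwm, g$genome, s_max = 14, cutoff = 70)
    recovery_metrics(hits, g$truth, tol = 0)$recall
  }, numeric(1))
  expect_equal(recalls[1], 1.0)
  expect_true(all(diff(recalls) <= 0))
})

test_that("recovery metrics agree with a naive matcher", {
  truth <- data.frame(element = 1:3, start = c(0, 100, 200),
                      end = c(50, 150, 250), strand = "+", subfamily = "x",
                      site_start = c(10L, 110L, 210L), spacer = c(0L, 3L, 0L))
  pred <- data.frame(start = c(10L, 111L, 500L), spacer = c(0L, 3L, 0L))
  rec <- recovery_metrics(pred, truth, tol = 2)
  expect_equal(rec$recall, 2 / 3)
  expect_equal(rec$precision, 2 / 3)
  none <- recovery_metrics(pred[0, ], truth)
  expect_equal(none$recall, 0)
  per <- rec$per_spacer
  expect_equal(per$recall[per$spacer == 3], 1)
  expect_equal(per$recall[per$spacer == 0], 0.5)
})

test_that("simulation configs round-trip through JSON", {
  cfg <- synthetic_config(n_elements = 5, substitution_rate = 0.07,
                          background_length = 4000,
                          implant_spec = list(list(site = strrep("ACGT", 5),
                                                   spacer = 3, offset = 50)),
                          seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_synthetic_config(cfg, path)
  back <- read_synthetic_config(path)
  expect_equal(back$substitution_rate, cfg$substitution_rate)
  expect_equal(back$seed, cfg$seed)
  expect_equal(back$implant_spec[[1]]$offset, 50)
  expect_identical(build_synthetic_genome(back)$genome,
                   build_synthetic_genome(cfg)$genome)
})
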