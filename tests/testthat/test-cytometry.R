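test_that("gating accounts for every event and errors on an empty gate", {
  ev <- toy_events(nuclear = c(5, 10, 100, 500), x = 1:4)
  res <- gate_events(ev, gating_strategy("nuclear", 30), min_events = 1)
  expect_equal(res$report$n_total, 4)
  expect_equal(res$report$n_debris + res$report$n_sperm, 4)
  expect_equal(nrow(res$events), 2)
  # nothing below threshold: output identical to input
  hi <- toy_events(nuclear = c(100, 200), x = 1:2)
  res2 <- gate_events(hi, gating_strategy("nuclear", 30), min_events = 1)
  expect_identical(res2$events, hi)
  expect_equal(res2$report$n_debris, 0)
  # everything below: error
  lo <- toy_events(nuclear = c(1, 2), x = 1:2)
  expect_error(gate_events(lo, gating_strategy("nuclear", 30), 1),
               "empty gate")
  expect_error(gate_events(ev, gating_strategy("absent", 30), 1),
               "unknown channel")
  expect_warning(gate_events(ev, gating_strategy("nuclear", 30),
                             min_events = 5000), "after gating")
})

test_that("gated-out fraction matches a synthetic debris truth", {
  tr <- default_truths()$SCSA
  tr$structure$debris <- 0.2
  ev <- simulate_scsa_events(tr, 5000, seed = 8)
  res <- gate_events(ev, gating_strategy(c("green", "red"), 30),
                     min_events = 100)
  se <- sqrt(0.2 * 0.8 / 5000)
  expect_lt(abs(res$report$n_debris / res$report$n_total - 0.2), 3 * se)
})

test_that("SCSA statistics match the hand-computed worked set", {
  ev <- scsa_worked_events()
  res <- scsa_statistics(ev)
  dfis <- c(rep(100, 9), 750)
  expect_equal(res$pct_dfi, 10.0)
  expect_equal(res$sd_dfi, sd(dfis))
  expect_equal(round(res$sd_dfi, 1), 205.5)
  expect_equal(res$pct_hds, 0)
  expect_equal(res$n_events, 10)
})

test_that("the DFI threshold is strictly greater than 250", {
  ev <- toy_events(green = 3, red = 1)           # DFI exactly 250
  expect_equal(scsa_statistics(ev)$pct_dfi, 0)
  ev2 <- toy_events(green = c(3, 1), red = c(1, 1))  # 250 and 500
  expect_equal(scsa_statistics(ev2)$pct_dfi, 50)
  expect_error(scsa_statistics(toy_events(green = 0, red = 0)),
               "red \\+ green")
})

test_that("the stainability cut sits on the green channel scale", {
  cut <- 0.65 * 1023
  ev <- toy_events(green = c(700, 600), red = c(20, 20))
  expect_equal(scsa_statistics(ev, hds_threshold = cut)$pct_hds, 50)
})

test_that("median fluorescence normalizes by the reference", {
  ev <- toy_events(ch = c(1, 2, 9))
  expect_equal(median_fluorescence(ev, "ch"), 2)
  expect_equal(median_fluorescence(ev, "ch", 2), 1)
  expect_error(median_fluorescence(ev, "ch", 0), "positive")
  expect_error(median_fluorescence(ev[0, ], "ch"), "empty")
})

test_that("gate fractions partition to exactly 100", {
  ev <- toy_events(x = c(10, 20, 300, 900))
  fr <- gate_fractions(ev, "x", c(50, 500))
  expect_equal(unname(fr), c(50, 25, 25))
  expect_equal(sum(fr), 100)
  lo <- toy_events(x = c(1, 2, 3))
  expect_equal(unname(gate_fractions(lo, "x", c(50, 500))), c(100, 0, 0))
  expect_error(gate_fractions(ev, "x", c(500, 50)), "inverted")
  # property: random inputs always sum to 100
  for (i in 1:20) {
    set.seed(i)
    e <- toy_events(x = runif(50, 0, 1000))
    expect_equal(sum(gate_fractions(e, "x", c(200, 600))), 100)
  }
})

test_that("mBBr statistics implement the half-difference disulfide index", {
  u <- toy_events(mbbr = rep(4, 11))
  d <- toy_events(mbbr = rep(10, 11))
  res <- mbbr_statistics(u, d, reference_mfi = 1, bounds = c(1, 6))
  expect_equal(res$disulfide_index, 3)
  expect_false(res$negative_index)
  same <- mbbr_statistics(u, u, 1, c(1, 6))
  expect_equal(same$disulfide_index, 0)
  neg <- mbbr_statistics(d, u, 1, c(1, 6))
  expect_equal(neg$disulfide_index, -3)
  expect_true(neg$negative_index)
})

test_that("normalized statistics are invariant to a joint rescaling", {
  set.seed(4)
  ev <- toy_events(green = rlnorm(500, log(180), .2),
                   red = rlnorm(500, log(20), .2),
                   sig = rlnorm(500, log(200), .3))
  c0 <- 3.7
  scaled <- toy_events(green = c0 * ev$green, red = c0 * ev$red,
                       sig = c0 * ev$sig)
  # DFI invariant under joint rescale of red and green
  expect_equal(scsa_statistics(scaled, hds_threshold = c0 * 665)$pct_dfi,
               scsa_statistics(ev, hds_threshold = 665)$pct_dfi)
  expect_equal(median_fluorescence(scaled, "sig", c0 * 200),
               median_fluorescence(ev, "sig", 200))
  expect_equal(unname(gate_fractions(scaled, "sig", c0 * c(120, 450))),
               unname(gate_fractions(ev, "sig", c(120, 450))))
})

test_that("per-cell DFI is monotone in red at fixed green", {
  red <- seq(0.5, 400, length.out = 50)
  dfi <- 1000 * red / (red + 180)
  expect_true(all(diff(dfi) > 0))
  # through the statistic: increasing red can only increase pct_dfi
  base <- toy_events(green = rep(180, 50), red = red)
  more <- toy_events(green = rep(180, 50), red = red * 1.5)
  expect_gte(scsa_statistics(more)$pct_dfi, scsa_statistics(base)$pct_dfi)
})

test_that("CMA3 and 8-oxo-dG statistics compose median and fractions", {
  ev <- toy_events(cma3 = c(200, 250, 300, 350, 400))
  res <- cma3_statistics(ev, reference_mfi = 300, bounds = c(150, 550))
  expect_equal(res$mfi_norm, 1)
  expect_equal(res$pct_moderate, 100)
  ox <- toy_events(fitc = c(100, 200, 300, 400))
  r <- oxodg_statistics(ox, reference_mfi = 250, high_cut = 250)
  expect_equal(r$mfi_norm, 1)
  expect_equal(r$pct_high, 50)
  expect_equal(oxodg_statistics(ox, 1, 1000)$pct_high, 0)
})

test_that("physiology conditional ratios use their stated denominators", {
  p1 <- toy_events(pi = c(10, 10, 10, 500), yp = c(10, 500, 10, 500),
                   m540 = c(500, 10, 10, 10), pna = c(10, 10, 500, 500))
  p2 <- toy_events(h258 = c(10, 10, 500), cfda = c(50, 70, 400),
                   mx = c(500, 10, 10), mtdr = c(500, 500, 10))
  res <- physiology_statistics(p1, p2, stain_cut = 110, ros_reference = 60)
  expect_equal(res$pct_viable, 75)
  expect_equal(res$pct_apoptotic_of_viable, 100 / 3)
  expect_equal(res$pct_acrosome_damaged_total, 50)
  expect_equal(res$pct_acrosome_damaged_of_nonapoptotic, 50)
  expect_equal(res$pct_capacitated_of_nonapoptotic, 50)
  expect_equal(res$pct_active_mitochondria, 100 * 2 / 3)
  expect_equal(res$pct_high_superoxide_of_viable, 50)
  expect_equal(res$cytoplasmic_ros_mfi, 1)
  expect_length(res$flags, 0)
})

test_that("an empty denominator yields a flagged NA, not a failure", {
  p1 <- toy_events(pi = c(500, 500), yp = c(500, 500),
                   m540 = c(10, 10), pna = c(10, 10))
  p2 <- toy_events(h258 = c(500, 500), cfda = c(50, 60),
                   mx = c(10, 10), mtdr = c(10, 10))
  res <- physiology_statistics(p1, p2)
  expect_true(is.na(res$pct_apoptotic_of_viable))
  expect_true(is.na(res$pct_high_superoxide_of_viable))
  expect_true("pct_apoptotic_of_viable" %in% res$flags)
  expect_equal(res$pct_viable, 0)
})

test_that("all-viable panel reports 100% viability", {
  p1 <- toy_events(pi = rep(10, 5), yp = rep(10, 5),
                   m540 = rep(10, 5), pna = rep(10, 5))
  p2 <- toy_events(h258 = rep(10, 5), cfda = rep(60, 5),
                   mx = rep(10, 5), mtdr = rep(500, 5))
  res <- physiology_statistics(p1, p2, ros_reference = 60)
  expect_equal(res$pct_viable, 100)
  expect_equal(res$pct_apoptotic_of_viable, 0)
  expect_equal(res$pct_active_mitochondria, 100)
})
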