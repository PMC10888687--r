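test_that("design table enumerates boars x ejaculates x days", {
  d <- study_design(boars = 2, ejaculates_per_boar = 1, seed = 3)
  tab <- design_table(d)
  expect_equal(nrow(tab), 4)
  expect_equal(sort(unique(tab$day)), c("D0", "D11"))
  expect_false(anyDuplicated(tab$sample_id) > 0)
  expect_error(study_design(boars = 0), "boars")
})

test_that("generators are bit-identical under a fixed seed", {
  d <- study_design(boars = 2, ejaculates_per_boar = 1,
                    events_per_sample = 300, casa_cells_per_sample = 100,
                    seed = 7)
  s1 <- generate_study(d)
  s2 <- generate_study(d)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$kinematics, s2$kinematics)
  expect_identical(s1$truth, s2$truth)
  # and a different seed changes the draw
  s3 <- generate_study(study_design(boars = 2, ejaculates_per_boar = 1,
                                    events_per_sample = 300,
                                    casa_cells_per_sample = 100, seed = 8))
  expect_false(identical(s1$events[[1]]$scsa$green,
                         s3$events[[1]]$scsa$green))
})

test_that("generate_study validates its inputs", {
  d <- study_design(boars = 1, ejaculates_per_boar = 1,
                    events_per_sample = 50, casa_cells_per_sample = 50)
  tr <- default_truths()
  expect_error(generate_study(d, c(tr, tr["SCSA"])), "duplicate")
  expect_error(generate_study(d, tr[-1]), "missing assay")
})

test_that("degenerate SCSA mixture has no fragmented or stainable events", {
  tr <- default_truths()$SCSA
  tr$structure$debris <- 0
  ev <- simulate_scsa_events(tr, 3000, seed = 5,
                             params = c(p_frag = 0, p_hds = 0))
  dfi <- 1000 * ev$red / (ev$red + ev$green)
  expect_true(all(dfi <= 250))
  expect_true(all(ev$.state == "main"))
})

test_that("fragmented and debris counts follow the generator fractions", {
  tr <- default_truths()$SCSA
  n <- 5000
  ev <- simulate_scsa_events(tr, n, seed = 11,
                             params = c(p_frag = 0.011, p_hds = 0.043))
  # truth-fragmented events ~ Binomial(n, (1 - debris) * 0.011)
  p <- (1 - tr$structure$debris) * 0.011
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(ev$.state == "frag") - p), 3 * se)

  tr$structure$debris <- 0.2
  ev2 <- simulate_scsa_events(tr, n, seed = 12,
                              params = c(p_frag = 0.011, p_hds = 0.043))
  below <- ev2$green <= 30 & ev2$red <= 30
  se2 <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(mean(below) - 0.2), 3 * se2)
})

test_that("mBBr pair encodes the disulfide index in its medians", {
  tr <- default_truths()$MBBR
  # symmetric pair: zero disulfide index means identical split distributions
  pr0 <- simulate_stain_pair_mbbr(tr, 4000, seed = 3,
                                  params = c(w_low = 0.07, w_high = 0.05,
                                             loc = 1, disulfide = 1e-9))
  expect_equal(attr(pr0, "truth")[["median_dtt"]],
               attr(pr0, "truth")[["median_untreated"]], tolerance = 1e-6)
  # a stated index is recovered from the sample medians within Monte-Carlo
  # tolerance (median SE ~ 1/(2 f(m) sqrt(n)))
  pr <- simulate_stain_pair_mbbr(tr, 5000, seed = 4,
                                 params = c(w_low = 0.07, w_high = 0.05,
                                            loc = 1, disulfide = 100))
  est <- (median(pr$dtt$mbbr) - median(pr$untreated$mbbr)) / 2
  expect_lt(abs(est - 100), 5)
  # seeded determinism of the linked pair
  pr2 <- simulate_stain_pair_mbbr(tr, 5000, seed = 4,
                                  params = c(w_low = 0.07, w_high = 0.05,
                                             loc = 1, disulfide = 100))
  expect_identical(pr$untreated, pr2$untreated)
  expect_identical(pr$dtt, pr2$dtt)
})

test_that("CASA sampler respects the velocity ordering and its weights", {
  comp <- separated_casa_components()
  kin <- simulate_casa_sample(comp, 2000, seed = 21)
  expect_true(all(kin$vsl <= kin$vap + 1e-9))
  expect_true(all(kin$vap <= kin$vcl + 1e-9))
  # empirical weights within 3 multinomial SEs
  w_hat <- table(factor(kin$.component, comp$name)) / 2000
  se <- sqrt(comp$weight * (1 - comp$weight) / 2000)
  expect_true(all(abs(w_hat - comp$weight) < 3 * se))
})

test_that("a single zero-variance component gives exact identical rows", {
  comp <- casa_components(name = "only", weight = 1, vcl_med = 100,
                          vcl_sdlog = 0, wob_mean = 0.5, str_mean = 0.5,
                          kappa = Inf, alh_med = 2, alh_sdlog = 0,
                          bcf_med = 10, bcf_sdlog = 0)
  kin <- simulate_casa_sample(comp, 20, seed = 1)
  expect_equal(nrow(dplyr::distinct(kin)), 1)
  expect_equal(kin$lin[1], 100 * kin$vsl[1] / kin$vcl[1])
  expect_equal(kin$vap[1], 50)
  expect_equal(kin$vsl[1], 25)
})

test_that("channel values respect [0, channel_max] and clipping is reported", {
  tr <- default_truths()$MBBR
  pr <- simulate_stain_pair_mbbr(tr, 4000, seed = 9)
  for (ev in pr) {
    expect_true(all(ev$mbbr >= 0 & ev$mbbr <= 1023))
    expect_true(is.numeric(attr(ev, "clipped_fraction")))
  }
})

test_that("pooled %DFI over a small study recovers the generator truth", {
  d <- study_design(boars = 6, ejaculates_per_boar = 2,
                    events_per_sample = 5000, casa_cells_per_sample = 50,
                    seed = 42)
  study <- generate_study(d)
  est <- vapply(study$events, function(ev) {
    g <- gate_events(ev$scsa, gating_strategy(c("green", "red"), 30), 100)
    scsa_statistics(g$events)$pct_dfi
  }, numeric(1))
  dif <- est - study$truth$pct_dfi
  se <- sd(dif) / sqrt(length(dif))
  expect_lt(abs(mean(dif)), 3 * se + 1e-12)
})
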