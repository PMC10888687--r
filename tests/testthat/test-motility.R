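test_that("kinematic derivation reproduces the ratio definitions", {
  k <- derive_kinematics(vcl = 100, vsl = 25, vap = 50, alh = 2, bcf = 10)
  expect_equal(k$lin, 25)
  expect_equal(k$str, 50)
  expect_equal(k$wob, 50)
  expect_equal(k$dnc, 200)
  expect_equal(k$dncm, 8)
  # identity case
  k2 <- derive_kinematics(80, 80, 80, 1, 5)
  expect_equal(c(k2$lin, k2$str, k2$wob), c(100, 100, 100))
  # degenerate vsl
  k3 <- derive_kinematics(50, 0, 30, 1, 5)
  expect_equal(c(k3$lin, k3$str), c(0, 0))
  expect_true(is.na(k3$dncm))
  expect_error(derive_kinematics(0, 0, 10, 1, 1), "positive")
})

test_that("lin equals str * wob / 100 for random records", {
  set.seed(2)
  vcl <- runif(200, 20, 150)
  vap <- vcl * runif(200, 0.3, 1)
  vsl <- vap * runif(200, 0, 1)
  k <- derive_kinematics(vcl, vsl, vap, runif(200, 0.5, 4), runif(200, 2, 25))
  expect_equal(k$lin, k$str * k$wob / 100, tolerance = 1e-12)
})

test_that("motility classes follow the progressive criterion", {
  k <- derive_kinematics(vcl = c(30, 30, 5, 12),
                         vsl = c(0, 0, 0, 0) + c(30, 30, 5, 12) *
                           c(0.5, 0.4, 0.5, 0.2),
                         vap = c(30, 30, 5, 12), alh = 1, bcf = 5)
  cls <- classify_motility(k)
  expect_equal(as.character(cls),
               c("progressive", "nonprogressive", "immotile",
                 "nonprogressive"))
})

test_that("two-stage clustering recovers well-separated components", {
  kin <- simulate_casa_sample(separated_casa_components(), 2000, seed = 31)
  model <- cluster_subpopulations(kin, seed = 1)
  expect_equal(model$final_k, 3)
  expect_gt(label_agreement(kin$.component, model$labels), 0.95)
})

test_that("clustering is deterministic and order-invariant", {
  kin <- simulate_casa_sample(separated_casa_components(), 1000, seed = 32)
  m1 <- cluster_subpopulations(kin, seed = 5)
  m2 <- cluster_subpopulations(kin, seed = 5)
  expect_identical(m1$labels, m2$labels)
  perm <- sample(nrow(kin))
  m3 <- cluster_subpopulations(kin[perm, ], seed = 5)
  expect_identical(m1$labels[perm], m3$labels)
})

test_that("degenerate clustering inputs raise named errors", {
  kin <- simulate_casa_sample(separated_casa_components(), 30, seed = 1)
  expect_error(cluster_subpopulations(kin, stage1_k = 40), "fewer cells")
  same <- derive_kinematics(rep(100, 60), rep(50, 60), rep(70, 60),
                            rep(2, 60), rep(10, 60))
  expect_error(cluster_subpopulations(same, stage1_k = 10),
               "zero-variance")
})

test_that("subpopulation summaries report median, MAD and percentages", {
  kin <- simulate_casa_sample(separated_casa_components(), 1500, seed = 33)
  model <- cluster_subpopulations(kin, seed = 2)
  sid <- rep(c("s1", "s2", "s3"), length.out = nrow(kin))
  summ <- summarize_subpopulations(model, kin, sid)
  # per-sample percentages sum to 100
  pct <- as.matrix(summ$sample_percentages[, -1])
  expect_equal(unname(rowSums(pct)), rep(100, 3))
  # cluster medians recover the separated component VCL medians
  med_vcl <- unname(sort(summ$cluster_summary$median[
    summ$cluster_summary$variable == "vcl"]))
  expect_equal(med_vcl, sort(c(30, 120, 110)), tolerance = 0.1)
  # identical cells give MAD zero and a single 100% cluster
  same <- derive_kinematics(rep(c(100, 30), each = 30),
                            rep(c(50, 10), each = 30),
                            rep(c(70, 20), each = 30),
                            rep(c(2, 1), each = 30),
                            rep(c(10, 5), each = 30))
  m2 <- cluster_subpopulations(same, stage1_k = 2, k_range = 2, seed = 1)
  s2 <- summarize_subpopulations(m2, same)
  expect_true(all(s2$cluster_summary$mad == 0))
  one <- summarize_subpopulations(
    structure(list(labels = rep(1L, 10)), class = "subpop_model"),
    derive_kinematics(runif(10, 50, 60), runif(10, 10, 20),
                      runif(10, 30, 40), 2, 10))
  expect_equal(unique(one$cluster_summary$pct_overall), 100)
})
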