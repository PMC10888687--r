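test_that("exact linear dependence gives r = 1 and survives the FDR mask", {
  x <- 1:10
  tab <- tibble::tibble(a = x, b = 2 * x + 1, c = rnorm(10))
  cm <- correlation_matrix(tab, c("a", "b", "c"))
  expect_equal(cm$r["a", "b"], 1)
  expect_true(cm$significant["a", "b"])
  expect_equal(unname(diag(cm$r)), rep(1, 3))
  expect_false(any(diag(cm$significant)))
  # adjusted p never below raw p
  ut <- upper.tri(cm$p_raw)
  expect_true(all(cm$p_adjusted[ut] >= cm$p_raw[ut] - 1e-15))
})

test_that("BH adjustment matches the hand computation", {
  # hand BH on p = (.001, .02, .04, .2, .5): p * m / rank with running
  # minimum from the largest rank down
  p <- c(0.001, 0.02, 0.04, 0.2, 0.5)
  hand <- c(0.005, 0.05, 0.2 / 3, 0.25, 0.5)
  expect_equal(p.adjust(p, "BH"), hand)
  # and the matrix path masks exactly the pairs whose adjusted p > alpha
  set.seed(8)
  tab <- as.data.frame(matrix(rnorm(40 * 5), 40))
  cm <- correlation_matrix(tab, names(tab), alpha = 0.05)
  ut <- upper.tri(cm$p_adjusted)
  expect_equal(unname(cm$significant[ut]),
               unname(cm$p_adjusted[ut] <= 0.05))
  # masking never increases the number of significant pairs
  expect_lte(sum(cm$p_adjusted[ut] <= 0.05), sum(cm$p_raw[ut] <= 0.05))
})

test_that("constant variables are flagged, not fatal", {
  tab <- tibble::tibble(a = 1:10, b = rep(3, 10), c = rnorm(10))
  expect_silent(cm <- correlation_matrix(tab, c("a", "b", "c")))
  expect_equal(cm$flagged, "b")
  expect_true(is.na(cm$r["a", "b"]))
})

test_that("variable clustering merges duplicated variables first", {
  set.seed(5)
  tab <- tibble::tibble(a = rnorm(40))
  tab$b <- tab$a                       # duplicate
  tab$c <- rnorm(40)
  tab$d <- rnorm(40)
  vc <- cluster_variables(tab, c("a", "b", "c", "d"))
  expect_equal(vc$similarity["a", "b"], 1)
  first <- vc$hclust$merge[1, ]
  expect_setequal(vc$hclust$labels[-first], c("a", "b"))
  expect_equal(vc$hclust$height[1], 0, tolerance = 1e-12)
  # every variable appears exactly once as a leaf
  expect_setequal(vc$hclust$labels, c("a", "b", "c", "d"))
  expect_equal(length(vc$hclust$order), 4)
})

test_that("independent variables merge at statistically similar heights", {
  set.seed(9)
  tab <- as.data.frame(matrix(rnorm(400 * 3), 400))
  vc <- cluster_variables(tab, names(tab))
  expect_lt(diff(range(vc$hclust$height)), 0.02)
  expect_gt(min(vc$hclust$height), 0.9)
})

test_that("standardized PCA satisfies its algebraic identities", {
  set.seed(12)
  n <- 60; p <- 6
  x <- matrix(rnorm(n * p), n)
  x[, 2] <- x[, 1] + 0.5 * x[, 2]      # induce structure
  tab <- as.data.frame(x)
  fit <- principal_components(tab, names(tab))
  expect_equal(sum(fit$eigenvalues), p, tolerance = 1e-8)
  expect_equal(unname(colSums(fit$contributions)), rep(100, p),
               tolerance = 1e-8)
  expect_equal(unname(colSums(fit$loadings^2)), unname(fit$eigenvalues),
               tolerance = 1e-8)
  # loadings are the variable-score correlations
  for (j in 1:3)
    expect_equal(as.vector(stats::cor(x, fit$scores[, j])),
                 unname(fit$loadings[, j]), tolerance = 1e-8)
  # sign rule: the largest-|loading| variable of each PC is positive
  for (j in 1:p)
    expect_gte(fit$loadings[which.max(abs(fit$loadings[, j])), j], 0)
  # contributions tie loadings to eigenvalues
  expect_equal(fit$contributions,
               100 * sweep(fit$loadings^2, 2, fit$eigenvalues, "/"),
               tolerance = 1e-8)
})

test_that("independent standardized variables give near-unit eigenvalues", {
  set.seed(21)
  tab <- as.data.frame(matrix(rnorm(10000 * 4), 10000))
  fit <- principal_components(tab, names(tab))
  expect_true(all(abs(fit$eigenvalues - 1) < 0.1))
})

test_that("PCA rejects under-determined or degenerate input", {
  tab <- as.data.frame(matrix(rnorm(4 * 5), 4))
  expect_error(principal_components(tab, names(tab)), "singular")
  tab2 <- tibble::tibble(a = 1:10, b = rep(2, 10))
  expect_error(principal_components(tab2, c("a", "b")), "constant")
})

test_that("observation clustering on PC scores separates two blobs", {
  set.seed(31)
  n <- 30
  blob <- rep(c(0, 8), each = n)
  tab <- tibble::tibble(a = rnorm(2 * n) + blob, b = rnorm(2 * n) + blob,
                        c = rnorm(2 * n) + blob, d = rnorm(2 * n))
  fit <- principal_components(tab, names(tab))
  lab <- cluster_observations_on_pcs(fit, n_pcs = 2, k = 2)
  expect_equal(length(unique(lab[1:n])), 1)
  expect_equal(length(unique(lab[(n + 1):(2 * n)])), 1)
  expect_false(lab[1] == lab[2 * n])
  # duplicates always share a label; k = n gives singletons
  lab2 <- cluster_observations_on_pcs(fit, k = 2 * n)
  expect_equal(length(unique(lab2)), 2 * n)
  tab3 <- tab[rep(1:10, 2), ]
  fit3 <- principal_components(tab3, names(tab3))
  lab3 <- cluster_observations_on_pcs(fit3, k = 3)
  expect_equal(unname(lab3[1:10]), unname(lab3[11:20]))
  expect_error(cluster_observations_on_pcs(fit, k = 1000), "exceed")
})

test_that("mixed-model day means equal raw means under perfect balance", {
  d <- design_table(study_design(boars = 5, ejaculates_per_boar = 2))
  set.seed(14)
  ej <- rnorm(10, 0, 0.5)
  names(ej) <- unique(d$ejaculate)
  d$y <- 1 + (d$day == "D11") * 0.5 + ej[d$ejaculate] + rnorm(nrow(d), 0, 0.3)
  mt <- fit_factorial_mixed_models(d, "y")
  raw <- tapply(d$y, d$day, mean)
  expect_equal(mt$mean_day1, unname(raw["D0"]), tolerance = 1e-6)
  expect_equal(mt$mean_day2, unname(raw["D11"]), tolerance = 1e-6)
  expect_true(all(c(mt$sem_day1, mt$sem_day2) > 0))
  expect_true(all(mt[, c("p_day", "p_boar", "p_day_boar")] >= 0 &
                    mt[, c("p_day", "p_boar", "p_day_boar")] <= 1))
})

test_that("a strong injected day shift is detected with high power", {
  d <- design_table(study_design(boars = 12, ejaculates_per_boar = 2))
  set.seed(15)
  ej <- rnorm(length(unique(d$ejaculate)), 0, 0.5)
  names(ej) <- unique(d$ejaculate)
  d$y <- (d$day == "D11") * 2 + ej[d$ejaculate] + rnorm(nrow(d))
  mt <- fit_factorial_mixed_models(d, "y")
  expect_lt(mt$p_day, 0.001)
  expect_equal(mt$model, "mixed")
})
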