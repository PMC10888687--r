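#' Pearson correlation matrix with FDR masking
#'
#' Pairwise Pearson correlations with Benjamini-Hochberg adjustment of the
#' upper-triangle p-values; cells with adjusted p above `alpha` are masked.
#' Constant variables are masked with a flag rather than failing.
#'
#' @param table data frame with the variables (plus any identifier columns,
#'   ignored when `variables` is given).
#' @param variables character vector of variable names; default all numeric
#'   columns.
#' @param alpha significance level for the mask (default 0.05).
#' @return object of class `chrom_corr`: matrices `r`, `p_raw`, `p_adjusted`,
#'   logical `significant`, character `flagged` (constant variables), `alpha`.
#' @export
correlation_matrix <- function(table, variables = NULL, alpha = 0.05) {
  if (is.null(variables))
    variables <- names(table)[vapply(table, is.numeric, logical(1))]
  x <- as.data.frame(table[, variables])
  p <- length(variables)
  const <- vapply(x, function(v) stats::sd(v, na.rm = TRUE) == 0, logical(1))
  r <- praw <- matrix(NA_real_, p, p, dimnames = list(variables, variables))
  diag(r) <- 1
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (const[i] || const[j]) next
    ok <- stats::complete.cases(x[[i]], x[[j]])
    if (sum(ok) < 3) next
    ct <- stats::cor.test(x[[i]][ok], x[[j]][ok], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    praw[i, j] <- praw[j, i] <- ct$p.value
  }
  upper <- upper.tri(praw)
  padj <- praw
  padj[upper] <- stats::p.adjust(praw[upper], method = "BH")
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  sig <- !is.na(padj) & padj <= alpha
  diag(sig) <- FALSE
  structure(list(r = r, p_raw = praw, p_adjusted = padj, significant = sig,
                 flagged = variables[const], alpha = alpha),
            class = "chrom_corr")
}

#' Variable clustering on Hoeffding's D
#'
#' Builds the pairwise scaled Hoeffding-D similarity matrix, converts it to
#' a distance (1 - D, i.e. maximum scale minus similarity) and agglomerates
#' with average linkage. Undefined pairwise D values propagate as missing
#' with a flag.
#'
#' @inheritParams correlation_matrix
#' @return object of class `chrom_varclust`: `similarity` (scaled D matrix),
#'   `hclust` (the tree), `flagged`.
#' @export
cluster_variables <- function(table, variables = NULL) {
  if (is.null(variables))
    variables <- names(table)[vapply(table, is.numeric, logical(1))]
  if (length(variables) < 2) stop("need at least 2 variables")
  sim <- hoeffding_d_matrix(table[, variables])
  flagged <- variables[apply(is.na(sim), 1, any)]
  if (length(flagged))
    warning("undefined Hoeffding D for: ", paste(flagged, collapse = ", "))
  d <- 1 - sim
  d[d < 0] <- 0            # sampling noise can push D slightly above 1
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  structure(list(similarity = sim, hclust = hc, flagged = flagged),
            class = "chrom_varclust")
}

#' Contribution of a variable to a principal component
#'
#' In a standardized PCA the loading of a variable on a component is its
#' correlation with the component, and the variable's contribution to that
#' component is `100 * loading^2 / eigenvalue` (per cent of the component's
#' variance). For a component explaining a share `s` of `p` standardized
#' variables the eigenvalue is `p * s`.
#'
#' @param loading variable-component correlation in `[-1, 1]`.
#' @param eigenvalue component eigenvalue (> 0).
#' @return contribution in per cent.
#' @examples
#' pca_contribution(0.910, 13 * 0.317)  # ~20.1
#' @export
pca_contribution <- function(loading, eigenvalue) {
  stopifnot(eigenvalue > 0, all(abs(loading) <= 1 + 1e-8))
  100 * loading^2 / eigenvalue
}

#' Standardized principal component analysis with contributions
#'
#' Eigen-decomposition of the correlation matrix of the complete cases.
#' Loadings are the variable-component correlations, contributions the
#' percentage importance of each variable for each component
#' (`100 * loading^2 / eigenvalue`), and scores the projections of the
#' standardized observations. PCA signs being arbitrary, each component is
#' oriented so that its largest-|loading| variable loads positively.
#'
#' @inheritParams correlation_matrix
#' @return object of class `chrom_pca`: `eigenvalues`, `prop_variance`,
#'   `loadings`, `contributions`, `scores`, `complete_cases` (row index
#'   used), `variables`.
#' @export
principal_components <- function(table, variables = NULL) {
  if (is.null(variables))
    variables <- names(table)[vapply(table, is.numeric, logical(1))]
  x <- as.data.frame(table[, variables])
  cc <- stats::complete.cases(x)
  x <- as.matrix(x[cc, ])
  p <- length(variables)
  if (nrow(x) < p + 1)
    stop("singular input: need at least variables + 1 complete observations")
  if (any(apply(x, 2, stats::sd) == 0))
    stop("constant variable cannot be standardized")
  rmat <- stats::cor(x)
  eig <- eigen(rmat, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  v <- eig$vectors
  loadings <- v %*% diag(sqrt(lambda), p)
  # orient: largest-|loading| variable positive on each component
  for (j in seq_len(p)) {
    i_star <- which.max(abs(loadings[, j]))
    if (loadings[i_star, j] < 0) {
      loadings[, j] <- -loadings[, j]
      v[, j] <- -v[, j]
    }
  }
  scores <- scale(x) %*% v
  contributions <- 100 * v^2
  dn <- list(variables, paste0("PC", seq_len(p)))
  dimnames(loadings) <- dimnames(contributions) <- dn
  colnames(scores) <- dn[[2]]
  structure(list(eigenvalues = stats::setNames(lambda, dn[[2]]),
                 prop_variance = stats::setNames(lambda / sum(lambda), dn[[2]]),
                 loadings = loadings, contributions = contributions,
                 scores = scores, complete_cases = which(cc),
                 variables = variables),
            class = "chrom_pca")
}

#' Hierarchical clustering of observations on PC scores
#'
#' Ward clustering of the observation scores on the first `n_pcs`
#' components, cut at `k` clusters.
#'
#' @param pca a [principal_components()] fit.
#' @param n_pcs number of leading components to use (default 2).
#' @param k number of clusters (default 2).
#' @return integer cluster labels, one per observation used in the PCA.
#' @export
cluster_observations_on_pcs <- function(pca, n_pcs = 2, k = 2) {
  stopifnot(inherits(pca, "chrom_pca"))
  sc <- pca$scores[, seq_len(n_pcs), drop = FALSE]
  if (k > nrow(sc)) stop("k cannot exceed the number of observations")
  hc <- stats::hclust(stats::dist(sc), method = "ward.D2")
  stats::cutree(hc, k)
}

#' Factorial linear mixed-effects models per variable
#'
#' For each response fits `value ~ day * boar + (1 | ejaculate)` by REML
#' (ejaculates are coded nested within boar), with storage day and boar as
#' fixed factors, and reports the estimated marginal day means with their
#' SEMs and the type-III Satterthwaite p-values for day, boar and their
#' interaction. Under perfect balance the estimated day means equal the raw
#' day means. A singular or failing mixed fit falls back to the
#' fixed-effects linear model with a flag.
#'
#' @param table data frame with `day`, `boar`, `ejaculate` columns and the
#'   response variables.
#' @param variables character vector of response names.
#' @return tibble with one row per variable: day means and SEMs, the three
#'   p-values, and the model type (`"mixed"` or `"fixed"`).
#' @export
fit_factorial_mixed_models <- function(table, variables) {
  stopifnot(all(c("day", "boar", "ejaculate") %in% names(table)),
            all(variables %in% names(table)))
  df <- as.data.frame(table)
  df$day <- factor(df$day)
  df$boar <- factor(df$boar)
  df$ejaculate <- factor(df$ejaculate)
  if (nlevels(df$day) < 2 || nlevels(df$boar) < 2)
    stop("need at least 2 days and 2 boars")
  purrr::map_dfr(variables, function(v) {
    d <- df[!is.na(df[[v]]), ]
    d$.y <- d[[v]]
    fit <- tryCatch(
      lmerTest::lmer(.y ~ day * boar + (1 | ejaculate), data = d, REML = TRUE,
                     control = lme4::lmerControl(check.conv.singular =
                                                   lme4::.makeCC("ignore", tol = 1e-4))),
      error = function(e) NULL)
    singular <- is.null(fit) || lme4::isSingular(fit, tol = 1e-4)
    if (!singular) {
      an <- stats::anova(fit, type = 3)
      pv <- stats::setNames(an[["Pr(>F)"]], rownames(an))
      emm <- summary(suppressMessages(
        emmeans::emmeans(fit, "day", lmer.df = "satterthwaite")))
      model <- "mixed"
    } else {
      lfit <- stats::lm(.y ~ day * boar, data = d,
                        contrasts = list(day = "contr.sum",
                                         boar = "contr.sum"))
      an <- car::Anova(lfit, type = 3)
      pv <- stats::setNames(an[["Pr(>F)"]], rownames(an))
      emm <- summary(suppressMessages(emmeans::emmeans(lfit, "day")))
      model <- "fixed"
    }
    days <- as.character(emm$day)
    tibble::tibble(
      variable = v,
      mean_day1 = emm$emmean[1], sem_day1 = emm$SE[1],
      mean_day2 = emm$emmean[2], sem_day2 = emm$SE[2],
      day_levels = paste(days, collapse = "/"),
      p_day = pv[["day"]], p_boar = pv[["boar"]],
      p_day_boar = pv[["day:boar"]],
      model = model)
  })
}
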