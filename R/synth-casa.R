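#' Kinematic component table for the CASA generator
#'
#' Components are parameterized so that the velocity ordering
#' VSL <= VAP <= VCL holds for every sampled cell by construction: VCL is
#' log-normal and the ratios WOB = VAP/VCL and STR = VSL/VAP are Beta
#' distributed on (0, 1) (mean/concentration parameterization; an infinite
#' concentration gives a degenerate, exact ratio). ALH and BCF are
#' log-normal. Defaults describe the three canonical boar subpopulations --
#' Slow, Fast and Hyper (fast, non-linear, hyperactivated-like) -- centred on
#' their published median kinematics.
#'
#' @param name,weight component labels and mixture weights (sum to 1).
#' @param vcl_med,vcl_sdlog median (um/s) and log-SD of curvilinear velocity.
#' @param wob_mean,str_mean mean VAP/VCL and VSL/VAP ratios, in (0, 1].
#' @param kappa Beta concentration for both ratios (Inf = degenerate).
#' @param alh_med,alh_sdlog,bcf_med,bcf_sdlog ALH (um) and BCF (Hz) medians
#'   and log-SDs.
#' @return tibble of class `casa_components`.
#' @export
casa_components <- function(name = c("Slow", "Fast", "Hyper"),
                            weight = c(0.299, 0.518, 0.183),
                            vcl_med = c(50.1, 117.3, 113.5),
                            vcl_sdlog = c(0.35, 0.30, 0.30),
                            wob_mean = c(0.547, 0.578, 0.455),
                            str_mean = c(0.526, 0.509, 0.176),
                            kappa = c(80, 80, 80),
                            alh_med = c(1.4, 2.6, 2.9),
                            alh_sdlog = c(0.25, 0.30, 0.30),
                            bcf_med = c(9, 20, 13),
                            bcf_sdlog = c(0.30, 0.25, 0.30)) {
  comp <- tibble::tibble(name, weight, vcl_med, vcl_sdlog, wob_mean,
                         str_mean, kappa, alh_med, alh_sdlog, bcf_med,
                         bcf_sdlog)
  if (abs(sum(comp$weight) - 1) > 1e-8) stop("component weights must sum to 1")
  if (any(comp$wob_mean <= 0 | comp$wob_mean > 1 |
          comp$str_mean <= 0 | comp$str_mean > 1))
    stop("ratio means must lie in (0, 1]: component means must satisfy VSL <= VAP <= VCL")
  if (any(comp$vcl_med <= 0 | comp$alh_med <= 0 | comp$bcf_med <= 0))
    stop("kinematic medians must be positive")
  class(comp) <- c("casa_components", class(comp))
  comp
}

.rbeta_mean <- function(n, mean, kappa) {
  if (is.infinite(kappa)) return(rep(mean, n))
  if (mean >= 1) return(rep(1, n))
  stats::rbeta(n, mean * kappa, (1 - mean) * kappa)
}

.rlnorm_med <- function(n, med, sdlog) {
  if (sdlog == 0) rep(med, n) else stats::rlnorm(n, log(med), sdlog)
}

#' Simulate one CASA sample from a kinematic mixture
#'
#' Draws per-cell component membership and raw kinematics, then recomputes
#' every derived ratio from the sampled velocities through
#' [derive_kinematics()] so that LIN = 100*VSL/VCL etc. hold exactly.
#' Latent component labels are kept in `.component`.
#'
#' @param components a [casa_components()] table.
#' @param n number of cells.
#' @param seed integer seed; same seed, same table.
#' @return tibble with `vcl`, `vsl`, `vap`, `lin`, `str`, `wob`, `alh`,
#'   `bcf`, `dnc`, `dncm`, `.component`.
#' @export
simulate_casa_sample <- function(components, n, seed = NULL) {
  stopifnot(inherits(components, "casa_components"), n >= 1)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  k <- nrow(components)
  idx <- sample.int(k, n, replace = TRUE, prob = components$weight)
  vcl <- vsl <- vap <- alh <- bcf <- numeric(n)
  for (j in seq_len(k)) {
    sel <- idx == j
    m <- sum(sel)
    if (!m) next
    co <- components[j, ]
    v <- .rlnorm_med(m, co$vcl_med, co$vcl_sdlog)
    wob <- .rbeta_mean(m, co$wob_mean, co$kappa)
    str <- .rbeta_mean(m, co$str_mean, co$kappa)
    vcl[sel] <- v
    vap[sel] <- wob * v
    vsl[sel] <- str * wob * v
    alh[sel] <- .rlnorm_med(m, co$alh_med, co$alh_sdlog)
    bcf[sel] <- .rlnorm_med(m, co$bcf_med, co$bcf_sdlog)
  }
  out <- derive_kinematics(vcl, vsl, vap, alh, bcf)
  out$.component <- components$name[idx]
  out
}

#' Default motile + immotile component table for a realized CASA truth
#'
#' Combines the three motile subpopulations with an immotile component
#' (near-zero velocities) using the realized motile fraction and
#' subpopulation weight shifts.
#'
#' @param params realized parameter vector from the `CASA` [assay_truth()]
#'   (`motile`, `w_slow`, `w_hyper`).
#' @return a [casa_components()] table with four components.
#' @export
casa_components_realized <- function(params) {
  mot <- params[["motile"]]
  w_slow <- params[["w_slow"]]; w_hyper <- params[["w_hyper"]]
  if (w_slow + w_hyper > 0.98) {
    tot <- w_slow + w_hyper
    w_slow <- 0.98 * w_slow / tot
    w_hyper <- 0.98 * w_hyper / tot
  }
  w_fast <- 1 - w_slow - w_hyper
  casa_components(
    name = c("Slow", "Fast", "Hyper", "Immotile"),
    weight = c(mot * w_slow, mot * w_fast, mot * w_hyper, 1 - mot),
    vcl_med = c(50.1, 117.3, 113.5, 3),
    vcl_sdlog = c(0.35, 0.30, 0.30, 0.50),
    wob_mean = c(0.547, 0.578, 0.455, 0.5),
    str_mean = c(0.526, 0.509, 0.176, 0.5),
    kappa = c(80, 80, 80, 10),
    alh_med = c(1.4, 2.6, 2.9, 0.3),
    alh_sdlog = c(0.25, 0.30, 0.30, 0.40),
    bcf_med = c(9, 20, 13, 2),
    bcf_sdlog = c(0.30, 0.25, 0.30, 0.50))
}
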