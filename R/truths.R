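#' Assay ground-truth specification
#'
#' An `assay_truth` bundles, for one assay, the baseline (day-0) values of
#' its tunable truth parameters, the scale on which boar/ejaculate random
#' effects and the storage-day shift act (`"logit"` for proportions, `"log"`
#' for locations and positive indices), the effect sizes, and the structural
#' constants of the emission model (component locations/spreads, gate and
#' split cuts, reference medians). Baselines and day shifts default to values
#' that reproduce the direction and rough magnitude of the published day-0 /
#' day-11 contrasts for each variable.
#'
#' @param assay one of `"SCSA"`, `"MBBR"`, `"CMA3"`, `"OXODG"`, `"PHYS1"`,
#'   `"PHYS2"`, `"CASA"`.
#' @param base named numeric vector of baseline parameter values on the
#'   natural scale (proportions in `[0,1]`, locations > 0).
#' @param scale named character vector (`"logit"` or `"log"`), same names.
#' @param day_shift named numeric, additive shift on the transformed scale
#'   applied on the second analysis day.
#' @param boar_sd,ejaculate_sd named numeric SDs of Gaussian random
#'   intercepts on the transformed scale (boar, and ejaculate nested in boar).
#' @param structure list of structural constants for the emission model.
#' @return an object of class `assay_truth`.
#' @export
assay_truth <- function(assay, base, scale, day_shift, boar_sd, ejaculate_sd,
                        structure = list()) {
  assay <- match.arg(assay,
                     c("SCSA", "MBBR", "CMA3", "OXODG", "PHYS1", "PHYS2", "CASA"))
  nm <- names(base)
  stopifnot(!is.null(nm), identical(nm, names(scale)),
            identical(nm, names(day_shift)), identical(nm, names(boar_sd)),
            identical(nm, names(ejaculate_sd)))
  prop <- scale == "logit"
  if (any(base[prop] < 0 | base[prop] > 1))
    stop("proportion parameters must lie in [0, 1]")
  if (any(base[scale == "log"] <= 0))
    stop("log-scale parameters (locations, scales) must be positive")
  if (any(c(boar_sd, ejaculate_sd) < 0)) stop("effect SDs must be >= 0")
  structure(list(assay = assay, base = base, scale = scale,
                 day_shift = day_shift, boar_sd = boar_sd,
                 ejaculate_sd = ejaculate_sd, structure = structure),
            class = "assay_truth")
}

.fwd <- function(x, scale) {
  out <- x
  out[scale == "logit"] <- stats::qlogis(x[scale == "logit"])
  out[scale != "logit"] <- log(x[scale != "logit"])
  out
}

.bwd <- function(z, scale) {
  out <- z
  out[scale == "logit"] <- stats::plogis(z[scale == "logit"])
  out[scale != "logit"] <- exp(z[scale != "logit"])
  out
}

#' Realize per-sample truth parameters
#'
#' Applies boar and ejaculate random intercepts and the storage-day shift on
#' the transformed scale and maps back to the natural scale.
#'
#' @param truth an [assay_truth()].
#' @param boar_effect,ejaculate_effect named numeric vectors (zero vector for
#'   the population baseline); names must match `truth$base`.
#' @param day_index 0 for the first analysis day, 1 for the second.
#' @return named numeric vector of realized parameter values.
#' @export
realize_truth <- function(truth, boar_effect = NULL, ejaculate_effect = NULL,
                          day_index = 0) {
  nm <- names(truth$base)
  if (is.null(boar_effect)) boar_effect <- stats::setNames(numeric(length(nm)), nm)
  if (is.null(ejaculate_effect))
    ejaculate_effect <- stats::setNames(numeric(length(nm)), nm)
  z <- .fwd(truth$base, truth$scale) + boar_effect[nm] + ejaculate_effect[nm] +
    day_index * truth$day_shift
  stats::setNames(.bwd(z, truth$scale), nm)
}

#' Default assay truths for the emulated boar study
#'
#' Returns one [assay_truth()] per assay with baselines and day shifts chosen
#' to reproduce the direction (and approximate size) of the published
#' storage contrasts: a small increase in DNA fragmentation and 8-oxo-dG, a
#' strong redistribution of the mBBr population towards low fluorescence with
#' rising mBBr MFI and falling disulfide index, a mild CMA3 shift, slightly
#' reduced viability/mitochondrial activity and increased ROS, and slower,
#' less motile cells after storage.
#'
#' @return named list of `assay_truth` objects.
#' @export
default_truths <- function() {
  list(
    SCSA = assay_truth(
      "SCSA",
      base = c(p_frag = 0.0112, p_hds = 0.0431),
      scale = c(p_frag = "logit", p_hds = "logit"),
      day_shift = c(p_frag = 0.234, p_hds = 0.101),
      boar_sd = c(p_frag = 0.25, p_hds = 0.25),
      ejaculate_sd = c(p_frag = 0.08, p_hds = 0.08),
      structure = list(
        debris = 0.10,
        # state x channel log-normal emission (channel units, 10-bit scale)
        green = list(debris = c(log(5), 0.40), main = c(log(180), 0.15),
                     frag = c(log(100), 0.15), hds = c(log(850), 0.07)),
        red = list(debris = c(log(5), 0.40), main = c(log(20), 0.20),
                   frag = c(log(110), 0.20), hds = c(log(90), 0.20)),
        gate_cut = 30)),
    MBBR = assay_truth(
      "MBBR",
      base = c(w_low = 0.069, w_high = 0.048, loc = 1, disulfide = 33.28),
      scale = c(w_low = "logit", w_high = "logit", loc = "log",
                disulfide = "log"),
      day_shift = c(w_low = 1.95, w_high = -1.37, loc = 0.215,
                    disulfide = -0.446),
      boar_sd = c(w_low = 0.30, w_high = 0.30, loc = 0.05, disulfide = 0.08),
      ejaculate_sd = c(w_low = 0.10, w_high = 0.10, loc = 0.02,
                       disulfide = 0.03),
      structure = list(debris = 0.08, locations = c(low = 60, moderate = 220,
                                                    high = 700),
                       sdlog = c(low = 0.18, moderate = 0.18, high = 0.15),
                       nuclear = c(log(300), 0.20), gate_cut = 30,
                       bounds = c(120, 450), reference_mfi = 210)),
    CMA3 = assay_truth(
      "CMA3",
      base = c(w_low = 0.061, w_high = 0.0645, loc = 1),
      scale = c(w_low = "logit", w_high = "logit", loc = "log"),
      day_shift = c(w_low = -0.076, w_high = 0.162, loc = 0.0147),
      boar_sd = c(w_low = 0.06, w_high = 0.06, loc = 0.015),
      ejaculate_sd = c(w_low = 0.08, w_high = 0.08, loc = 0.01),
      structure = list(debris = 0.07, locations = c(low = 80, moderate = 300,
                                                    high = 800),
                       sdlog = c(low = 0.18, moderate = 0.18, high = 0.15),
                       nuclear = c(log(350), 0.20), gate_cut = 30,
                       bounds = c(150, 550), reference_mfi = 277)),
    OXODG = assay_truth(
      "OXODG",
      base = c(p_high = 0.07, loc = 1),
      scale = c(p_high = "logit", loc = "log"),
      day_shift = c(p_high = 0.20, loc = 0.0975),
      boar_sd = c(p_high = 0.20, loc = 0.10),
      ejaculate_sd = c(p_high = 0.08, loc = 0.03),
      structure = list(debris = 0.06, locations = c(main = 170, high = 600),
                       sdlog = c(main = 0.20, high = 0.18),
                       nuclear = c(log(350), 0.20), gate_cut = 30,
                       high_cut = 380, reference_mfi = 68)),
    PHYS1 = assay_truth(
      "PHYS1",
      base = c(viable = 0.90, apoptotic = 0.08, capacitated = 0.15,
               acrosome = 0.04),
      scale = c(viable = "logit", apoptotic = "logit", capacitated = "logit",
                acrosome = "logit"),
      day_shift = c(viable = -0.205, apoptotic = 0.10, capacitated = 0.15,
                    acrosome = 0.10),
      boar_sd = c(viable = 0.20, apoptotic = 0.20, capacitated = 0.20,
                  acrosome = 0.20),
      ejaculate_sd = c(viable = 0.08, apoptotic = 0.08, capacitated = 0.08,
                       acrosome = 0.08),
      structure = list(debris = 0.07,
                       dead_m540 = 0.60, dead_pna = 0.55,
                       apo_m540 = 0.50, apo_pna = 0.30)),
    PHYS2 = assay_truth(
      "PHYS2",
      base = c(viable = 0.90, mito = 0.95, superoxide = 0.04, ros_loc = 60),
      scale = c(viable = "logit", mito = "logit", superoxide = "logit",
                ros_loc = "log"),
      day_shift = c(viable = -0.205, mito = -0.20, superoxide = 0.50,
                    ros_loc = 0.262),
      boar_sd = c(viable = 0.20, mito = 0.20, superoxide = 0.20,
                  ros_loc = 0.08),
      ejaculate_sd = c(viable = 0.08, mito = 0.08, superoxide = 0.08,
                       ros_loc = 0.03),
      structure = list(debris = 0.07, dead_mx = 0.30, dead_mtdr = 0.05,
                       ros_reference = 60)),
    CASA = assay_truth(
      "CASA",
      base = c(motile = 0.85, w_slow = 0.299, w_hyper = 0.183),
      scale = c(motile = "logit", w_slow = "logit", w_hyper = "logit"),
      day_shift = c(motile = -0.888, w_slow = 0.40, w_hyper = -0.20),
      boar_sd = c(motile = 0.30, w_slow = 0.15, w_hyper = 0.15),
      ejaculate_sd = c(motile = 0.10, w_slow = 0.08, w_hyper = 0.08),
      structure = list())
  )
}
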