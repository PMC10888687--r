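#' @title Synthetic cytometry event generators
#' @description Each assay's generator builds a latent-state log-normal
#'   mixture from realized truth parameters, draws per-cell events, and
#'   attaches the theoretical value of every downstream statistic as the
#'   sample's ground truth (attribute `truth`). See the methods vignette for
#'   the emission models.
#' @name synth-cytometry
NULL

# shared emission constants for the physiology panels (channel units):
# a stain classified "positive"/"negative" and the scatter/debris components
.EMIT <- list(pos = c(log(420), 0.35), neg = c(log(25), 0.35),
              fsc_sperm = c(log(400), 0.25), fsc_debris = c(log(30), 0.45),
              dim = c(log(10), 0.50), stain_cut = 110, fsc_cut = 130)

.emission_matrix <- function(spec) {
  # spec: named list state -> named list channel -> c(meanlog, sdlog)
  states <- names(spec)
  channels <- names(spec[[1]])
  ml <- matrix(NA_real_, length(states), length(channels),
               dimnames = list(states, channels))
  sl <- ml
  for (s in states) for (ch in channels) {
    ml[s, ch] <- spec[[s]][[ch]][1]
    sl[s, ch] <- spec[[s]][[ch]][2]
  }
  list(meanlog = ml, sdlog = sl)
}

# ---------------------------------------------------------------------------
# SCSA: acridine-orange red/green after acid denaturation

scsa_mixture <- function(params, structure) {
  p_frag <- params[["p_frag"]]; p_hds <- params[["p_hds"]]
  if (p_frag + p_hds > 1) stop("SCSA component fractions exceed 1")
  d <- structure$debris
  w <- c(debris = d, main = (1 - d) * (1 - p_frag - p_hds),
         frag = (1 - d) * p_frag, hds = (1 - d) * p_hds)
  spec <- lapply(c("debris", "main", "frag", "hds"), function(s)
    list(green = structure$green[[s]], red = structure$red[[s]]))
  names(spec) <- names(w)
  em <- .emission_matrix(spec)
  new_channel_mixture(w, em$meanlog, em$sdlog)
}

scsa_truth_stats <- function(mix, channel_max = 1023) {
  sperm <- setdiff(names(mix$weights), "debris")
  hds_cut <- 0.65 * channel_max
  c(pct_dfi = 100 * mixture_ratio_prob(mix, "red", "green", 0.25,
                                       states = sperm),
    pct_hds = 100 * mixture_conditional_prob(
      mix, list(channel = "green", cut = hds_cut, side = "gt"),
      states = sperm))
}

#' Simulate SCSA (acridine orange) events for one sample
#'
#' Generates a four-component mixture: the main population (high green, low
#' red), a fragmented tail whose per-cell DNA fragmentation index
#' (DFI = 1000 * red / (red + green)) lies above 250, a high-green
#' high-stainability (HDS) component above the fixed stainability cut, and
#' AO double-negative debris. Component memberships are kept in `.state`;
#' the theoretical %DFI and %HDS of the realized mixture are attached as
#' attribute `truth`.
#'
#' @param truth an [assay_truth()] for the SCSA assay.
#' @param n number of events (>= 1).
#' @param seed integer seed.
#' @param params optional realized parameter vector (from [realize_truth()]);
#'   defaults to the baseline parameters of `truth`.
#' @param channel_max full-scale channel value.
#' @return event tibble with channels `green`, `red`, latent `.state`, and
#'   attributes `truth`, `assay`, `clipped_fraction`.
#' @export
simulate_scsa_events <- function(truth, n, seed = NULL, params = NULL,
                                 channel_max = 1023) {
  stopifnot(inherits(truth, "assay_truth"), truth$assay == "SCSA", n >= 1)
  if (is.null(params)) params <- realize_truth(truth)
  mix <- scsa_mixture(params, truth$structure)
  ev <- r_channel_mixture(mix, n, channel_max, seed)
  attr(ev, "truth") <- scsa_truth_stats(mix, channel_max)
  attr(ev, "assay") <- "SCSA"
  ev
}

# ---------------------------------------------------------------------------
# three-band stain assays (mBBr untreated split, CMA3): nuclear stain +
# low/moderate/high signal components

.band_mixture <- function(w_low, w_high, loc_mult, structure, signal_name) {
  if (w_low + w_high > 0.98) {           # keep a real moderate band
    tot <- w_low + w_high
    w_low <- 0.98 * w_low / tot
    w_high <- 0.98 * w_high / tot
  }
  d <- structure$debris
  w <- c(debris = d, low = (1 - d) * w_low,
         moderate = (1 - d) * (1 - w_low - w_high), high = (1 - d) * w_high)
  loc <- structure$locations * loc_mult
  sd <- structure$sdlog
  spec <- list(
    debris = stats::setNames(list(c(log(5), 0.40), c(log(8), 0.50)),
                             c("nuclear", signal_name)),
    low = stats::setNames(list(structure$nuclear, c(log(loc[["low"]]), sd[["low"]])),
                          c("nuclear", signal_name)),
    moderate = stats::setNames(list(structure$nuclear,
                                    c(log(loc[["moderate"]]), sd[["moderate"]])),
                               c("nuclear", signal_name)),
    high = stats::setNames(list(structure$nuclear,
                                c(log(loc[["high"]]), sd[["high"]])),
                           c("nuclear", signal_name)))
  em <- .emission_matrix(spec)
  new_channel_mixture(w, em$meanlog, em$sdlog)
}

.band_truth_stats <- function(mix, signal, bounds, reference_mfi) {
  sperm <- setdiff(names(mix$weights), "debris")
  p_low <- mixture_conditional_prob(
    mix, list(channel = signal, cut = bounds[1], side = "le"), states = sperm)
  p_high <- mixture_conditional_prob(
    mix, list(channel = signal, cut = bounds[2], side = "gt"), states = sperm)
  med <- mixture_median(mix, signal, states = sperm)
  c(low = 100 * p_low, moderate = 100 * (1 - p_low - p_high),
    high = 100 * p_high, mfi_norm = med / reference_mfi, median_raw = med)
}

#' Simulate a paired monobromobimane (mBBr) untreated/DTT sample
#'
#' The untreated split is a three-band (low/moderate/high thiol) mixture plus
#' debris; the DTT-reduced reference split is the same mixture with all
#' signal locations scaled so that its theoretical median exceeds the
#' untreated one by exactly twice the realized disulfide index
#' (index = (median_dtt - median_untreated) / 2 on the raw channel scale).
#'
#' @inheritParams simulate_scsa_events
#' @return list with elements `untreated` and `dtt` (event tibbles with
#'   channels `nuclear`, `mbbr`); attribute `truth` on the list carries the
#'   theoretical fractions, normalized MFI, raw medians and disulfide index.
#' @export
simulate_stain_pair_mbbr <- function(truth, n, seed = NULL, params = NULL,
                                     channel_max = 1023) {
  stopifnot(inherits(truth, "assay_truth"), truth$assay == "MBBR", n >= 1)
  if (is.null(params)) params <- realize_truth(truth)
  st <- truth$structure
  if (any(st$sdlog <= 0)) stop("component sdlog must be positive")
  mix_u <- .band_mixture(params[["w_low"]], params[["w_high"]],
                         params[["loc"]], st, "mbbr")
  tr <- .band_truth_stats(mix_u, "mbbr", st$bounds, st$reference_mfi)
  med_u <- tr[["median_raw"]]
  ds <- params[["disulfide"]]
  mix_d <- mix_u
  mix_d$meanlog[, "mbbr"] <- mix_d$meanlog[, "mbbr"] +
    log((med_u + 2 * ds) / med_u)
  # debris signal location kept as in the untreated split
  mix_d$meanlog["debris", "mbbr"] <- mix_u$meanlog["debris", "mbbr"]
  seed2 <- if (is.null(seed)) NULL else seed + 1L
  untreated <- r_channel_mixture(mix_u, n, channel_max, seed)
  dtt <- r_channel_mixture(mix_d, n, channel_max, seed2)
  attr(untreated, "assay") <- "MBBR_UNTREATED"
  attr(dtt, "assay") <- "MBBR_DTT"
  out <- list(untreated = untreated, dtt = dtt)
  attr(out, "truth") <- c(
    mbbr_low = tr[["low"]], mbbr_moderate = tr[["moderate"]],
    mbbr_high = tr[["high"]], mbbr_mfi = tr[["mfi_norm"]],
    disulfide = ds, median_untreated = med_u, median_dtt = med_u + 2 * ds)
  out
}

#' Simulate chromomycin A3 (CMA3) events for one sample
#'
#' Three-band protamination mixture (low/moderate/high CMA3) plus debris on
#' an H342 nuclear-stain channel.
#'
#' @inheritParams simulate_scsa_events
#' @return event tibble with channels `nuclear`, `cma3` and attribute
#'   `truth` (theoretical low/moderate/high fractions and normalized MFI).
#' @export
simulate_cma3_events <- function(truth, n, seed = NULL, params = NULL,
                                 channel_max = 1023) {
  stopifnot(inherits(truth, "assay_truth"), truth$assay == "CMA3", n >= 1)
  if (is.null(params)) params <- realize_truth(truth)
  st <- truth$structure
  mix <- .band_mixture(params[["w_low"]], params[["w_high"]],
                       params[["loc"]], st, "cma3")
  tr <- .band_truth_stats(mix, "cma3", st$bounds, st$reference_mfi)
  ev <- r_channel_mixture(mix, n, channel_max, seed)
  attr(ev, "truth") <- c(cma3_low = tr[["low"]],
                         cma3_moderate = tr[["moderate"]],
                         cma3_high = tr[["high"]], cma3_mfi = tr[["mfi_norm"]])
  attr(ev, "assay") <- "CMA3"
  ev
}

#' Simulate 8-oxo-dG immunodetection events for one sample
#'
#' Main population plus a high-FITC oxidized component and debris on an H342
#' nuclear channel. The day shift acts on both the FITC location (MFI) and
#' the high-FITC fraction.
#'
#' @inheritParams simulate_scsa_events
#' @return event tibble with channels `nuclear`, `fitc` and attribute
#'   `truth` (`oxodg_high` percentage and `oxodg_mfi` normalized median).
#' @export
simulate_oxodg_events <- function(truth, n, seed = NULL, params = NULL,
                                  channel_max = 1023) {
  stopifnot(inherits(truth, "assay_truth"), truth$assay == "OXODG", n >= 1)
  if (is.null(params)) params <- realize_truth(truth)
  st <- truth$structure
  d <- st$debris
  p_high <- params[["p_high"]]
  w <- c(debris = d, main = (1 - d) * (1 - p_high), high = (1 - d) * p_high)
  loc <- st$locations * params[["loc"]]
  spec <- list(
    debris = list(nuclear = c(log(5), 0.40), fitc = c(log(6), 0.50)),
    main = list(nuclear = st$nuclear, fitc = c(log(loc[["main"]]),
                                               st$sdlog[["main"]])),
    high = list(nuclear = st$nuclear, fitc = c(log(loc[["high"]]),
                                               st$sdlog[["high"]])))
  em <- .emission_matrix(spec)
  mix <- new_channel_mixture(w, em$meanlog, em$sdlog)
  sperm <- c("main", "high")
  truth_stats <- c(
    oxodg_high = 100 * mixture_conditional_prob(
      mix, list(channel = "fitc", cut = st$high_cut, side = "gt"),
      states = sperm),
    oxodg_mfi = mixture_median(mix, "fitc", states = sperm) / st$reference_mfi)
  ev <- r_channel_mixture(mix, n, channel_max, seed)
  attr(ev, "truth") <- truth_stats
  attr(ev, "assay") <- "OXODG"
  ev
}

# ---------------------------------------------------------------------------
# physiology panels: latent cell states with stochastic stain positivity,
# expanded into a full joint-state mixture so conditionals stay closed form

.expand_states <- function(class_weights, flag_probs, channels_fixed) {
  # class_weights: named numeric; flag_probs: list class -> named prob of
  # positivity per flag channel; channels_fixed: list class -> named list of
  # channel emissions shared by all flag combinations of that class
  states <- list()
  for (cl in names(class_weights)) {
    flags <- names(flag_probs[[cl]])
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(flags)))
    names(combos) <- flags
    for (i in seq_len(nrow(combos))) {
      on <- unlist(combos[i, , drop = FALSE])
      p <- prod(ifelse(on, flag_probs[[cl]], 1 - flag_probs[[cl]]))
      if (p <= 0) next
      em <- channels_fixed[[cl]]
      for (f in flags) em[[f]] <- if (on[[f]]) .EMIT$pos else .EMIT$neg
      nm <- paste0(cl, if (length(flags))
        paste0("_", paste0(substr(flags, 1, 2), as.integer(on), collapse = "")))
      states[[nm]] <- list(weight = class_weights[[cl]] * p, emission = em)
    }
  }
  states
}

.states_to_mixture <- function(states) {
  w <- vapply(states, `[[`, numeric(1), "weight")
  w <- w / sum(w)
  em <- .emission_matrix(lapply(states, `[[`, "emission"))
  new_channel_mixture(w, em$meanlog, em$sdlog)
}

phys1_mixture <- function(params, structure) {
  v <- params[["viable"]]; a <- params[["apoptotic"]]
  cls <- c(debris = structure$debris,
           dead = (1 - structure$debris) * (1 - v),
           apo = (1 - structure$debris) * v * a,
           via = (1 - structure$debris) * v * (1 - a))
  flag_probs <- list(
    debris = c(m540 = 0, pna = 0),
    dead = c(m540 = structure$dead_m540, pna = structure$dead_pna),
    apo = c(m540 = structure$apo_m540, pna = structure$apo_pna),
    via = c(m540 = params[["capacitated"]], pna = params[["acrosome"]]))
  fixed <- list(
    debris = list(fsc = .EMIT$fsc_debris, pi = .EMIT$dim, yp = .EMIT$dim),
    dead = list(fsc = .EMIT$fsc_sperm, pi = .EMIT$pos, yp = .EMIT$pos),
    apo = list(fsc = .EMIT$fsc_sperm, pi = .EMIT$neg, yp = .EMIT$pos),
    via = list(fsc = .EMIT$fsc_sperm, pi = .EMIT$neg, yp = .EMIT$neg))
  .states_to_mixture(.expand_states(cls, flag_probs, fixed))
}

phys1_truth_stats <- function(mix) {
  cut <- .EMIT$stain_cut
  gate <- list(list(channel = "fsc", cut = .EMIT$fsc_cut, side = "gt"))
  gt <- function(ch) list(channel = ch, cut = cut, side = "gt")
  le <- function(ch) list(channel = ch, cut = cut, side = "le")
  c(pct_viable = 100 * mixture_conditional_prob(mix, le("pi"), gate),
    pct_apoptotic_of_viable = 100 * mixture_conditional_prob(
      mix, gt("yp"), c(gate, list(le("pi")))),
    pct_acrosome_damaged_total = 100 * mixture_conditional_prob(
      mix, gt("pna"), gate),
    pct_acrosome_damaged_of_nonapoptotic = 100 * mixture_conditional_prob(
      mix, gt("pna"), c(gate, list(le("yp")))),
    pct_capacitated_of_nonapoptotic = 100 * mixture_conditional_prob(
      mix, gt("m540"), c(gate, list(le("yp")))))
}

phys2_mixture <- function(params, structure) {
  v <- params[["viable"]]
  ros <- params[["ros_loc"]]
  cls <- c(debris = structure$debris,
           dead = (1 - structure$debris) * (1 - v),
           via = (1 - structure$debris) * v)
  flag_probs <- list(
    debris = c(mx = 0, mtdr = 0),
    dead = c(mx = structure$dead_mx, mtdr = structure$dead_mtdr),
    via = c(mx = params[["superoxide"]], mtdr = params[["mito"]]))
  fixed <- list(
    debris = list(fsc = .EMIT$fsc_debris, h258 = .EMIT$dim,
                  cfda = c(log(8), 0.5)),
    dead = list(fsc = .EMIT$fsc_sperm, h258 = .EMIT$pos,
                cfda = c(log(1.6 * ros), 0.40)),
    via = list(fsc = .EMIT$fsc_sperm, h258 = .EMIT$neg,
               cfda = c(log(ros), 0.30)))
  .states_to_mixture(.expand_states(cls, flag_probs, fixed))
}

phys2_truth_stats <- function(mix, ros_reference) {
  cut <- .EMIT$stain_cut
  gate <- list(list(channel = "fsc", cut = .EMIT$fsc_cut, side = "gt"))
  viable_cond <- c(gate, list(list(channel = "h258", cut = cut, side = "le")))
  c(pct_active_mitochondria = 100 * mixture_conditional_prob(
      mix, list(channel = "mtdr", cut = cut, side = "gt"), gate),
    pct_high_superoxide_of_viable = 100 * mixture_conditional_prob(
      mix, list(channel = "mx", cut = cut, side = "gt"), viable_cond),
    cytoplasmic_ros_mfi = mixture_median(mix, "cfda", viable_cond) /
      ros_reference)
}

#' Simulate the two sperm-physiology panels for one sample
#'
#' Panel 1 carries viability (PI), apoptosis (YO-PRO-1), capacitation
#' (M540) and acrosomal status (PNA) channels; panel 2 carries viability
#' (H258), cytoplasmic ROS (CFDA), mitochondrial superoxide (MX) and
#' mitochondrial activity (MTdr). Latent cell classes (debris, dead,
#' apoptotic, viable) emit each stain from a "positive" or "negative"
#' log-normal; the theoretical value of each conditional statistic is
#' attached as `truth`.
#'
#' @inheritParams simulate_scsa_events
#' @param truth_p1,truth_p2 [assay_truth()] objects for `PHYS1` and `PHYS2`.
#' @param params_p1,params_p2 optional realized parameter vectors.
#' @return list with event tibbles `panel1`, `panel2` and a combined
#'   attribute `truth`.
#' @export
simulate_phys_panels <- function(truth_p1, truth_p2, n, seed = NULL,
                                 params_p1 = NULL, params_p2 = NULL,
                                 channel_max = 1023) {
  stopifnot(truth_p1$assay == "PHYS1", truth_p2$assay == "PHYS2", n >= 1)
  if (is.null(params_p1)) params_p1 <- realize_truth(truth_p1)
  if (is.null(params_p2)) params_p2 <- realize_truth(truth_p2)
  mix1 <- phys1_mixture(params_p1, truth_p1$structure)
  mix2 <- phys2_mixture(params_p2, truth_p2$structure)
  seed2 <- if (is.null(seed)) NULL else seed + 1L
  p1 <- r_channel_mixture(mix1, n, channel_max, seed)
  p2 <- r_channel_mixture(mix2, n, channel_max, seed2)
  attr(p1, "assay") <- "PHYS1"
  attr(p2, "assay") <- "PHYS2"
  out <- list(panel1 = p1, panel2 = p2)
  attr(out, "truth") <- c(phys1_truth_stats(mix1),
                          phys2_truth_stats(mix2,
                                            truth_p2$structure$ros_reference))
  out
}
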