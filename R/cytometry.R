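#' Gating strategy for debris exclusion
#'
#' An event is debris when it is at or below the cut on *every* listed
#' channel; a single nuclear-stain channel gives the usual stain-negative
#' rule, and listing both acridine-orange channels gives the AO
#' double-negative rule used for SCSA.
#'
#' @param channels character vector of channel names.
#' @param cuts numeric cuts, recycled to the channels.
#' @return list of class `gating_strategy`.
#' @export
gating_strategy <- function(channels, cuts) {
  stopifnot(length(channels) >= 1)
  cuts <- rep_len(cuts, length(channels))
  structure(list(channels = channels, cuts = cuts), class = "gating_strategy")
}

#' Gate debris out of an event table
#'
#' Retains events positive (above the cut) on at least one strategy channel;
#' the report accounts for every input event. A gated sample with fewer than
#' `min_events` sperm raises a warning (never silent exclusion) and the
#' report carries the flag.
#'
#' @param events event tibble with named channel columns.
#' @param strategy a [gating_strategy()].
#' @param min_events acquisition floor below which the report is flagged.
#' @return list with `events` (gated tibble) and `report` (list:
#'   `n_total`, `n_debris`, `n_sperm`, `thresholds`, `low_count`).
#' @export
gate_events <- function(events, strategy, min_events = 5000) {
  stopifnot(inherits(strategy, "gating_strategy"))
  missing_ch <- setdiff(strategy$channels, names(events))
  if (length(missing_ch))
    stop("unknown channel(s): ", paste(missing_ch, collapse = ", "))
  below <- mapply(function(ch, cut) events[[ch]] <= cut,
                  strategy$channels, strategy$cuts)
  if (is.null(dim(below))) below <- matrix(below, nrow = nrow(events))
  is_debris <- rowSums(below) == length(strategy$channels)
  gated <- events[!is_debris, , drop = FALSE]
  if (nrow(gated) == 0) stop("empty gate: all events classified as debris")
  low <- nrow(gated) < min_events
  if (low)
    warning(sprintf("only %d sperm events after gating (< %d)",
                    nrow(gated), min_events))
  list(events = gated,
       report = list(n_total = nrow(events), n_debris = sum(is_debris),
                     n_sperm = nrow(gated),
                     thresholds = stats::setNames(strategy$cuts,
                                                  strategy$channels),
                     low_count = low))
}

#' SCSA per-sample statistics
#'
#' The per-cell DNA fragmentation index is DFI = 1000 * red / (red + green);
#' %DFI is the percentage of cells with DFI strictly above 250, SD-DFI the
#' sample (n-1) standard deviation of DFI, and %HDS the percentage with
#' green fluorescence above the stainability cut (a fixed position on the
#' green channel scale, by default 65% of full scale).
#'
#' @param events gated event tibble with `red` and `green` channels.
#' @param hds_threshold green-channel cut for high DNA stainability; default
#'   `0.65 * channel_max`.
#' @param channel_max full-scale channel value.
#' @return list of class `scsa_result`: `sd_dfi`, `pct_dfi`, `pct_hds`,
#'   `n_events`.
#' @export
scsa_statistics <- function(events, hds_threshold = NULL, channel_max = 1023) {
  stopifnot(all(c("red", "green") %in% names(events)), nrow(events) >= 1)
  if (is.null(hds_threshold)) hds_threshold <- 0.65 * channel_max
  total <- events$red + events$green
  if (any(total == 0))
    stop("event with red + green = 0: AO double-negative events must be gated out")
  dfi <- 1000 * events$red / total
  structure(list(
    sd_dfi = stats::sd(dfi),
    pct_dfi = 100 * mean(dfi > 250),
    pct_hds = 100 * mean(events$green > hds_threshold),
    n_events = nrow(events)), class = "scsa_result")
}

#' Reference-normalized median fluorescence intensity
#'
#' @param events gated event tibble.
#' @param channel channel name.
#' @param reference_mfi daily standard-sample median (> 0); 1 returns the
#'   raw median.
#' @return `median(channel) / reference_mfi`.
#' @export
median_fluorescence <- function(events, channel, reference_mfi = 1) {
  if (reference_mfi <= 0) stop("reference_mfi must be positive")
  if (nrow(events) == 0) stop("empty event table")
  stopifnot(channel %in% names(events))
  stats::median(events[[channel]]) / reference_mfi
}

#' Low/moderate/high fractions of a fluorescence channel
#'
#' Low is value <= `bounds[1]`, high is value > `bounds[2]`, moderate the
#' remainder; the three percentages sum to 100 exactly.
#'
#' @param events gated event tibble.
#' @param channel channel name.
#' @param bounds numeric `c(low_cut, high_cut)` with `low_cut < high_cut`.
#' @return named numeric `c(pct_low, pct_moderate, pct_high)`.
#' @export
gate_fractions <- function(events, channel, bounds) {
  stopifnot(length(bounds) == 2)
  if (bounds[1] >= bounds[2]) stop("inverted bounds: low_cut must be < high_cut")
  x <- events[[channel]]
  if (is.null(x)) stop("unknown channel: ", channel)
  p_low <- 100 * mean(x <= bounds[1])
  p_high <- 100 * mean(x > bounds[2])
  c(pct_low = p_low, pct_moderate = 100 - p_low - p_high, pct_high = p_high)
}

#' Monobromobimane (mBBr) per-sample statistics
#'
#' The normalized MFI and the low/moderate/high fractions come from the
#' untreated split; the disulfide index is half the difference between the
#' DTT-reduced and untreated medians, computed on the scale set by
#' `disulfide_reference` (1 = raw channel units). A negative index is
#' returned but flagged.
#'
#' @param untreated,dtt gated event tibbles with an `mbbr` channel.
#' @param reference_mfi daily standard median for MFI normalization.
#' @param bounds low/high cuts for the fractions.
#' @param disulfide_reference reference scale for the disulfide index.
#' @return list of class `mbbr_result`: `mfi_norm`, `pct_low`,
#'   `pct_moderate`, `pct_high`, `disulfide_index`, `negative_index` flag.
#' @export
mbbr_statistics <- function(untreated, dtt, reference_mfi, bounds,
                            disulfide_reference = 1) {
  med_u <- median_fluorescence(untreated, "mbbr", disulfide_reference)
  med_d <- median_fluorescence(dtt, "mbbr", disulfide_reference)
  fr <- gate_fractions(untreated, "mbbr", bounds)
  idx <- (med_d - med_u) / 2
  structure(list(
    mfi_norm = median_fluorescence(untreated, "mbbr", reference_mfi),
    pct_low = fr[["pct_low"]], pct_moderate = fr[["pct_moderate"]],
    pct_high = fr[["pct_high"]],
    disulfide_index = idx,
    negative_index = idx < 0), class = "mbbr_result")
}

#' Chromomycin A3 (CMA3) per-sample statistics
#'
#' @param events gated event tibble with a `cma3` channel.
#' @inheritParams mbbr_statistics
#' @return list of class `cma3_result`: `mfi_norm`, `pct_low`,
#'   `pct_moderate`, `pct_high`.
#' @export
cma3_statistics <- function(events, reference_mfi, bounds) {
  fr <- gate_fractions(events, "cma3", bounds)
  structure(list(
    mfi_norm = median_fluorescence(events, "cma3", reference_mfi),
    pct_low = fr[["pct_low"]], pct_moderate = fr[["pct_moderate"]],
    pct_high = fr[["pct_high"]]), class = "cma3_result")
}

#' 8-oxo-dG per-sample statistics
#'
#' DNA oxidative damage is summarized both as the percentage of cells with
#' high FITC fluorescence and as the normalized FITC median.
#'
#' @param events gated event tibble with a `fitc` channel.
#' @param reference_mfi daily standard median.
#' @param high_cut FITC cut for the high-fluorescence fraction.
#' @return list of class `oxodg_result`: `mfi_norm`, `pct_high`.
#' @export
oxodg_statistics <- function(events, reference_mfi, high_cut) {
  if (nrow(events) == 0) stop("empty event table")
  structure(list(
    mfi_norm = median_fluorescence(events, "fitc", reference_mfi),
    pct_high = 100 * mean(events$fitc > high_cut)), class = "oxodg_result")
}

.cond_pct <- function(num, den) {
  if (!any(den)) return(NA_real_)
  100 * mean(num[den])
}

#' Sperm physiology per-sample statistics
#'
#' Computes the panel read-outs with their stated denominators: viability
#' (PI-negative), apoptosis among viable (YO-PRO-1-positive of PI-negative),
#' acrosome damage (total and among non-apoptotic), capacitation among
#' non-apoptotic, active mitochondria, high mitochondrial superoxide among
#' viable (H258-negative), and the cytoplasmic-ROS median of H258-negative
#' cells. Empty denominator subpopulations yield `NA` with a flag, never a
#' failure.
#'
#' @param panel1 gated event tibble with `pi`, `yp`, `m540`, `pna` channels.
#' @param panel2 gated event tibble with `h258`, `cfda`, `mx`, `mtdr`.
#' @param stain_cut positive/negative threshold on the stain channels.
#' @param ros_reference reference median for the cytoplasmic ROS MFI.
#' @return list of class `physiology_result` with the eight statistics and a
#'   `flags` character vector naming any empty denominators.
#' @export
physiology_statistics <- function(panel1, panel2, stain_cut = 110,
                                  ros_reference = 1) {
  stopifnot(all(c("pi", "yp", "m540", "pna") %in% names(panel1)),
            all(c("h258", "cfda", "mx", "mtdr") %in% names(panel2)))
  pi_neg <- panel1$pi <= stain_cut
  yp_pos <- panel1$yp > stain_cut
  flags <- character(0)
  res <- list(
    pct_viable = 100 * mean(pi_neg),
    pct_apoptotic_of_viable = .cond_pct(yp_pos, pi_neg),
    pct_acrosome_damaged_total = 100 * mean(panel1$pna > stain_cut),
    pct_acrosome_damaged_of_nonapoptotic = .cond_pct(panel1$pna > stain_cut,
                                                     !yp_pos),
    pct_capacitated_of_nonapoptotic = .cond_pct(panel1$m540 > stain_cut,
                                                !yp_pos))
  h_neg <- panel2$h258 <= stain_cut
  res$pct_active_mitochondria <- 100 * mean(panel2$mtdr > stain_cut)
  res$pct_high_superoxide_of_viable <- .cond_pct(panel2$mx > stain_cut, h_neg)
  res$cytoplasmic_ros_mfi <- if (any(h_neg))
    stats::median(panel2$cfda[h_neg]) / ros_reference else NA_real_
  flags <- names(res)[vapply(res, function(x) is.na(x), logical(1))]
  res$flags <- flags
  class(res) <- "physiology_result"
  res
}
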