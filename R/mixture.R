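#' Finite log-normal mixture over named cytometry channels
#'
#' The synthetic event generators all share one generative model: each event
#' belongs to a latent state (main population, fragmented tail, debris,
#' dead/apoptotic cell, ...) and, given the state, every channel is an
#' independent log-normal on the native channel scale. Keeping the model this
#' explicit lets the generator report the *theoretical* value of every
#' downstream statistic (threshold exceedance probabilities, conditional
#' fractions, population medians) in closed form or by one-dimensional root
#' finding, so truth-recovery tests are unbiased by construction.
#'
#' @param weights named numeric vector of state weights; must be non-negative
#'   and sum to 1 (within 1e-8).
#' @param meanlog,sdlog numeric matrices, states x channels, with matching
#'   dimnames; `sdlog` strictly positive.
#' @return an object of class `channel_mixture`.
#' @keywords internal
new_channel_mixture <- function(weights, meanlog, sdlog) {
  stopifnot(is.numeric(weights), !is.null(names(weights)),
            is.matrix(meanlog), is.matrix(sdlog))
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("mixture weights must be non-negative and sum to 1")
  if (!identical(dim(meanlog), dim(sdlog)))
    stop("meanlog and sdlog must have identical dimensions")
  if (any(sdlog <= 0)) stop("all sdlog values must be positive")
  if (!identical(rownames(meanlog), names(weights)))
    stop("rownames of meanlog must match names of weights")
  if (anyDuplicated(colnames(meanlog))) stop("channel names must be unique")
  structure(list(weights = weights, meanlog = meanlog, sdlog = sdlog),
            class = "channel_mixture")
}

#' Draw events from a channel mixture
#'
#' Values above `channel_max` are clipped to `channel_max` (detector pile-up),
#' never discarded; the clipped mass is reported as the `clipped_fraction`
#' attribute. Latent state labels are kept in the `.state` column so tests can
#' compare estimates against the generating truth.
#'
#' @param mix a `channel_mixture`.
#' @param n number of events (>= 1).
#' @param channel_max full-scale channel value; defaults to 1023 (10-bit
#'   display scale).
#' @param seed optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is untouched.
#' @return tibble with one column per channel plus `.state`.
#' @export
r_channel_mixture <- function(mix, n, channel_max = 1023, seed = NULL) {
  stopifnot(inherits(mix, "channel_mixture"), n >= 1)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  states <- names(mix$weights)
  idx <- sample.int(length(states), n, replace = TRUE, prob = mix$weights)
  out <- lapply(colnames(mix$meanlog), function(ch) {
    stats::rlnorm(n, mix$meanlog[idx, ch], mix$sdlog[idx, ch])
  })
  names(out) <- colnames(mix$meanlog)
  tab <- tibble::as_tibble(out)
  clipped <- mean(purrr::map_dbl(tab, ~ mean(.x > channel_max)))
  tab <- dplyr::mutate(tab, dplyr::across(
    dplyr::everything(), ~ pmin(.x, channel_max)))
  tab$.state <- states[idx]
  attr(tab, "clipped_fraction") <- clipped
  attr(tab, "channel_max") <- channel_max
  tab
}

# save/restore of .Random.seed so seeded generators do not disturb callers
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# P(channel <side> cut | state s) for a single condition
.cond_prob_by_state <- function(mix, cond) {
  stopifnot(cond$channel %in% colnames(mix$meanlog))
  p_le <- stats::plnorm(cond$cut, mix$meanlog[, cond$channel],
                        mix$sdlog[, cond$channel])
  switch(cond$side, le = p_le, gt = 1 - p_le,
         stop("condition side must be 'le' or 'gt'"))
}

#' Exact conditional threshold probability under a channel mixture
#'
#' Computes `P(target | conditions)` where the target and each condition is a
#' one-sided threshold on a channel (`side` is `"gt"` or `"le"`). Channels are
#' independent given the state, so joint probabilities factorize per state;
#' conditions on the *same* channel as the target are not supported.
#'
#' @param mix a `channel_mixture`.
#' @param target list(channel=, cut=, side=).
#' @param conditions list of such lists (possibly empty) to condition on,
#'   e.g. the debris gate or a viability gate.
#' @param states optional character vector of states to restrict to
#'   (renormalized) before conditioning, e.g. the non-debris states.
#' @return probability in `[0, 1]`.
#' @export
mixture_conditional_prob <- function(mix, target, conditions = list(),
                                     states = NULL) {
  for (cond in conditions)
    if (cond$channel == target$channel)
      stop("conditioning on the target channel is not supported")
  w <- .posterior_weights(mix, conditions, states)
  sum(w * .cond_prob_by_state(mix, target)[names(w)])
}

.posterior_weights <- function(mix, conditions, states = NULL) {
  keep <- if (is.null(states)) names(mix$weights) else states
  w <- mix$weights[keep] / sum(mix$weights[keep])
  for (cond in conditions) w <- w * .cond_prob_by_state(mix, cond)[keep]
  tot <- sum(w)
  if (tot <= 0) stop("conditioning event has probability zero")
  w / tot
}

#' Exact probability that a two-channel fluorescence ratio exceeds a cut
#'
#' Computes `P(num / (num + den) > frac)` under the mixture, optionally
#' restricted to a subset of states. Because both channels are log-normal
#' given the state, the log-ratio is Gaussian and the probability is closed
#' form. Used for the per-cell DNA fragmentation index, where
#' DFI = 1000 * red / (red + green) and DFI > 250 is red/green > 1/3.
#'
#' @param mix a `channel_mixture`.
#' @param num,den channel names of numerator and denominator-complement.
#' @param frac cut on the ratio num/(num+den), in (0, 1).
#' @param states optional character vector of states to restrict to
#'   (renormalized), e.g. the sperm (non-debris) states.
#' @return probability in `[0, 1]`.
#' @export
mixture_ratio_prob <- function(mix, num, den, frac, states = NULL) {
  stopifnot(frac > 0, frac < 1)
  keep <- if (is.null(states)) names(mix$weights) else states
  w <- mix$weights[keep] / sum(mix$weights[keep])
  # num/(num+den) > frac  <=>  log(num) - log(den) > log(frac/(1-frac))
  mu <- mix$meanlog[keep, num] - mix$meanlog[keep, den]
  sd <- sqrt(mix$sdlog[keep, num]^2 + mix$sdlog[keep, den]^2)
  sum(w * stats::pnorm(log(frac / (1 - frac)), mu, sd, lower.tail = FALSE))
}

#' Exact median of a channel under a (conditioned) channel mixture
#'
#' Solves `P(X <= m | conditions) = 1/2` by root finding on the mixture CDF.
#'
#' @inheritParams mixture_conditional_prob
#' @param channel channel name.
#' @return the theoretical median on the channel scale.
#' @export
mixture_median <- function(mix, channel, conditions = list(), states = NULL) {
  w <- .posterior_weights(mix, conditions, states)
  ml <- mix$meanlog[names(w), channel]
  sl <- mix$sdlog[names(w), channel]
  cdf <- function(q) sum(w * stats::plnorm(q, ml, sl)) - 0.5
  upper <- exp(max(ml + 6 * sl))
  stats::uniroot(cdf, c(1e-12, upper), tol = 1e-10)$root
}
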