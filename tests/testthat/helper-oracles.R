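# Independent oracles used across tests.

# Brute-force Hoeffding D straight from the counting definition: midranks,
# Q as the point itself plus points strictly smaller on both axes with half
# credit for ties, then the 30-scaled combination of D1, D2, D3.
brute_hoeffding_d <- function(x, y) {
  n <- length(x)
  r <- rank(x)
  s <- rank(y)
  phi <- function(a, b) if (a < b) 1 else if (a == b) 0.5 else 0
  q <- vapply(seq_len(n), function(i) {
    1 + sum(vapply(seq_len(n)[-i], function(j)
      phi(x[j], x[i]) * phi(y[j], y[i]), numeric(1)))
  }, numeric(1))
  d1 <- sum((q - 1) * (q - 2))
  d2 <- sum((r - 1) * (r - 2) * (s - 1) * (s - 2))
  d3 <- sum((r - 2) * (s - 2) * (q - 1))
  30 * ((n - 2) * (n - 3) * d1 + d2 - 2 * (n - 2) * d3) /
    (n * (n - 1) * (n - 2) * (n - 3) * (n - 4))
}

# The ten-event SCSA worked set: nine main-population cells and one
# fragmented cell. DFIs are 100 (x9) and 750; %DFI = 10; SD is the sample SD.
scsa_worked_events <- function() {
  tibble::tibble(green = c(rep(180, 9), 50), red = c(rep(20, 9), 150))
}

# a tiny three-blob kinematic mixture, clearly separated, for clustering
separated_casa_components <- function(weights = c(0.3, 0.5, 0.2)) {
  casa_components(
    name = c("Slow", "Fast", "Hyper"), weight = weights,
    vcl_med = c(30, 120, 110), vcl_sdlog = c(0.12, 0.10, 0.10),
    wob_mean = c(0.55, 0.60, 0.45), str_mean = c(0.55, 0.55, 0.15),
    kappa = c(400, 400, 400),
    alh_med = c(1.2, 2.6, 4.5), alh_sdlog = c(0.10, 0.10, 0.10),
    bcf_med = c(8, 22, 12), bcf_sdlog = c(0.10, 0.10, 0.10))
}

# best-permutation label agreement between truth and cluster labels
label_agreement <- function(truth, labels) {
  truth <- as.character(truth)
  k <- length(unique(labels))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- 0
  for (p in perms(unique(truth))) {
    map <- stats::setNames(seq_along(p), p)
    best <- max(best, mean(map[truth] == labels))
  }
  best
}

# small deterministic event table helper
toy_events <- function(...) tibble::tibble(...)
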