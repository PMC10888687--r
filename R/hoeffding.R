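#' Hoeffding's D statistic of bivariate dependence
#'
#' Rank-based nonparametric measure of general (not merely monotone)
#' dependence. With midranks R and S of x and y and the bivariate rank
#' Q_i = 1 + #\{j : x_j < x_i, y_j < y_i\} (half credit for ties on either
#' axis, quarter credit for ties on both), the statistic is
#' \deqn{D = 30 \frac{(n-2)(n-3) D_1 + D_2 - 2(n-2) D_3}
#'                  {n(n-1)(n-2)(n-3)(n-4)}}
#' with \eqn{D_1 = \sum (Q-1)(Q-2)}, \eqn{D_2 = \sum (R-1)(R-2)(S-1)(S-2)},
#' \eqn{D_3 = \sum (R-2)(S-2)(Q-1)}. The factor 30 scales perfect
#' dependence to 1; the attainable range is about \[-0.5, 1\] and the
#' expectation under independence is 0.
#'
#' @param x,y paired numeric vectors, n >= 5.
#' @return scaled D (length-1 numeric); `NA` with a warning if either input
#'   is constant (dependence undefined).
#' @examples
#' hoeffding_d(1:5, 1:5)   # exactly 1
#' hoeffding_d(1:5, 5:1)   # also 1: dependence, not direction
#' @export
hoeffding_d <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("hoeffding_d requires at least 5 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant input: Hoeffding's D undefined")
    return(NA_real_)
  }
  r <- rank(x)                 # midranks
  s <- rank(y)
  # Q via pairwise comparison with half credit for ties; the 0.25
  # self-comparison (tie on both axes) is removed so Q counts the point
  # itself exactly once
  phi_x <- outer(x, x, FUN = function(a, b) (a < b) + 0.5 * (a == b))
  phi_y <- outer(y, y, FUN = function(a, b) (a < b) + 0.5 * (a == b))
  q <- 1 + colSums(phi_x * phi_y) - 0.25
  d1 <- sum((q - 1) * (q - 2))
  d2 <- sum((r - 1) * (r - 2) * (s - 1) * (s - 2))
  d3 <- sum((r - 2) * (s - 2) * (q - 1))
  30 * ((n - 2) * (n - 3) * d1 + d2 - 2 * (n - 2) * d3) /
    (n * (n - 1) * (n - 2) * (n - 3) * (n - 4))
}

#' Pairwise scaled Hoeffding-D matrix
#'
#' @param data data frame or matrix of numeric variables.
#' @return symmetric matrix of scaled D values with unit diagonal; pairs
#'   with an undefined D are `NA`.
#' @export
hoeffding_d_matrix <- function(data) {
  data <- as.data.frame(data)
  p <- ncol(data)
  out <- diag(1, p)
  dimnames(out) <- list(names(data), names(data))
  if (p < 2) return(out)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    d <- suppressWarnings(hoeffding_d(data[[i]], data[[j]]))
    out[i, j] <- out[j, i] <- d
  }
  out
}
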