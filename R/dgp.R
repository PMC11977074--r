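#' Laplace scale parameter from a target variance
#'
#' The Laplace (double-exponential) density
#' `f(x) = exp(-|x - mu| / b) / (2b)` has mean `mu` and variance `2 b^2`;
#' the scale matching a target variance `s2` is therefore `sqrt(s2 / 2)`.
#' The simulation grid `b` in `{0.2, 0.4, 0.6, 0.8}` corresponds to the
#' variances `{0.08, 0.32, 0.72, 1.28}`.
#'
#' @param s2 Target variance, strictly positive.
#' @return Scale parameter `b = sqrt(s2/2)`.
#' @examples
#' b_from_variance(1.28)  # 0.8
#' @export
b_from_variance <- function(s2) {
  if (any(!is.finite(s2)) || any(s2 <= 0))
    stop("`s2` must be strictly positive", call. = FALSE)
  sqrt(s2 / 2)
}

#' Laplace random draws by inverse-CDF
#'
#' Draws i.i.d. Laplace variates by inverting the CDF on `runif()` uniforms:
#' with `u` uniform on (-1/2, 1/2), `x = mu - b * sign(u) * log(1 - 2|u|)`.
#' Tying the sampler to the uniform stream makes the draws a function of the
#' R RNG state only, which is the reproducibility contract of the simulation
#' engine (`set.seed()` fixes everything downstream).
#'
#' @param n Number of draws.
#' @param mu Location (= mean), default 0.
#' @param b Scale, default 1; variance is `2 b^2`.
#' @return Numeric vector of `n` draws.
#' @examples
#' set.seed(1); var(rlaplace(1e4, b = 0.8))  # about 1.28
#' @seealso [plaplace()], [dlaplace()]
#' @export
rlaplace <- function(n, mu = 0, b = 1) {
  stopifnot(b > 0)
  u <- stats::runif(n) - 0.5
  # pmax guards the measure-zero event u = -0.5 (runif can return 0)
  mu - b * sign(u) * log(pmax(1 - 2 * abs(u), .Machine$double.xmin))
}

#' Laplace cumulative distribution function
#'
#' @param q Vector of quantiles.
#' @param mu Location, default 0.
#' @param b Scale, default 1.
#' @return `P(X <= q)` for X Laplace(`mu`, `b`).
#' @export
plaplace <- function(q, mu = 0, b = 1) {
  stopifnot(b > 0)
  z <- (q - mu) / b
  ifelse(z < 0, 0.5 * exp(z), 1 - 0.5 * exp(-z))
}

#' Laplace probability density function
#'
#' @inheritParams plaplace
#' @param x Vector of evaluation points.
#' @return Density values `exp(-|x - mu|/b) / (2b)`.
#' @export
dlaplace <- function(x, mu = 0, b = 1) {
  stopifnot(b > 0)
  exp(-abs(x - mu) / b) / (2 * b)
}

#' Group locations realizing a standardized effect size
#'
#' For effect size `D` (Cohen's d for the unpaired design, the same grid
#' value labelled d_z for the paired design) and group variances `s2_a`,
#' `s2_b`, the two population means are placed symmetrically around 0:
#' `mu_a = +D * sqrt((s2_a + s2_b)/2) / 2` and `mu_b = -mu_a`, so that
#' `(mu_a - mu_b) / sqrt((s2_a + s2_b)/2) = D` exactly.
#'
#' @param D_effect Standardized effect size, non-negative.
#' @param s2_a,s2_b Group variances, strictly positive.
#' @return Named numeric vector `c(mu_a = ..., mu_b = ...)`.
#' @examples
#' effect_to_locations(1, 0.08, 0.08)  # +/- sqrt(0.08)/2
#' @export
effect_to_locations <- function(D_effect, s2_a, s2_b) {
  if (!is.numeric(D_effect) || length(D_effect) != 1L || !is.finite(D_effect) ||
      D_effect < 0)
    stop("`D_effect` must be a single non-negative number", call. = FALSE)
  if (any(!is.finite(c(s2_a, s2_b))) || s2_a <= 0 || s2_b <= 0)
    stop("variances must be strictly positive", call. = FALSE)
  mu_a <- D_effect * sqrt((s2_a + s2_b) / 2) / 2
  c(mu_a = mu_a, mu_b = -mu_a)
}
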