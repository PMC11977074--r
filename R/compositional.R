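#' Compositional data point on the simplex
#'
#' A D-part composition is a vector of strictly positive parts with fixed sum
#' `kappa` (the closure constant). Bipolar Likert data give the bivariate case
#' `(x*, kappa - x*)`: the orders of magnitude of agreement and disagreement.
#'
#' @param parts Numeric vector of strictly positive parts.
#' @param kappa Closure constant; defaults to `sum(parts)`. If supplied, the
#'   parts must sum to `kappa` within a relative tolerance of `1e-9`.
#' @return An object of class `composition`: list with `parts` and `kappa`.
#' @examples
#' composition(c(73.75, 26.25))
#' @export
composition <- function(parts, kappa = sum(parts)) {
  parts <- as.numeric(parts)
  if (length(parts) < 2L || any(!is.finite(parts)))
    stop("a composition needs at least 2 finite parts", call. = FALSE)
  if (any(parts <= 0))
    stop("all parts of a composition must be strictly positive", call. = FALSE)
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) || kappa <= 0)
    stop("`kappa` must be a single positive number", call. = FALSE)
  if (abs(sum(parts) - kappa) > 1e-9 * kappa)
    stop("parts must sum to `kappa` (within 1e-9 relative tolerance)", call. = FALSE)
  structure(list(parts = parts, kappa = kappa), class = "composition")
}

#' @export
print.composition <- function(x, ...) {
  cat(sprintf("%d-part composition (kappa = %g): ", length(x$parts), x$kappa),
      paste(format(x$parts), collapse = ", "), "\n")
  invisible(x)
}

#' Isometric log-ratio (ilr) transform of a composition
#'
#' Maps a D-part composition to D-1 real coordinates
#' \deqn{z_s = \sqrt{s/(s+1)} \, \ln\!\big( g(x_1,\dots,x_s) / x_{s+1} \big),
#'       \quad s = 1, \dots, D-1,}
#' where `g` is the geometric mean. For D = 2 this reduces to
#' `z_1 = sqrt(0.5) * log(x_1 / x_2)`; see [bilr()] for the vectorized
#' bivariate form. The transform is invariant to the closure constant.
#'
#' Compositions with a zero part are invalid inputs (the log-ratio is
#' undefined); they are rejected, not clamped. The scales produced by
#' [star_scale()] never touch the boundary because `p > 0`.
#'
#' @param x A [composition()] or a numeric vector of positive parts (closed
#'   to its own sum).
#' @return Numeric vector of D-1 ilr coordinates.
#' @examples
#' round(ilr(c(97.5, 2.5)), 2)  # 2.59
#' @seealso [ilr_inverse()], [bilr()]
#' @export
ilr <- function(x) {
  x <- if (inherits(x, "composition")) x else composition(x)
  lp <- log(x$parts)
  D <- length(lp)
  s <- seq_len(D - 1L)
  # log geometric mean of the first s parts, against part s+1
  sqrt(s / (s + 1)) * (cumsum(lp)[s] / s - lp[s + 1L])
}

#' Inverse ilr transform
#'
#' Maps D-1 ilr coordinates back to the simplex with closure `kappa`. With
#' the boundary convention `z_0 := z_D := 0`,
#' \deqn{y_s = \sum_{j=s}^{D} z_j / \sqrt{j(j+1)} - \sqrt{(s-1)/s}\, z_{s-1},
#'       \qquad x_s = \kappa\, e^{y_s} \big/ \sum_j e^{y_j}.}
#' The closing ratio is evaluated softmax-style after subtracting `max(y)`,
#' so large coordinates do not overflow.
#'
#' @param z Numeric vector of D-1 finite ilr coordinates.
#' @param kappa Closure constant of the result, default 100.
#' @return A [composition()] with D parts summing to `kappa`.
#' @examples
#' round(ilr_inverse(0.73)$parts, 2)  # 73.75 26.25
#' @export
ilr_inverse <- function(z, kappa = 100) {
  z <- as.numeric(z)
  if (length(z) < 1L || any(!is.finite(z)))
    stop("`z` must be a vector of at least one finite coordinate", call. = FALSE)
  D <- length(z) + 1L
  zfull <- c(z, 0)                       # z_D := 0
  j <- seq_len(D)
  term <- zfull / sqrt(j * (j + 1))
  tail_sums <- rev(cumsum(rev(term)))    # sum_{j=s}^{D} term_j
  zprev <- c(0, z)                       # z_{s-1}, with z_0 := 0
  y <- tail_sums - sqrt((j - 1) / j) * zprev
  y <- y - max(y)
  composition(kappa * exp(y) / sum(exp(y)), kappa)
}

#' Vectorized bivariate ilr
#'
#' The two-part special case of [ilr()]: each star value `x*` in
#' `(0, kappa)` represents the composition `(x*, kappa - x*)` and maps to
#' `sqrt(0.5) * log(x* / (kappa - x*))`. Element-wise identical to calling
#' [ilr()] on each composition.
#'
#' @param x_star Numeric vector (or matrix) of star values, all strictly
#'   inside `(0, kappa)`.
#' @param kappa Closure constant, default 100.
#' @return Numeric vector/matrix of ilr values, same shape as `x_star`.
#' @examples
#' round(bilr(c(2.5, 26.25, 50, 73.75, 97.5)), 2)
#' @export
bilr <- function(x_star, kappa = 100) {
  if (any(!is.finite(x_star)) || any(x_star <= 0) || any(x_star >= kappa))
    stop("star values must lie strictly inside (0, kappa)", call. = FALSE)
  sqrt(0.5) * log(x_star / (kappa - x_star))
}

#' Vectorized bivariate inverse ilr
#'
#' Returns the first part `x* = kappa * exp(y1) / (exp(y1) + exp(y2))` with
#' `y1 = sqrt(0.5) z`, `y2 = -sqrt(0.5) z`, evaluated through the logistic
#' function so that arbitrarily large `|z|` cannot overflow. The full
#' composition is `(x*, kappa - x*)`.
#'
#' @param z Numeric vector (or matrix) of ilr values.
#' @param kappa Closure constant, default 100.
#' @return Numeric vector/matrix of star values, same shape as `z`.
#' @examples
#' round(bilr_inverse(0.82), 2)  # 76.13
#' @export
bilr_inverse <- function(z, kappa = 100) {
  kappa * stats::plogis(sqrt(2) * z)
}
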