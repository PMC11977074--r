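#' Limit of quantification (LOQ) of a bipolar response scale
#'
#' A Likert response scale never covers the full trait continuum: the edge
#' areas of the trait scale that no response category can express make up a
#' fraction `p` of its total mass, split symmetrically into a lower and an
#' upper edge area of width `p/2` each.
#'
#' @param p Fraction of the trait scale not covered by the response scale,
#'   strictly between 0 and 1.
#' @param kappa Total mass of the trait scale (its upper minus lower bound);
#'   default 100.
#' @return A list with elements `p`, `kappa`, `lLOQ` (`kappa * p/2`),
#'   `uLOQ` (`kappa * (1 - p/2)`), `delta_l` and `delta_u` (both `p/2`).
#' @examples
#' loq(0.05)  # lLOQ = 2.5, uLOQ = 97.5 on the 0..100 trait scale
#' @export
loq <- function(p, kappa = 100) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
    stop("`p` must be a single number strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) || kappa <= 0)
    stop("`kappa` must be a single positive number", call. = FALSE)
  list(p = p, kappa = kappa,
       lLOQ = kappa * p / 2, uLOQ = kappa * (1 - p / 2),
       delta_l = p / 2, delta_u = p / 2)
}

#' Map a K-category response scale onto the trait scale (the "star" scale)
#'
#' Places the `K` ordered response categories `1, ..., K` equidistantly on the
#' trait scale `[0, kappa]`, restricted to the part of the continuum the scale
#' can actually quantify: category 1 lands on the lower limit of
#' quantification `lLOQ = kappa * p/2`, category `K` on the upper limit
#' `uLOQ = kappa * (1 - p/2)`, with step width
#' `sw = (uLOQ - lLOQ) / (K - 1)` in between. Any star value `x*` together
#' with its complement `kappa - x*` forms a two-part composition (order of
#' magnitude of agreement / disagreement).
#'
#' Only the symmetric LOQ is supported: both edge areas have width `p/2`.
#'
#' @param K Number of response categories (integer, at least 2).
#' @param p Limit of quantification, strictly between 0 and 1.
#' @param kappa Trait-scale mass, default 100.
#' @return An object of class `star_scale`: a list with `K`, `p`, `kappa`,
#'   `lLOQ`, `uLOQ`, `sw` and the numeric vector `values` of length `K`.
#' @examples
#' s <- star_scale(K = 5, p = 0.05)
#' s$values  # 2.5 26.25 50 73.75 97.5
#' s$sw      # 23.75
#' @seealso [transform_response()], [ilr_scale()]
#' @export
star_scale <- function(K, p, kappa = 100) {
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K != round(K) || K < 2)
    stop("`K` must be a single integer >= 2", call. = FALSE)
  K <- as.integer(K)
  lq <- loq(p, kappa)
  sw <- (lq$uLOQ - lq$lLOQ) / (K - 1)
  values <- lq$lLOQ + sw * (seq_len(K) - 1)
  structure(
    list(K = K, p = p, kappa = kappa,
         lLOQ = lq$lLOQ, uLOQ = lq$uLOQ, sw = sw, values = values),
    class = "star_scale"
  )
}

#' @export
print.star_scale <- function(x, ...) {
  cat(sprintf("Star response scale: K = %d, p = %g, kappa = %g\n", x$K, x$p, x$kappa))
  cat(sprintf("  lLOQ = %g, uLOQ = %g, step width = %g\n", x$lLOQ, x$uLOQ, x$sw))
  cat("  values:", paste(format(x$values), collapse = ", "), "\n")
  invisible(x)
}

#' Transform observed response categories to the star scale
#'
#' An observed category `s` in `1, ..., K` is assigned the star value
#' `lLOQ + sw * (s - 1)`.
#'
#' @param x_prime Vector of observed response categories (integers in
#'   `1, ..., K`).
#' @param scale A [star_scale()] object.
#' @return Numeric vector of star values, same length as `x_prime`.
#' @examples
#' transform_response(3, star_scale(5, 0.05))  # 50
#' @export
transform_response <- function(x_prime, scale) {
  stopifnot(inherits(scale, "star_scale"))
  if (length(x_prime) == 0L) return(numeric(0))
  if (!is.numeric(x_prime) || any(!is.finite(x_prime)) ||
      any(x_prime != round(x_prime)) || any(x_prime < 1) || any(x_prime > scale$K))
    stop(sprintf("responses must be integers in 1..%d", scale$K), call. = FALSE)
  scale$values[as.integer(x_prime)]
}

#' Ilr image of a star scale
#'
#' Applies the bivariate isometric log-ratio transform to each star value
#' `x*`, i.e. `sqrt(0.5) * log(x* / (kappa - x*))`, yielding the response
#' scale on the real line. The ilr scale is symmetric about 0 but, unlike the
#' original scale, not equidistant: the gaps widen towards the edges, the
#' more so the smaller `p`.
#'
#' @param scale A [star_scale()] object.
#' @return Numeric vector of length `K` of ilr-scale response values.
#' @examples
#' round(ilr_scale(star_scale(5, 0.05)), 2)  # -2.59 -0.73 0 0.73 2.59
#' @export
ilr_scale <- function(scale) {
  stopifnot(inherits(scale, "star_scale"))
  bilr(scale$values, scale$kappa)
}

#' Relative distance of the two top responses of a scale
#'
#' The gap between the largest and second-largest response value, as a
#' fraction of the full scale range. On an equidistant K-category scale this
#' is `1/(K-1)`; on an ilr scale it is larger, and it grows as the LOQ `p`
#' shrinks, which is the diagnostic for edge spreading of ilr scales.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return `(max - second_max) / (max - min)` over the distinct values.
#' @examples
#' relative_edge_distance(1:5)  # 0.25
#' @export
relative_edge_distance <- function(values) {
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("`values` must be finite numerics", call. = FALSE)
  u <- sort(unique(values))
  if (length(u) < 2L)
    stop("`values` must contain at least 2 distinct values", call. = FALSE)
  m <- length(u)
  (u[m] - u[m - 1L]) / (u[m] - u[1L])
}
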