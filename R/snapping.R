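#' Snap values to their nearest possible mean
#'
#' Replaces every input value by the element of the possible-means set
#' closest in Euclidean distance. Values outside the support clamp to the
#' nearest extreme (the automatic consequence of nearest-neighbour search);
#' exact ties between two neighbours break towards the smaller element, a
#' fixed deterministic rule (ties are measure-zero under a continuous DGP).
#'
#' @param x Numeric vector or matrix of values.
#' @param spm A [possible_means()] object, or a numeric vector of support
#'   points (sorted internally).
#' @return The snapped values, same shape as `x`.
#' @examples
#' spm <- possible_means(bilr(star_scale(5, 0.05)$values), I = 2)
#' round(snap(0.82, spm), 2)
#' @export
snap <- function(x, spm) {
  v <- if (inherits(spm, "possible_means")) spm$values else sort(as.numeric(spm))
  if (length(v) < 1L) stop("`spm` must be non-empty", call. = FALSE)
  i <- findInterval(x, v)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(v))
  out <- ifelse(x - v[lo] <= v[hi] - x, v[lo], v[hi])
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}

#' Snap a simulated ilr-scale mean along both analysis paths
#'
#' One simulated mean feeds two parallel representations:
#' \describe{
#'   \item{ilr path}{the raw value is snapped directly to the set of
#'     possible means of ilr-transformed item responses (`mu_ilr`).}
#'   \item{original path}{the *same* raw value is inverse-ilr-transformed to
#'     the star scale, snapped (Euclidean, deliberately ignoring the
#'     compositional Aitchison geometry, as uninstructed practice would) to
#'     the star-scale possible means, and mapped by the affine mean
#'     correspondence to the original response scale (`mu_orig`).}
#' }
#'
#' @param z Numeric vector or matrix of raw simulated ilr-scale means.
#' @param scale A [star_scale()] object.
#' @param I Item count used to build the possible-means sets when they are
#'   not supplied.
#' @param spm_ilr,spm_star Optional precomputed [possible_means()] for the
#'   ilr and star scales (pass them when snapping many batches).
#' @return List with `mu_ilr`, `mu_orig` and the intermediate star-scale
#'   snap `mu_star`, each the same shape as `z`.
#' @examples
#' s <- star_scale(5, 0.05)
#' snap_both_paths(0.82, s, I = 2)[c("mu_ilr", "mu_orig")]
#' @export
snap_both_paths <- function(z, scale, I, spm_ilr = NULL, spm_star = NULL) {
  stopifnot(inherits(scale, "star_scale"))
  if (is.null(spm_ilr))
    spm_ilr <- possible_means(ilr_scale(scale), I, scale_tag = "ILR")
  if (is.null(spm_star))
    spm_star <- possible_means(scale$values, I, scale_tag = "RS*")
  mu_ilr <- snap(z, spm_ilr)
  mu_star <- snap(bilr_inverse(z, scale$kappa), spm_star)
  list(mu_ilr = mu_ilr,
       mu_orig = star_mean_to_rs_mean(mu_star, scale),
       mu_star = mu_star)
}
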