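#' Set of possible means (SPM) of I item responses
#'
#' Averaging `I` item responses drawn from a finite response scale can only
#' produce a discrete set of values: the means over all multisets of size `I`
#' of the scale values (combinations with replacement). On the original
#' equidistant scale `1..K` this set has exactly `I*(K-1) + 1` elements; on
#' the non-equidistant ilr scale distinct multisets can collide only through
#' symmetry, so near-equal means are merged within a small tolerance.
#'
#' Enumeration is over the `choose(K + I - 1, I)` multisets; configurations
#' beyond `cap` are refused.
#'
#' @param scale_values Numeric vector of at least 2 response-scale values.
#' @param I Number of items averaged (integer, at least 1).
#' @param tol Absolute tolerance for merging floating-point-equal means,
#'   default `1e-9`.
#' @param cap Maximum number of multisets enumerated, default `1e6`.
#' @param scale_tag Optional label (`"RS"`, `"RS*"`, `"ILR"`, ...) carried in
#'   the result and in its data-frame export.
#' @return Object of class `possible_means`: list with sorted distinct
#'   `values`, `I`, `tol` and `scale_tag`.
#' @examples
#' possible_means(1:5, I = 2)$values  # 1 1.5 2 ... 5
#' @export
possible_means <- function(scale_values, I, tol = 1e-9, cap = 1e6,
                           scale_tag = NULL) {
  scale_values <- as.numeric(scale_values)
  if (length(scale_values) < 2L || any(!is.finite(scale_values)))
    stop("`scale_values` must be at least 2 finite values", call. = FALSE)
  if (!is.numeric(I) || length(I) != 1L || I != round(I) || I < 1)
    stop("`I` must be a single integer >= 1", call. = FALSE)
  I <- as.integer(I)
  K <- length(scale_values)
  n_multisets <- choose(K + I - 1, I)
  if (n_multisets > cap)
    stop(sprintf("enumeration of %.3g multisets exceeds cap %.3g", n_multisets, cap),
         call. = FALSE)
  v <- sort(scale_values)
  sums <- sort(.multiset_sums(v, I))
  means <- sums / I
  keep <- c(TRUE, diff(means) > tol)
  structure(list(values = means[keep], I = I, tol = tol, scale_tag = scale_tag),
            class = "possible_means")
}

# all sums over nondecreasing index tuples of length I (multisets)
.multiset_sums <- function(v, I) {
  if (I == 1L) return(v)
  n <- length(v)
  unlist(lapply(seq_len(n), function(i)
    v[i] + .multiset_sums(v[i:n], I - 1L)), use.names = FALSE)
}

#' @export
print.possible_means <- function(x, ...) {
  tag <- if (is.null(x$scale_tag)) "" else sprintf(" [%s]", x$scale_tag)
  cat(sprintf("Set of %d possible means of I = %d item responses%s\n",
              length(x$values), x$I, tag))
  print(x$values)
  invisible(x)
}

#' @export
as.data.frame.possible_means <- function(x, ...) {
  data.frame(scale_tag = if (is.null(x$scale_tag)) NA_character_ else x$scale_tag,
             I = x$I, value = x$values, stringsAsFactors = FALSE)
}

#' Map a star-scale mean to the corresponding original-scale mean
#'
#' The category-to-star map is affine (`x* = lLOQ + sw * (s - 1)`), so means
#' of item responses correspond one-to-one across the two scales:
#' a star-scale mean `m` represents the original-scale mean
#' `1 + (m - lLOQ) / sw`.
#'
#' @param star_mean Numeric vector of star-scale means.
#' @param scale A [star_scale()] object.
#' @return Numeric vector of original response-scale means, same shape as
#'   `star_mean`.
#' @examples
#' star_mean_to_rs_mean(73.75, star_scale(5, 0.05))  # 4
#' @export
star_mean_to_rs_mean <- function(star_mean, scale) {
  stopifnot(inherits(scale, "star_scale"))
  1 + (star_mean - scale$lLOQ) / scale$sw
}
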