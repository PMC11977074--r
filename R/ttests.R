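#' Unpaired two-sample t-test (Student or Welch)
#'
#' Tests `H0: mu_x - mu_y = 0` against the two-sided alternative. The
#' Student variant pools the variances (`df = n1 + n2 - 2`); the Welch
#' variant uses separate variances with Satterthwaite degrees of freedom.
#' In the simulation engine the Welch variant is selected from the
#' *population* variances of the data-generating processes, never from a
#' pre-test on the samples.
#'
#' Snapping can collapse a sample to a constant, so degenerate inputs have
#' defined conventions: if both samples have zero variance, `p = 1` when the
#' means agree and `p = 0` (infinite statistic) when they differ.
#'
#' @param x,y Numeric samples, each of length at least 2.
#' @param welch Use the Welch modification? Default `FALSE` (Student).
#' @param alpha Two-sided significance level, default 0.05.
#' @return Object of class `ilr_ttest`: list with `statistic`, `df`,
#'   `p_value`, `reject` (`p_value < alpha`), `alpha` and `method`.
#' @examples
#' t_unpaired(1:5, 2:6)
#' @export
t_unpaired <- function(x, y, welch = FALSE, alpha = 0.05) {
  .check_alpha(alpha)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("both samples need at least 2 values", call. = FALSE)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- if (se2 > 0)
      se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)) else NA_real_
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  .t_result(m1 - m2, se2, df, alpha,
            method = if (welch) "Welch unpaired t-test" else "Student unpaired t-test")
}

#' Paired two-sample t-test
#'
#' One-sample t-test of the pairwise differences against 0, `df = n - 1`,
#' two-sided. Degenerate conventions as in [t_unpaired()]: constant
#' differences give `p = 1` (mean 0) or `p = 0` (mean nonzero).
#'
#' @param x,y Paired numeric samples of equal length, at least 2.
#' @param alpha Two-sided significance level, default 0.05.
#' @return Object of class `ilr_ttest`; see [t_unpaired()].
#' @examples
#' t_paired(c(3, 2, 4, 2), c(1, 2, 2, 2))
#' @export
t_paired <- function(x, y, alpha = 0.05) {
  .check_alpha(alpha)
  if (length(x) != length(y)) stop("paired samples must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("paired samples need at least 2 pairs", call. = FALSE)
  d <- x - y
  .t_result(mean(d), stats::var(d) / n, n - 1, alpha, method = "Paired t-test")
}

.check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be a single number in (0, 1)", call. = FALSE)
}

.t_result <- function(diff, se2, df, alpha, method) {
  if (se2 > 0) {
    statistic <- diff / sqrt(se2)
    p <- 2 * stats::pt(-abs(statistic), df)
  } else if (diff == 0) {
    statistic <- 0; p <- 1
  } else {
    statistic <- sign(diff) * Inf; p <- 0
  }
  structure(list(statistic = statistic, df = df, p_value = p,
                 reject = p < alpha, alpha = alpha, method = method),
            class = "ilr_ttest")
}

#' @export
print.ilr_ttest <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  t = %.4f, df = %.3f, p = %.4g (%s H0 at alpha = %g)\n",
              x$statistic, x$df, x$p_value,
              if (x$reject) "reject" else "retain", x$alpha))
  invisible(x)
}

# --- column-vectorized internals used by the Monte-Carlo engine -------------
# Each column of A (and B) is one simulation run; returns the vector of
# two-sided p-values. One-pass column variances (values are bounded scale
# points, so cancellation is harmless); tiny negatives are clipped to 0 so
# the degenerate conventions engage.

.col_stats <- function(M) {
  n <- nrow(M)
  m <- colMeans(M)
  v <- pmax((colSums(M * M) - n * m * m) / (n - 1), 0)
  list(n = n, m = m, v = v)
}

.p_from <- function(diff, se2, df) {
  ok <- se2 > 0
  p <- numeric(length(diff))
  p[ok] <- 2 * stats::pt(-abs(diff[ok] / sqrt(se2[ok])),
                         if (length(df) > 1L) df[ok] else df)
  p[!ok] <- ifelse(diff[!ok] == 0, 1, 0)
  p
}

.t_cols_unpaired <- function(A, B, welch) {
  a <- .col_stats(A); b <- .col_stats(B)
  if (welch) {
    ta <- a$v / a$n; tb <- b$v / b$n
    se2 <- ta + tb
    df <- se2^2 / (ta^2 / (a$n - 1) + tb^2 / (b$n - 1))  # NaN when se2 = 0; unused there
  } else {
    sp2 <- ((a$n - 1) * a$v + (b$n - 1) * b$v) / (a$n + b$n - 2)
    se2 <- sp2 * (1 / a$n + 1 / b$n)
    df <- a$n + b$n - 2
  }
  .p_from(a$m - b$m, se2, df)
}

.t_cols_paired <- function(A, B) {
  D <- A - B
  d <- .col_stats(D)
  .p_from(d$m, d$v / d$n, d$n - 1)
}
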