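#' Aggregate power differences by a design factor
#'
#' Summarizes `delta_power` over all scenarios at each level of one design
#' factor using Tukey boxplot conventions: quartiles by linear interpolation
#' of order statistics (quantile type 7), whiskers at the most extreme
#' observations within 1.5 IQR of the box. `s2_total` is `s2_a + s2_b`; `N`
#' refers to the common group size `N1` of the replication design.
#'
#' @param results Data frame of scenario results from [run_grid()].
#' @param factor One of `"D_effect"`, `"p"`, `"s2_total"`, `"K"`, `"I"`,
#'   `"N"`.
#' @return Data frame with one row per factor level: `factor`, `level`,
#'   `n_scenarios`, `mean`, `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`.
#' @examples
#' g <- replication_grid("unpaired")[1:10, ]
#' aggregate_delta_power(run_grid(g, n_runs = 50), "K")
#' @export
aggregate_delta_power <- function(results,
                                  factor = c("D_effect", "p", "s2_total", "K",
                                             "I", "N")) {
  factor <- match.arg(factor)
  if (!is.data.frame(results) || nrow(results) == 0L)
    stop("`results` must be a non-empty data frame", call. = FALSE)
  if (!"delta_power" %in% names(results))
    stop("`results` must contain a `delta_power` column", call. = FALSE)
  if (!"s2_total" %in% names(results) && all(c("s2_a", "s2_b") %in% names(results)))
    results$s2_total <- results$s2_a + results$s2_b
  key <- if (factor == "N") "N1" else factor
  if (!key %in% names(results))
    stop(sprintf("`results` lacks column `%s`", key), call. = FALSE)
  lv <- sort(unique(results[[key]]))
  rows <- lapply(lv, function(l) {
    x <- results$delta_power[results[[key]] == l]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(factor = factor, level = l, n_scenarios = length(x),
               mean = mean(x), median = q[2], q1 = q[1], q3 = q[3],
               whisker_lo = min(x[x >= q[1] - 1.5 * iqr]),
               whisker_hi = max(x[x <= q[3] + 1.5 * iqr]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Structured findings report over a replication grid
#'
#' Recomputes, from a table of scenario results, the qualitative findings of
#' the power study:
#' \enumerate{
#'   \item the share of scenarios with `delta_power < 0` (ilr loses power in
#'     most scenarios);
#'   \item the effect-size level whose median `delta_power` is most negative
#'     (expected 0.4);
#'   \item whether the median |delta_power| decreases as the LOQ `p`
#'     increases;
#'   \item whether |delta_power| is near 0 (smallest) at the smallest total
#'     variance, and larger at the largest total variance than at the
#'     smallest (a direction claim: overall dispersion drives the loss);
#'   \item whether the spread of medians across `K` is small relative to the
#'     spread across `s2_total` (at most half, by convention);
#'   \item whether `I = 1` gives a more negative median `delta_power` than
#'     every `I >= 2` level.
#' }
#'
#' @param results Data frame of scenario results from [run_grid()], normally
#'   the full [replication_grid()]; partial grids are refused unless
#'   `force = TRUE`.
#' @param force Evaluate a partial grid anyway (with a warning).
#' @return Object of class `power_findings`: list of the quantities and
#'   booleans above plus the per-factor median tables used to compute them.
#' @export
findings_report <- function(results, force = FALSE) {
  if (!is.data.frame(results) || nrow(results) == 0L)
    stop("`results` must be a non-empty data frame", call. = FALSE)
  if (!"s2_total" %in% names(results))
    results$s2_total <- results$s2_a + results$s2_b
  full_levels <- list(D_effect = c(0.2, 0.4, 0.6, 0.8, 1.0),
                      p = c(0.05, 0.1, 0.2),
                      s2_total = c(0.16, 0.4, 0.64, 0.8, 1.04, 1.36, 1.44, 1.6, 2, 2.56),
                      K = c(4, 5, 6), I = c(1, 2, 4, 6))
  missing_lv <- vapply(names(full_levels), function(f) {
    key <- if (f == "N") "N1" else f
    !all(full_levels[[f]] %in% round(unique(results[[key]]), 9))
  }, logical(1))
  if (any(missing_lv)) {
    msg <- sprintf("results do not cover the full replication grid (incomplete: %s)",
                   paste(names(full_levels)[missing_lv], collapse = ", "))
    if (!force) stop(msg, " -- pass force = TRUE to evaluate anyway", call. = FALSE)
    warning(msg, call. = FALSE)
  }
  med_by <- function(key) {
    lv <- sort(unique(results[[key]]))
    data.frame(level = lv,
               median = vapply(lv, function(l)
                 stats::median(results$delta_power[results[[key]] == l]), numeric(1)),
               median_abs = vapply(lv, function(l)
                 stats::median(abs(results$delta_power[results[[key]] == l])), numeric(1)))
  }
  by_D <- med_by("D_effect"); by_p <- med_by("p")
  by_s2 <- med_by("s2_total"); by_K <- med_by("K"); by_I <- med_by("I")
  share_negative <- mean(results$delta_power < 0)
  argmin_D <- by_D$level[which.min(by_D$median)]
  i1 <- by_I$median[by_I$level == 1]
  range_K <- diff(range(by_K$median))
  range_s2 <- diff(range(by_s2$median))
  structure(list(
    share_negative = share_negative,
    majority_negative = share_negative > 0.5,
    argmin_D = argmin_D,
    p_monotone_decreasing = all(diff(by_p$median_abs) < 0),
    s2_smallest_at_min = which.min(by_s2$median_abs) == 1L,
    s2_max_exceeds_min = by_s2$median_abs[nrow(by_s2)] > by_s2$median_abs[1L],
    K_spread = range_K,
    s2_spread = range_s2,
    K_effect_small = range_K <= 0.5 * range_s2,
    I1_most_negative = length(i1) == 1 && all(i1 < by_I$median[by_I$level > 1]),
    medians = list(D_effect = by_D, p = by_p, s2_total = by_s2, K = by_K, I = by_I)),
    class = "power_findings")
}

#' @export
print.power_findings <- function(x, ...) {
  ok <- function(b) if (isTRUE(b)) "yes" else "NO"
  cat("Findings over the scenario grid\n")
  cat(sprintf("  share of scenarios with DeltaPower < 0 : %.3f (majority: %s)\n",
              x$share_negative, ok(x$majority_negative)))
  cat(sprintf("  most negative median DeltaPower at D   : %g\n", x$argmin_D))
  cat(sprintf("  median |DeltaPower| decreases in p     : %s\n",
              ok(x$p_monotone_decreasing)))
  cat(sprintf("  |DeltaPower| smallest at min s2_total  : %s, max level > min level: %s\n",
              ok(x$s2_smallest_at_min), ok(x$s2_max_exceeds_min)))
  cat(sprintf("  K effect small vs s2 effect            : %s (%.4f vs %.4f)\n",
              ok(x$K_effect_small), x$K_spread, x$s2_spread))
  cat(sprintf("  I = 1 more negative than I >= 2        : %s\n",
              ok(x$I1_most_negative)))
  invisible(x)
}
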