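#' Define one simulation scenario
#'
#' Bundles and validates the parameters of one Monte-Carlo power scenario:
#' scale geometry (`K`, `p`, `I`), design (`test_type`, `N1`, `N2`), the
#' data-generating process (`s2_a <= s2_b`, `D_effect`, `dgp`) and the test
#' level. Group a carries the smaller variance and the positive location
#' `+D * sqrt((s2_a + s2_b)/2) / 2`; group b the mirrored negative location.
#'
#' @param test_type `"unpaired"` or `"paired"`. Paired designs require
#'   `N1 == N2`; the two groups are sampled independently (no within-pair
#'   correlation is induced).
#' @param K Number of response categories (>= 2).
#' @param p Limit of quantification in (0, 1).
#' @param I Number of items averaged per simulated respondent mean.
#' @param N1,N2 Group sample sizes (>= 2); `N2` defaults to `N1`.
#' @param s2_a,s2_b Population variances of the two DGPs, `s2_a <= s2_b`;
#'   `s2_b` defaults to `s2_a`.
#' @param D_effect Standardized effect size (Cohen's d / d_z grid value).
#' @param alpha Two-sided significance level, default 0.05.
#' @param n_runs Monte-Carlo repetitions, default 1000.
#' @param seed RNG seed for this scenario, default 1.
#' @param dgp `"laplace"` (heavy-tailed study condition, variance `2 b^2`)
#'   or `"normal"` (comparison mode with matched mean and variance).
#' @return Object of class `scenario_params` (a validated list).
#' @examples
#' scenario("unpaired", K = 5, p = 0.05, I = 2, N1 = 50,
#'          s2_a = 0.32, D_effect = 0.4, n_runs = 200)
#' @export
scenario <- function(test_type = c("unpaired", "paired"), K, p, I, N1, N2 = N1,
                     s2_a, s2_b = s2_a, D_effect, alpha = 0.05, n_runs = 1000,
                     seed = 1L, dgp = c("laplace", "normal")) {
  test_type <- match.arg(test_type)
  dgp <- match.arg(dgp)
  if (test_type == "paired" && N1 != N2)
    stop("paired scenarios require N1 == N2", call. = FALSE)
  if (s2_a > s2_b)
    stop("`s2_a` must not exceed `s2_b` (the smaller variance is group a's)",
         call. = FALSE)
  if (N1 < 2 || N2 < 2 || N1 != round(N1) || N2 != round(N2))
    stop("sample sizes must be integers >= 2", call. = FALSE)
  if (n_runs < 1 || n_runs != round(n_runs))
    stop("`n_runs` must be a positive integer", call. = FALSE)
  .check_alpha(alpha)
  if (!is.finite(D_effect) || D_effect < 0)
    stop("`D_effect` must be non-negative", call. = FALSE)
  # delegate remaining validation
  star_scale(K, p)
  if (I < 1 || I != round(I)) stop("`I` must be a positive integer", call. = FALSE)
  structure(list(test_type = test_type, K = as.integer(K), p = p, I = as.integer(I),
                 N1 = as.integer(N1), N2 = as.integer(N2),
                 s2_a = s2_a, s2_b = s2_b, D_effect = D_effect, alpha = alpha,
                 n_runs = as.integer(n_runs), seed = as.integer(seed), dgp = dgp),
            class = "scenario_params")
}

#' Run one Monte-Carlo power scenario
#'
#' For each of `n_runs` repetitions, draws `N1` simulated ilr-scale means
#' from the group-a DGP and `N2` from group b, snaps every value along both
#' analysis paths ([snap_both_paths()]), applies the test to the ilr-snapped
#' dataset and to the original-scale dataset (Welch replaces Student for the
#' unpaired test iff the population variances differ), and estimates
#' `Power^ilr` and `Power^orig` as the two rejection proportions, with
#' `delta_power = power_ilr - power_orig`.
#'
#' Fresh data are drawn for both groups in every run; results are a
#' deterministic function of the scenario seed.
#'
#' @param sc A [scenario()] object.
#' @return Object of class `power_result`: list with `power_ilr`,
#'   `power_orig`, `delta_power`, `n_runs` and the `scenario`. Coerce with
#'   `as.data.frame()` for the standard one-row table.
#' @examples
#' sc <- scenario("unpaired", K = 5, p = 0.05, I = 2, N1 = 50,
#'                s2_a = 1.28, D_effect = 0.4, n_runs = 100, seed = 7)
#' run_scenario(sc)
#' @export
run_scenario <- function(sc) {
  stopifnot(inherits(sc, "scenario_params"))
  set.seed(sc$seed)
  scale <- star_scale(sc$K, sc$p)
  spm_ilr <- possible_means(ilr_scale(scale), sc$I, scale_tag = "ILR")
  spm_star <- possible_means(scale$values, sc$I, scale_tag = "RS*")
  loc <- effect_to_locations(sc$D_effect, sc$s2_a, sc$s2_b)
  R <- sc$n_runs
  gen <- function(n, mu, s2) {
    if (sc$dgp == "laplace") rlaplace(n, mu, b_from_variance(s2))
    else stats::rnorm(n, mu, sqrt(s2))
  }
  A <- matrix(gen(sc$N1 * R, loc[["mu_a"]], sc$s2_a), nrow = sc$N1)
  B <- matrix(gen(sc$N2 * R, loc[["mu_b"]], sc$s2_b), nrow = sc$N2)
  sa <- snap_both_paths(A, scale, sc$I, spm_ilr, spm_star)
  sb <- snap_both_paths(B, scale, sc$I, spm_ilr, spm_star)
  if (sc$test_type == "paired") {
    p_ilr <- .t_cols_paired(sa$mu_ilr, sb$mu_ilr)
    p_orig <- .t_cols_paired(sa$mu_orig, sb$mu_orig)
  } else {
    welch <- sc$s2_a != sc$s2_b
    p_ilr <- .t_cols_unpaired(sa$mu_ilr, sb$mu_ilr, welch)
    p_orig <- .t_cols_unpaired(sa$mu_orig, sb$mu_orig, welch)
  }
  power_ilr <- mean(p_ilr < sc$alpha)
  power_orig <- mean(p_orig < sc$alpha)
  structure(list(power_ilr = power_ilr, power_orig = power_orig,
                 delta_power = power_ilr - power_orig,
                 n_runs = R, scenario = sc),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf("%s | K=%d p=%g I=%d N1=%d N2=%d s2=(%g,%g) D=%g | %d runs\n",
              sc$test_type, sc$K, sc$p, sc$I, sc$N1, sc$N2,
              sc$s2_a, sc$s2_b, sc$D_effect, x$n_runs))
  cat(sprintf("  Power^ilr = %.4f  Power^orig = %.4f  DeltaPower = %+.4f\n",
              x$power_ilr, x$power_orig, x$delta_power))
  invisible(x)
}

#' @export
as.data.frame.power_result <- function(x, ...) {
  sc <- x$scenario
  data.frame(test_type = sc$test_type, K = sc$K, p = sc$p, I = sc$I,
             N1 = sc$N1, N2 = sc$N2, s2_a = sc$s2_a, s2_b = sc$s2_b,
             s2_total = sc$s2_a + sc$s2_b, D_effect = sc$D_effect,
             alpha = sc$alpha, n_runs = x$n_runs, seed = sc$seed,
             power_ilr = x$power_ilr, power_orig = x$power_orig,
             delta_power = x$delta_power, stringsAsFactors = FALSE)
}

# deterministic per-scenario substream seed; multipliers keep the arithmetic
# exact in doubles and the results inside the 32-bit integer range
scenario_seed <- function(master_seed, index) {
  as.integer(((as.double(master_seed) %% 2147483647) * 69069 +
                as.double(index) * 104729) %% 2147483647)
}

#' Run a grid of scenarios
#'
#' Executes [run_scenario()] for every row of a scenario grid, deriving an
#' independent deterministic substream seed per scenario from `master_seed`.
#' Identical `(grid, master_seed)` inputs reproduce identical tables.
#'
#' @param grid Data frame with columns `test_type`, `K`, `p`, `I`, `N1`,
#'   `N2`, `s2_a`, `s2_b`, `D_effect` (e.g. from [replication_grid()]).
#'   Optional columns `alpha` and `n_runs` override the arguments row-wise.
#' @param master_seed Master seed for the whole grid, default 1.
#' @param n_runs Monte-Carlo repetitions per scenario, default 1000.
#' @param alpha Significance level, default 0.05.
#' @param dgp `"laplace"` or `"normal"`, default `"laplace"`.
#' @param permissive If `TRUE`, invalid grid rows are reported with their
#'   index and skipped instead of aborting the grid. Default `FALSE`.
#' @param verbose Print per-scenario progress (index and substream seed).
#' @return Data frame with one row per scenario: the scenario columns plus
#'   `s2_total`, `alpha`, `n_runs`, `seed`, `power_ilr`, `power_orig`,
#'   `delta_power`.
#' @examples
#' g <- replication_grid("unpaired")[1:3, ]
#' run_grid(g, master_seed = 1, n_runs = 50)
#' @export
run_grid <- function(grid, master_seed = 1L, n_runs = 1000, alpha = 0.05,
                     dgp = "laplace", permissive = FALSE, verbose = FALSE) {
  empty <- as.data.frame(structure(list(
    power_ilr = 1, power_orig = 1, delta_power = 0, n_runs = 1L,
    scenario = scenario("unpaired", K = 2, p = 0.5, I = 1, N1 = 2,
                        s2_a = 1, D_effect = 0, n_runs = 1)),
    class = "power_result"))[0, ]
  if (nrow(grid) == 0L) return(empty)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    seed_i <- scenario_seed(master_seed, i)
    sc <- tryCatch(
      scenario(test_type = as.character(g$test_type), K = g$K, p = g$p, I = g$I,
               N1 = g$N1, N2 = if ("N2" %in% names(g)) g$N2 else g$N1,
               s2_a = g$s2_a, s2_b = if ("s2_b" %in% names(g)) g$s2_b else g$s2_a,
               D_effect = g$D_effect,
               alpha = if ("alpha" %in% names(g)) g$alpha else alpha,
               n_runs = if ("n_runs" %in% names(g)) g$n_runs else n_runs,
               seed = seed_i, dgp = dgp),
      error = function(e) {
        if (!permissive) stop(sprintf("grid row %d: %s", i, conditionMessage(e)),
                              call. = FALSE)
        warning(sprintf("skipping grid row %d: %s", i, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (is.null(sc)) next
    if (verbose)
      message(sprintf("scenario %d/%d (seed %d)", i, nrow(grid), seed_i))
    rows[[i]] <- as.data.frame(run_scenario(sc))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reconstructed replication scenario grid
#'
#' The full factorial grid of the simulation study:
#' `K` in \{4, 5, 6\}, `p` in \{0.05, 0.1, 0.2\}, `I` in \{1, 2, 4, 6\},
#' `N1 = N2` in \{50, 100\}, the 10 unordered variance pairs
#' `s2_a <= s2_b` from \{0.08, 0.32, 0.72, 1.28\}, and effect sizes
#' `D` in \{0.2, 0.4, 0.6, 0.8, 1\} -- 3600 scenarios per test type.
#'
#' @param test_type `"unpaired"` or `"paired"`.
#' @return Data frame of 3600 scenario rows suitable for [run_grid()].
#' @examples
#' nrow(replication_grid("unpaired"))  # 3600
#' @export
replication_grid <- function(test_type = c("unpaired", "paired")) {
  test_type <- match.arg(test_type)
  vs <- c(0.08, 0.32, 0.72, 1.28)
  idx <- which(outer(vs, vs, "<="), arr.ind = TRUE)  # s2_a <= s2_b, 10 pairs
  pairs <- data.frame(s2_a = vs[idx[, "row"]], s2_b = vs[idx[, "col"]])
  pairs <- pairs[order(pairs$s2_a, pairs$s2_b), ]
  g <- expand.grid(K = c(4L, 5L, 6L), p = c(0.05, 0.1, 0.2),
                   I = c(1L, 2L, 4L, 6L), N = c(50L, 100L),
                   pair = seq_len(nrow(pairs)),
                   D_effect = c(0.2, 0.4, 0.6, 0.8, 1.0),
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(test_type = test_type, K = g$K, p = g$p, I = g$I,
             N1 = g$N, N2 = g$N,
             s2_a = pairs$s2_a[g$pair], s2_b = pairs$s2_b[g$pair],
             D_effect = g$D_effect, stringsAsFactors = FALSE)
}
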