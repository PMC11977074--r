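test_that("scenario parameters are validated", {
  expect_error(scenario("paired", K = 5, p = 0.05, I = 2, N1 = 50, N2 = 100,
                        s2_a = 0.32, D_effect = 0.4), "N1 == N2")
  expect_error(scenario("unpaired", K = 5, p = 0.05, I = 2, N1 = 50,
                        s2_a = 1.28, s2_b = 0.08, D_effect = 0.4), "s2_a")
  expect_error(scenario("unpaired", K = 5, p = 0.05, I = 2, N1 = 1,
                        s2_a = 0.32, D_effect = 0.4), "sample sizes")
  expect_error(scenario("unpaired", K = 5, p = 2, I = 2, N1 = 50,
                        s2_a = 0.32, D_effect = 0.4), "p")
  expect_error(scenario("unpaired", K = 5, p = 0.05, I = 2, N1 = 50,
                        s2_a = 0.32, D_effect = -1), "non-negative")
})

test_that("identical seeds reproduce identical power estimates", {
  sc <- scenario("unpaired", K = 5, p = 0.1, I = 2, N1 = 50, s2_a = 0.32,
                 s2_b = 0.72, D_effect = 0.6, n_runs = 100, seed = 99)
  r1 <- run_scenario(sc)
  r2 <- run_scenario(sc)
  expect_identical(r1$power_ilr, r2$power_ilr)
  expect_identical(r1$power_orig, r2$power_orig)
  expect_equal(r1$delta_power, r1$power_ilr - r1$power_orig)
  # proportions are multiples of 1/n_runs
  expect_equal(r1$power_ilr * 100, round(r1$power_ilr * 100))

  g <- replication_grid("unpaired")[c(1, 500, 3600), ]
  t1 <- run_grid(g, master_seed = 5, n_runs = 60)
  t2 <- run_grid(g, master_seed = 5, n_runs = 60)
  expect_identical(t1, t2)
  t3 <- run_grid(g, master_seed = 6, n_runs = 60)
  expect_false(identical(t1$power_ilr, t3$power_ilr))
})

test_that("empty grids yield empty result tables with the standard columns", {
  out <- run_grid(replication_grid("unpaired")[0, ])
  expect_equal(nrow(out), 0)
  expect_true(all(c("test_type", "K", "p", "I", "N1", "N2", "s2_a", "s2_b",
                    "s2_total", "D_effect", "alpha", "n_runs", "seed",
                    "power_ilr", "power_orig", "delta_power") %in% names(out)))
})

test_that("the reconstructed replication grid has the documented structure", {
  for (tt in c("unpaired", "paired")) {
    g <- replication_grid(tt)
    expect_equal(nrow(g), 3600)
    expect_setequal(unique(g$K), c(4, 5, 6))
    expect_setequal(unique(g$p), c(0.05, 0.1, 0.2))
    expect_setequal(unique(g$I), c(1, 2, 4, 6))
    expect_setequal(unique(g$N1), c(50, 100))
    expect_true(all(g$N1 == g$N2))
    expect_true(all(g$s2_a <= g$s2_b))
    expect_equal(nrow(unique(g[, c("s2_a", "s2_b")])), 10)
    expect_setequal(unique(g$D_effect), c(0.2, 0.4, 0.6, 0.8, 1))
    expect_equal(anyDuplicated(g[, -1]), 0)
  }
})

test_that("rejection rates stay near alpha under the null", {
  R <- 2000
  band <- 3 * sqrt(0.05 * 0.95 / R)
  for (cfg in list(list(tt = "unpaired", s2b = 0.32),   # Student
                   list(tt = "unpaired", s2b = 1.28),   # Welch
                   list(tt = "paired", s2b = 0.32))) {
    r <- run_scenario(scenario(cfg$tt, K = 5, p = 0.1, I = 2, N1 = 100,
                               s2_a = 0.32, s2_b = cfg$s2b, D_effect = 0,
                               n_runs = R, seed = 314))
    expect_lt(abs(r$power_ilr - 0.05), band)
    expect_lt(abs(r$power_orig - 0.05), band)
  }
})

test_that("power increases with effect size on both paths", {
  lo <- run_scenario(scenario("unpaired", K = 5, p = 0.1, I = 2, N1 = 50,
                              s2_a = 0.32, D_effect = 0.2, n_runs = 400, seed = 8))
  hi <- run_scenario(scenario("unpaired", K = 5, p = 0.1, I = 2, N1 = 50,
                              s2_a = 0.32, D_effect = 1, n_runs = 400, seed = 9))
  expect_gt(hi$power_ilr, lo$power_ilr + 0.2)
  expect_gt(hi$power_orig, lo$power_orig + 0.2)
})

test_that("heavy tails reverse the sign of the power difference seen under normality", {
  base <- list(K = 5, p = 0.05, I = 2, N1 = 100, s2_a = 1.28, D_effect = 0.4,
               n_runs = 1000)
  lap <- run_scenario(scenario("unpaired", K = base$K, p = base$p, I = base$I,
                               N1 = base$N1, s2_a = base$s2_a,
                               D_effect = base$D_effect, n_runs = base$n_runs,
                               seed = 21, dgp = "laplace"))
  expect_lt(lap$delta_power, 0)
  nor <- run_scenario(scenario("unpaired", K = base$K, p = base$p, I = base$I,
                               N1 = base$N1, s2_a = base$s2_a,
                               D_effect = base$D_effect, n_runs = base$n_runs,
                               seed = 21, dgp = "normal"))
  expect_gte(nor$delta_power, 0)
})

test_that("invalid grid rows abort, or are skipped when permissive", {
  g <- replication_grid("unpaired")[1:3, ]
  g$s2_b[2] <- 0.01  # violates s2_a <= s2_b
  expect_error(run_grid(g, n_runs = 30), "grid row 2")
  expect_warning(out <- run_grid(g, n_runs = 30, permissive = TRUE),
                 "skipping grid row 2")
  expect_equal(nrow(out), 2)
})
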