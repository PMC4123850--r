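# Trajectory simulation and learning curves.  Problem sizes here are small
# (few hundred paths, short horizons, coarse policy grids); the learning
# orderings at the reference scale are exercised in the acceptance tests.

small_case <- function(case = "pr_known", n_sites = 6) {
  p <- site_params(n_sites = n_sites)
  uncertainty_case(case, p)
}

solve_small <- function(case_obj, mode, order = 8) {
  solve_active(case_kernels(case_obj, mode), belief_grid(order))
}

test_that("ensembles are reproducible and well-formed", {
  case <- small_case()
  sol <- solve_small(case, "full")
  e1 <- simulate_ensemble(sol, case, true_model = 2, n_paths = 50,
                          n_years = 10, init_occupancy = 5, seed = 42)
  e2 <- simulate_ensemble(sol, case, true_model = 2, n_paths = 50,
                          n_years = 10, init_occupancy = 5, seed = 42)
  expect_identical(e1$paths, e2$paths)
  p <- e1$paths
  expect_true(all(p$S >= 0 & p$S <= 6))
  expect_true(all(p$A[!is.na(p$A)] <= p$S[!is.na(p$A)]))
  b <- as.matrix(p[, c("b1", "b2", "b3")])
  expect_true(all(abs(rowSums(b) - 1) < 1e-9))
  # year-0 belief is the prior, exactly
  expect_true(all(b[p$year == 0, ] == 1 / 3))
  # a different seed moves the draws
  e3 <- simulate_ensemble(sol, case, true_model = 2, n_paths = 50,
                          n_years = 10, init_occupancy = 5, seed = 43)
  expect_false(identical(e1$paths$S, e3$paths$S))
})

test_that("expected paths average the ensemble; a single path is itself", {
  case <- small_case()
  sol <- solve_small(case, "full")
  e <- simulate_ensemble(sol, case, true_model = 3, n_paths = 1,
                         n_years = 5, init_occupancy = 4, seed = 9)
  bp <- expected_belief_paths(e)
  expect_equal(bp$mean_b3, e$paths$b3)
  expect_equal(bp$year, 0:5)
  e2 <- simulate_ensemble(sol, case, true_model = 3, n_paths = 40,
                          n_years = 5, init_occupancy = 4, seed = 9)
  bp2 <- expected_belief_paths(e2)
  expect_equal(bp2$mean_b1[1], 1 / 3)
  expect_equal(bp2$mean_b2[3],
               mean(e2$paths$b2[e2$paths$year == 2]))
})

test_that("with p_n = p_s the no-signal updater never moves beliefs", {
  p <- site_params(n_sites = 6, p_n = 0.95, p_s = 0.95)
  case <- uncertainty_case("pr_known", p)
  sol <- solve_small(case, "none")
  e <- simulate_ensemble(sol, case, true_model = 3, n_paths = 30,
                         n_years = 15, init_occupancy = 5, seed = 3)
  b <- as.matrix(e$paths[, c("b1", "b2", "b3")])
  expect_true(all(abs(b - 1 / 3) < 1e-12))
})

test_that("mean weight on the true model is a submartingale and the full signal learns faster", {
  case <- small_case("pr_known")
  sol_f <- solve_small(case, "full")
  sol_t <- solve_small(case, "total")
  ef <- simulate_ensemble(sol_f, case, true_model = 3, n_paths = 400,
                          n_years = 40, init_occupancy = 5, seed = 21)
  et <- simulate_ensemble(sol_t, case, true_model = 3, n_paths = 400,
                          n_years = 40, init_occupancy = 5, seed = 21)
  bf <- expected_belief_paths(ef)
  bt <- expected_belief_paths(et)
  # nondecreasing in expectation, within Monte-Carlo noise
  expect_true(all(diff(bf$mean_b3) > -4 * bf$se_b3[-1] - 1e-9))
  # faster learning with the richer signal at the horizon
  n_yr <- nrow(bf)
  expect_gt(bf$mean_b3[n_yr],
            bt$mean_b3[n_yr] - 2 * sqrt(bf$se_b3[n_yr]^2 + bt$se_b3[n_yr]^2))
})

test_that("belief updating agrees with the kernel-based Bayes rule", {
  # one simulated year, recomputed observation-by-observation
  case <- small_case("both_uncertain", n_sites = 4)
  for (mode in c("full", "unrestricted_only", "restricted_only",
                 "total", "none")) {
    sol <- solve_active(case_kernels(case, mode), belief_grid(6))
    e <- simulate_ensemble(sol, case, true_model = 1, n_paths = 12,
                           n_years = 1, init_occupancy = 3, seed = 8)
    ks <- case_kernels(case, mode)
    p0 <- e$paths[e$paths$year == 0, ]
    p1 <- e$paths[e$paths$year == 1, ]
    for (i in seq_len(nrow(p0))) {
      Y <- switch(mode,
        full = c(p0$Y1[i], p0$Y2[i]),
        unrestricted_only = p0$Y1[i],
        restricted_only = p0$Y2[i],
        total = p0$Y1[i] + p0$Y2[i],
        none = NULL)
      ref <- belief_update(rep(1 / 3, 3), ks, p0$S[i], p0$A[i], Y, p1$S[i])
      expect_equal(unlist(p1[i, c("b1", "b2", "b3")]), ref,
                   tolerance = 1e-10, ignore_attr = TRUE)
    }
  }
})

test_that("a policy from one mode cannot be paired with another updater", {
  case <- small_case()
  sol <- solve_small(case, "full")
  expect_error(simulate_ensemble(sol, case, 1, n_paths = 2, n_years = 2,
                                 mode = "none"),
               "mismatch")
})

test_that("ensemble CSV export writes paths, summary and config", {
  case <- small_case()
  sol <- solve_small(case, "full")
  e <- simulate_ensemble(sol, case, 2, n_paths = 5, n_years = 3,
                         init_occupancy = 4, seed = 1)
  dir <- withr::local_tempdir()
  f <- file.path(dir, "ens.csv")
  write_ensemble_csv(e, f)
  expect_true(file.exists(f))
  expect_true(file.exists(file.path(dir, "ens_summary.csv")))
  cfg <- readLines(file.path(dir, "ens.config.txt"))
  expect_true(any(grepl("seed = 1", cfg)))
  back <- read.csv(f)
  expect_equal(nrow(back), 5 * 4)
})
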