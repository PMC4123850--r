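# Category-count aggregation to N sites: assignment enumeration, the joint
# kernel, and signal garbling.

test_that("assignment enumeration matches stars-and-bars", {
  a2 <- enumerate_assignments(2, 4)
  expect_equal(nrow(a2), 10L)
  # two distinct assignments share the signal/next-state pair (1, 1)
  both <- a2[a2$Y == 1 & a2$S_next == 1, c("NE", "SE", "NO", "SO")]
  expect_equal(nrow(both), 2L)
  expect_true(all(apply(both, 1, paste, collapse = "") %in%
                    c("0110", "1001")))
  expect_equal(nrow(enumerate_assignments(0, 4)), 1L)
  expect_equal(enumerate_assignments(0, 4)[, c("Y", "S_next")],
               data.frame(Y = 0L, S_next = 0L), ignore_attr = TRUE)
  expect_equal(nrow(enumerate_assignments(3, 4)), 20L)
  for (n in 0:5) {
    for (k in 1:4) {
      expect_equal(nrow(enumerate_assignments(n, k)),
                   choose(n + k - 1, k - 1))
    }
  }
})

test_that("kernel columns are distributions over the feasible cells", {
  set.seed(7)
  for (rep in 1:5) {
    params <- site_params(p_c = runif(1), p_n = runif(1), p_s = runif(1),
                          n_sites = 5)
    probs <- success_probs(runif(1), runif(1))
    k <- build_kernel(params, probs)
    df <- as.data.frame(k)
    sums <- tapply(df$prob, paste(df$S, df$A), sum)
    expect_true(all(abs(sums - 1) < 1e-12))
    expect_true(all(df$Y1 <= df$S - df$A & df$Y2 <= df$A))
  }
})

test_that("category-count kernel equals exhaustive per-site enumeration", {
  params <- site_params(n_sites = 3)
  probs <- success_probabilities(params)
  k <- build_kernel(params, probs)
  for (S in 0:3) {
    for (A in 0:S) {
      expect_column_matches_oracle(k, probs, params, S, A)
    }
  }
})

test_that("infeasible actions are rejected", {
  params <- site_params(n_sites = 2)
  k <- build_kernel(params, printed_moderate_probs())
  expect_error(kernel_column(k, 1, 2), "infeasible")
  expect_error(assignment_table(printed_moderate_probs(), params, 1, 2),
               "infeasible")
})

test_that("unsummed assignment contributions add up to the kernel cell", {
  params <- site_params(n_sites = 2)
  probs <- printed_moderate_probs()
  at <- assignment_table(probs, params, S = 1, A = 0)
  contrib <- at$prob[at$Y1 == 1 & at$S_next == 1]
  # one success that is not re-occupied while the empty site is colonized,
  # versus a re-occupied success with no colonization
  expect_equal(sort(round(contrib, 3)), c(0.004, 0.298))
  k <- garble(build_kernel(params, probs), "unrestricted_only")
  cell <- kernel_column(k, 1, 0)
  expect_equal(cell$prob[cell$Y1 == 1 & cell$S_next == 1], sum(contrib),
               tolerance = 1e-12)
  # same check for the two-occupied column
  at2 <- assignment_table(probs, params, S = 2, A = 0)
  contrib2 <- at2$prob[at2$Y1 == 1 & at2$S_next == 1]
  expect_equal(sort(round(contrib2, 3)), c(0.019, 0.026))
})

test_that("garbling sums signal cells and rejects refinement", {
  params <- site_params(n_sites = 2)
  probs <- printed_moderate_probs()
  k <- build_kernel(params, probs)
  expect_identical(garble(k, "full"), k)
  kt <- garble(k, "total")
  c21 <- kernel_column(kt, 2, 1)
  full21 <- kernel_column(k, 2, 1)
  expect_equal(c21$prob[c21$Y1 == 1 & c21$S_next == 2],
               sum(full21$prob[full21$Y1 + full21$Y2 == 1 &
                                 full21$S_next == 2]),
               tolerance = 1e-14)
  expect_error(garble(kt, "full"), "cannot refine")
  expect_error(garble(garble(k, "none"), "total"), "cannot refine")
  # restricted-only keeps Y2
  kr <- garble(k, "restricted_only")
  c11 <- kernel_column(kr, 1, 1)
  expect_true(all(!is.na(c11$Y2)) && all(is.na(c11$Y1)))
  expect_equal(sum(c11$prob), 1, tolerance = 1e-14)
})

test_that("no-signal garbling equals the binomial-convolution transition", {
  params <- site_params(n_sites = 4)
  probs <- success_probabilities(params)
  kn <- garble(build_kernel(params, probs), "none")
  tr <- state_transition(probs, params)
  for (S in 0:4) {
    for (A in 0:S) {
      col <- kernel_column(kn, S, A)
      # direct convolution of per-group occupied-next binomials
      direct <- nestadapt:::.conv(
        dbinom(0:(S - A), S - A, tr["occupied_next", "occupied_unrestricted"]),
        dbinom(0:A, A, tr["occupied_next", "occupied_restricted"]))
      direct <- nestadapt:::.conv(
        direct, dbinom(0:(4 - S), 4 - S, params$p_c))
      expect_equal(col$prob[order(col$S_next)], direct, tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
})

test_that("simulated outcome frequencies match the kernel column", {
  set.seed(99)
  params <- site_params(n_sites = 6)
  probs <- success_probabilities(params)
  k <- build_kernel(params, probs)
  col <- kernel_column(k, S = 4, A = 2)
  col <- col[col$prob > 0, ]
  n <- 1e5
  # sample via the same group-binomial scheme the simulator uses
  y1 <- rbinom(n, 2, probs$p_u)
  y2 <- rbinom(n, 2, probs$p_r)
  snx <- rbinom(n, y1 + y2, params$p_s) +
    rbinom(n, 4 - y1 - y2, params$p_n) + rbinom(n, 2, params$p_c)
  key <- paste(y1, y2, snx)
  obs <- table(factor(key, levels = paste(col$Y1, col$Y2, col$S_next)))
  gof <- suppressWarnings(chisq.test(obs, p = col$prob, rescale.p = TRUE))
  expect_gt(gof$p.value, 1e-3)
})

test_that("kernel CSV export round-trips", {
  params <- site_params(n_sites = 2)
  k <- build_kernel(params, printed_moderate_probs())
  f <- withr::local_tempfile(fileext = ".csv")
  write_kernel_csv(k, f)
  back <- read.csv(f)
  expect_named(back, c("S", "A", "Y1", "Y2", "S_next", "probability"))
  expect_equal(back$probability, as.data.frame(k)$prob)
})
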