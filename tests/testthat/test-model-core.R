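# Single-site probability model: logistic success probabilities, the joint
# event table and its marginals.

params_default <- site_params()

test_that("logistic success model reproduces the reference parameter table", {
  # all nine (p_u, p_r) pairs of the three assumption regimes at h = 9.4
  expected <- list(
    pr_known = rbind(c(0.454, 0.454), c(0.405, 0.454), c(0.313, 0.454)),
    both_uncertain = rbind(c(0.429, 0.429), c(0.405, 0.454), c(0.358, 0.479)),
    pu_known = rbind(c(0.405, 0.405), c(0.405, 0.454), c(0.405, 0.504))
  )
  # printed to 3 decimals; agreement within one unit in the last digit
  # (the table's own entries are rounded from fuller-precision estimates)
  for (cs in names(expected)) {
    sp <- case_success_probs(uncertainty_case(cs))
    got <- t(vapply(sp, function(x) c(x$p_u, x$p_r), numeric(2L)))
    expect_lt(max(abs(got - expected[[cs]])), 1e-3 + 1e-9, label = cs)
  }
})

test_that("zero disturbance coefficient forces p_u = p_r", {
  sp <- success_probabilities(params_default, 0)
  expect_identical(sp$p_u, sp$p_r)
})

test_that("success probability is increasing in hare index and disturbance", {
  hares <- c(0, 2.5, 9.4, 20, 32.5)
  pu_h <- vapply(hares, function(h) {
    success_probabilities(site_params(hare = h), -0.2)$p_u
  }, numeric(1L))
  expect_true(all(diff(pu_h) > 0))
  dists <- c(-0.8, -0.6, -0.3, -0.1, 0)
  pu_d <- vapply(dists, function(d) {
    success_probabilities(params_default, d)$p_u
  }, numeric(1L))
  expect_true(all(diff(pu_d) > 0))
})

test_that("event table columns are distributions with the structural zeros", {
  set.seed(41)
  for (rep in 1:20) {
    p <- site_params(p_c = runif(1), p_n = runif(1), p_s = runif(1))
    sp <- success_probs(runif(1), runif(1))
    et <- site_event_table(sp, p)
    ev <- attr(et, "events")
    expect_equal(colSums(et), c(1, 1, 1), ignore_attr = TRUE,
                 tolerance = 1e-12)
    # no success signal at an empty site
    expect_true(all(et[ev$Y1 + ev$Y2 > 0, "empty_unrestricted"] == 0))
    # Y2 impossible when unrestricted, Y1 impossible when restricted
    expect_true(all(et[ev$Y2 == 1, "occupied_unrestricted"] == 0))
    expect_true(all(et[ev$Y1 == 1, "occupied_restricted"] == 0))
  }
})

test_that("event table entries match the reference single-site matrix", {
  et <- site_event_table(printed_moderate_probs(), params_default)
  ev <- attr(et, "events")
  occ_u <- et[, "occupied_unrestricted"]
  # rows (no-success, empty), (no-success, occ), (Y1, empty), (Y1, occ)
  ulp <- 1e-3 + 1e-9  # one unit in the last printed digit
  expect_lt(abs(occ_u[ev$Y1 == 0 & ev$Y2 == 0 & ev$S_next == 0] - 0.034), ulp)
  expect_lt(abs(occ_u[ev$Y1 == 0 & ev$Y2 == 0 & ev$S_next == 1] - 0.561), ulp)
  expect_lt(abs(occ_u[ev$Y1 == 1 & ev$S_next == 0] - 0.017), ulp)
  expect_lt(abs(occ_u[ev$Y1 == 1 & ev$S_next == 1] - 0.388), ulp)
  expect_lt(abs(et[1, "empty_unrestricted"] - 0.769), ulp)
  expect_true(all(et[c(2, 3, 5, 6), "empty_unrestricted"] == 0))
  expect_lt(abs(sum(et[ev$S_next == 1, "empty_unrestricted"]) - 0.231), ulp)
  # p_u = 0 makes every unrestricted-success row impossible
  et0 <- site_event_table(success_probs(0, 0.454), params_default)
  expect_true(all(et0[ev$Y1 == 1, "occupied_unrestricted"] == 0))
})

test_that("state transition marginalizes the event table over signals", {
  sp <- printed_moderate_probs()
  tr <- state_transition(sp, params_default)
  et <- site_event_table(sp, params_default)
  ev <- attr(et, "events")
  expect_equal(tr["occupied_next", ],
               colSums(et[ev$S_next == 1, ]), tolerance = 1e-14)
  # closed forms
  with(params_default, {
    expect_equal(tr["occupied_next", "occupied_unrestricted"],
                 (1 - sp$p_u) * p_n + sp$p_u * p_s)
    expect_equal(round(tr["occupied_next", "occupied_restricted"], 3), 0.949)
    expect_equal(round(tr["occupied_next", "occupied_unrestricted"], 4),
                 0.9486)
  })
  # p_n = p_s removes all dependence on the action and success probabilities
  pns <- site_params(p_n = 0.9, p_s = 0.9)
  tr1 <- state_transition(success_probs(0.1, 0.9), pns)
  tr2 <- state_transition(success_probs(0.7, 0.2), pns)
  expect_equal(tr1, tr2, tolerance = 1e-14)
  expect_equal(tr1[, "occupied_unrestricted"], tr1[, "occupied_restricted"],
               ignore_attr = TRUE, tolerance = 1e-14)
})

test_that("outcome-conditional kernel composed with the garbling matrix gives the transition", {
  sp <- success_probabilities(params_default)
  sc <- signal_conditional_transition(params_default)
  expect_equal(sc["occupied_next", ],
               c(empty = params_default$p_c,
                 occupied_unsuccessful = params_default$p_n,
                 occupied_successful = params_default$p_s))
  expect_equal(unname(sc %*% outcome_garbling_matrix(sp)),
               unname(state_transition(sp, params_default)),
               tolerance = 1e-14)
  # p_n = p_s collapses the occupied columns
  sc2 <- signal_conditional_transition(site_params(p_n = 0.5, p_s = 0.5))
  expect_equal(sc2[, 2L], sc2[, 3L], ignore_attr = TRUE)
})

test_that("the packaged parameter file loads the published defaults", {
  p <- read_site_params(system.file("extdata", "eagle_params.txt",
                                    package = "nestadapt"))
  expect_equal(p, site_params())
})

test_that("plain-text parameter files round-trip", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# eagle defaults", "p_c = 0.2315", "p_n = 0.9427",
               "hare = 9.4", "n_sites = 25"), f)
  p <- read_site_params(f)
  expect_equal(p$p_c, 0.2315)
  expect_equal(p$p_n, 0.9427)
  expect_equal(p$p_s, site_params()$p_s)  # default fills in
  writeLines(c("p_c = 0.1", "bogus = 3"), f)
  expect_error(read_site_params(f), "unknown parameter")
  writeLines(c("p_c = 0.1", "p_c = 0.2"), f)
  expect_error(read_site_params(f), "duplicated")
})
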