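# Independent oracles used across the suite.

# Exhaustive joint kernel by enumerating every combination of per-site
# outcomes (each site independently draws one row of its event-table
# column).  Exponential in N; the package's category-count builder is
# checked against this for small N.
brute_force_column <- function(probs, params, S, A) {
  N <- params$n_sites
  et <- site_event_table(probs, params)
  ev <- attr(et, "events")
  site_outcomes <- function(col) {
    keep <- et[, col] > 0
    data.frame(Y1 = ev$Y1[keep], Y2 = ev$Y2[keep], S_next = ev$S_next[keep],
               p = et[keep, col])
  }
  groups <- c(rep(list(site_outcomes("occupied_unrestricted")), S - A),
              rep(list(site_outcomes("occupied_restricted")), A),
              rep(list(site_outcomes("empty_unrestricted")), N - S))
  if (length(groups) == 0L) {
    return(data.frame(Y1 = 0L, Y2 = 0L, S_next = 0L, prob = 1))
  }
  combos <- expand.grid(lapply(groups, function(g) seq_len(nrow(g))))
  y1 <- y2 <- snx <- numeric(nrow(combos))
  pr <- rep(1, nrow(combos))
  for (k in seq_along(groups)) {
    g <- groups[[k]][combos[[k]], ]
    y1 <- y1 + g$Y1; y2 <- y2 + g$Y2; snx <- snx + g$S_next
    pr <- pr * g$p
  }
  out <- aggregate(list(prob = pr),
                   by = list(Y1 = y1, Y2 = y2, S_next = snx), FUN = sum)
  out[order(out$Y1, out$Y2, out$S_next), , drop = FALSE]
}

# compare a built kernel column against the brute-force oracle
expect_column_matches_oracle <- function(kernel, probs, params, S, A,
                                         tol = 1e-12) {
  col <- kernel_column(kernel, S, A)
  col <- col[col$prob > 0, c("Y1", "Y2", "S_next", "prob")]
  col <- col[order(col$Y1, col$Y2, col$S_next), ]
  ora <- brute_force_column(probs, params, S, A)
  ora <- ora[ora$prob > tol, ]
  expect_equal(nrow(col), nrow(ora))
  expect_equal(col$Y1, ora$Y1, ignore_attr = TRUE)
  expect_equal(col$Y2, ora$Y2, ignore_attr = TRUE)
  expect_equal(col$S_next, ora$S_next, ignore_attr = TRUE)
  expect_lt(max(abs(col$prob - ora$prob)), tol)
}

# the moderate-disturbance probabilities at the printed 3-decimal precision,
# used to reproduce the reference multi-site tables
printed_moderate_probs <- function() success_probs(0.405, 0.454)
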