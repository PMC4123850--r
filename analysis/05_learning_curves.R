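#!/usr/bin/env Rscript
# Speed of learning under alternative monitoring signals: expected belief
# time paths over 100 years for each uncertainty assumption and each true
# disturbance model, comparing full success information, the unattributed
# total success count, and occupancy-only updating.  Writes
# results/learning_curves.csv.  About fifteen minutes at the default 2000
# paths (set N_PATHS=10000 for the reference scale).

library(nestadapt)
dir.create("results", showWarnings = FALSE)
n_paths <- as.integer(Sys.getenv("N_PATHS", "2000"))
order <- as.integer(Sys.getenv("GRID_ORDER", "20"))
g <- belief_grid(order)

out <- NULL
for (cs in c("pr_known", "both_uncertain", "pu_known")) {
  case <- uncertainty_case(cs)
  pols <- lapply(c(full = "full", total = "total", none = "none"),
                 function(m) solve_active(case_kernels(case, m), g))
  for (tm in 1:3) {
    for (m in names(pols)) {
      e <- simulate_ensemble(pols[[m]], case, tm, n_paths = n_paths,
                             n_years = 100, seed = 1000 + tm)
      bp <- expected_belief_paths(e)
      out <- rbind(out, cbind(case = cs, true_model = case$model_names[tm],
                              signal = m, bp))
    }
    w100 <- out[out$case == cs & out$true_model == case$model_names[tm] &
                  out$year == 100, ]
    truth <- paste0("mean_b", tm)
    cat(sprintf("%-15s true=%-15s year-100 weight on truth: %s\n",
                cs, case$model_names[tm],
                paste(sprintf("%s %.3f", w100$signal, w100[[truth]]),
                      collapse = "  ")))
  }
}
write.csv(out, "results/learning_curves.csv", row.names = FALSE)
cat("\nFull success attribution learns fastest; the bare success count is\n")
cat("close behind; occupancy alone (the traditional information set) barely\n")
cat("moves beliefs in a century because re-occupancy hardly depends on\n")
cat("fledging success.\n")
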