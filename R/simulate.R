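# Monte-Carlo simulation of management trajectories and belief learning
# curves under a chosen true disturbance model.

#' Simulate management trajectories under a true model
#'
#' Samples replicate multi-year trajectories of occupancy, restrictions,
#' fledging-success signals and Bayesian model weights: each year the action
#' is read from the policy at the current occupancy and the grid point
#' nearest the current belief; the success counts and next-year occupancy are
#' drawn from the true model's joint kernel; and the belief is updated by
#' Bayes rule using the policy's signal mode.  Beliefs are carried exactly
#' between years (the grid is used only for policy lookup), so no
#' discretization error accumulates in the learning curves.
#'
#' @param policy A `belief_policy` (active or passive) solved under the
#'   signal mode to be simulated.
#' @param case_obj The `uncertainty_case` defining the candidate models.
#' @param true_model Index (1-3) of the model generating the data.
#' @param n_paths Number of replicate paths (default 10000).
#' @param n_years Number of simulated years (default 100).
#' @param init_occupancy Initial occupied-site count (default 20 of 25).
#' @param init_belief Initial weight vector (default uniform).
#' @param seed RNG seed; ensembles are bit-for-bit reproducible given the
#'   seed and configuration.
#' @param mode Signal mode used for belief updating; must equal the
#'   policy's mode (supplied only as a cross-check).
#' @return Object of class `trajectory_ensemble`: list with `paths` (long
#'   data frame: path, year, S, A, Y1, Y2, b1, b2, b3; year 0 holds the
#'   initial state and belief, and the year-`n_years` row carries the final
#'   state with no action) and `meta`.
#' @export
simulate_ensemble <- function(policy, case_obj, true_model,
                              n_paths = 10000L, n_years = 100L,
                              init_occupancy = 20L,
                              init_belief = rep(1 / 3, 3),
                              seed = 1L, mode = policy$mode) {
  if (!identical(mode, policy$mode)) {
    stop("signal mode mismatch between the policy and the belief updater")
  }
  stopifnot(inherits(policy, "belief_policy"),
            true_model %in% 1:3, abs(sum(init_belief) - 1) < 1e-8)
  params <- case_obj$params
  N <- params$n_sites
  stopifnot(init_occupancy >= 0, init_occupancy <= N)
  sp <- case_success_probs(case_obj)
  pu <- vapply(sp, `[[`, numeric(1L), "p_u")
  pr <- vapply(sp, `[[`, numeric(1L), "p_r")
  grid <- policy$grid
  occ <- lapply(0:N, function(S) .occupancy_given_successes(S, params))

  set.seed(seed)
  np <- as.integer(n_paths)
  S <- rep(as.integer(init_occupancy), np)
  B <- matrix(rep(init_belief, each = np), np, 3L)
  rec <- vector("list", n_years + 1L)
  for (t in seq_len(n_years)) {
    gi <- nearest_grid_point(grid, B)
    A <- policy$action[cbind(S + 1L, gi)]
    Y1 <- stats::rbinom(np, S - A, pu[true_model])
    Y2 <- stats::rbinom(np, A, pr[true_model])
    ytot <- Y1 + Y2
    S_next <- stats::rbinom(np, ytot, params$p_s) +
      stats::rbinom(np, S - ytot, params$p_n) +
      stats::rbinom(np, N - S, params$p_c)
    rec[[t]] <- data.frame(path = seq_len(np), year = t - 1L,
                           S = S, A = A, Y1 = Y1, Y2 = Y2,
                           b1 = B[, 1L], b2 = B[, 2L], b3 = B[, 3L])
    B <- .update_beliefs(B, S, A, Y1, Y2, S_next, mode, pu, pr, occ, N)
    S <- S_next
  }
  rec[[n_years + 1L]] <- data.frame(path = seq_len(np), year = n_years,
                                    S = S, A = NA_integer_,
                                    Y1 = NA_integer_, Y2 = NA_integer_,
                                    b1 = B[, 1L], b2 = B[, 2L], b3 = B[, 3L])
  paths <- do.call(rbind, rec)
  paths <- paths[order(paths$path, paths$year), , drop = FALSE]
  rownames(paths) <- NULL
  structure(
    list(paths = paths,
         meta = list(case = case_obj$case, true_model = true_model,
                     mode = mode, strategy = policy$strategy, seed = seed,
                     n_paths = np, n_years = n_years,
                     init_occupancy = init_occupancy,
                     init_belief = init_belief)),
    class = "trajectory_ensemble"
  )
}

# vectorized Bayes update for all paths; likelihood factors common to every
# model (e.g. the occupancy convolution given total successes in the "full"
# and "total" modes) cancel in the normalization and are dropped
.update_beliefs <- function(B, S, A, Y1, Y2, S_next, mode, pu, pr, occ, N) {
  np <- nrow(B)
  L <- matrix(1, np, 3L)
  if (mode == "full") {
    for (i in 1:3) {
      L[, i] <- stats::dbinom(Y1, S - A, pu[i]) * stats::dbinom(Y2, A, pr[i])
    }
  } else {
    key <- S * (N + 1L) + A
    for (k in unique(key)) {
      g <- which(key == k)
      Sg <- S[g[1L]]; Ag <- A[g[1L]]
      Cg <- occ[[Sg + 1L]]
      for (i in 1:3) {
        L[g, i] <- switch(mode,
          unrestricted_only = {
            v <- numeric(length(g))
            for (y2 in 0:Ag) {
              v <- v + stats::dbinom(y2, Ag, pr[i]) *
                Cg[cbind(Y1[g] + y2 + 1L, S_next[g] + 1L)]
            }
            stats::dbinom(Y1[g], Sg - Ag, pu[i]) * v
          },
          restricted_only = {
            v <- numeric(length(g))
            for (y1 in 0:(Sg - Ag)) {
              v <- v + stats::dbinom(y1, Sg - Ag, pu[i]) *
                Cg[cbind(y1 + Y2[g] + 1L, S_next[g] + 1L)]
            }
            stats::dbinom(Y2[g], Ag, pr[i]) * v
          },
          total = {
            dv <- .conv(stats::dbinom(0:(Sg - Ag), Sg - Ag, pu[i]),
                        stats::dbinom(0:Ag, Ag, pr[i]))
            dv[Y1[g] + Y2[g] + 1L]
          },
          none = {
            dv <- .conv(stats::dbinom(0:(Sg - Ag), Sg - Ag, pu[i]),
                        stats::dbinom(0:Ag, Ag, pr[i]))
            as.vector(dv %*% Cg)[S_next[g] + 1L]
          })
      }
    }
  }
  post <- B * L
  tot <- rowSums(post)
  if (any(tot <= 0)) stop("simulated observation impossible under all models")
  post / tot
}

#' Expected belief time paths
#'
#' Yearly averages of the belief vector across the replicate paths of an
#' ensemble, with Monte-Carlo standard errors.
#'
#' @param ensemble A `trajectory_ensemble`.
#' @return Data frame: year, mean_b1..3, se_b1..3.
#' @export
expected_belief_paths <- function(ensemble) {
  p <- ensemble$paths
  np <- ensemble$meta$n_paths
  agg <- function(f) {
    vapply(c("b1", "b2", "b3"), function(v) {
      as.vector(tapply(p[[v]], p$year, f))
    }, numeric(length(unique(p$year))))
  }
  mu <- agg(mean)
  se <- agg(stats::sd) / sqrt(np)
  out <- data.frame(year = sort(unique(p$year)),
                    mean_b1 = mu[, 1L], mean_b2 = mu[, 2L],
                    mean_b3 = mu[, 3L],
                    se_b1 = se[, 1L], se_b2 = se[, 2L], se_b3 = se[, 3L])
  rownames(out) <- NULL
  out
}

#' Write an ensemble to CSV
#'
#' Long per-path file plus a per-year summary; the configuration is echoed
#' to a `.config.txt` sidecar for provenance.
#'
#' @param ensemble A `trajectory_ensemble`.
#' @param path Output CSV path (summary written alongside with suffix
#'   `_summary.csv`).
#' @export
write_ensemble_csv <- function(ensemble, path) {
  utils::write.csv(ensemble$paths, path, row.names = FALSE)
  base <- sub("\\.csv$", "", path)
  utils::write.csv(expected_belief_paths(ensemble),
                   paste0(base, "_summary.csv"), row.names = FALSE)
  meta <- ensemble$meta
  writeLines(paste(names(meta),
                   vapply(meta, function(x) paste(format(x), collapse = " "),
                          ""),
                   sep = " = "),
             paste0(base, ".config.txt"))
  invisible(path)
}
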