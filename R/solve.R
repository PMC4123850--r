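# Dynamic-programming solvers: certain-model MDP, passive (fixed-belief)
# strategy, and active belief-state value iteration.
#
# The active solver works on a compressed representation of the per-model
# kernels.  Within one (S, A) column, observation cells whose likelihood
# vectors across the candidate models are proportional lead to the same
# posterior, so they are grouped into "observation classes"; each class
# carries its per-model mass and a (model-independent) conditional
# distribution over S_next.  For the success-signal modes this collapses the
# observation space from O(S^2 N) cells to the distinct success counts,
# which is what makes grid-based value iteration affordable at N = 25.

# feasible (S, A) pairs in canonical order: S = 0..N, A = 0..S
.pairs <- function(N) {
  data.frame(S = rep(0:N, times = 1:(N + 1L)),
             A = unlist(lapply(0:N, function(S) 0:S)))
}

# Compress aligned per-model kernels into observation classes.
# Returns flat arrays consumed by the C++ backend.
.compress_kernels <- function(kernels) {
  stopifnot(length(kernels) == 3L)
  modes <- vapply(kernels, attr, "", "mode")
  if (length(unique(modes)) != 1L) stop("kernels must share one signal mode")
  N <- attr(kernels[[1L]], "n_sites")
  scaff <- as.data.frame(kernels[[1L]])[, c("S", "A", "S_next")]
  PM <- vapply(kernels, function(k) as.data.frame(k)$prob,
               numeric(nrow(scaff)))
  for (k in kernels[-1L]) {
    stopifnot(identical(as.data.frame(k)[, c("S", "A", "S_next")], scaff))
  }
  tot <- rowSums(PM)
  keep <- tot > 1e-300
  scaff <- scaff[keep, , drop = FALSE]
  PM <- PM[keep, , drop = FALSE]
  tot <- tot[keep]
  # likelihood-direction key: proportional rows share a posterior
  lik_dir <- round(PM / tot, 10L)
  pair_id <- scaff$S * (N + 1L) + scaff$A
  cls_key <- paste(pair_id, lik_dir[, 1L], lik_dir[, 2L], lik_dir[, 3L])
  cls <- match(cls_key, unique(cls_key))
  n_cls <- max(cls)
  W <- rowsum(PM, cls, reorder = TRUE)           # per-model class mass
  cls_pair <- pair_id[!duplicated(cls)][order(unique(cls))]
  # conditional S_next distribution within each class (model-independent
  # because rows are proportional); q indexed over 0..N
  Q <- rowsum(cbind(tot), paste(cls, scaff$S_next), reorder = FALSE)
  qrow <- as.integer(sub(" .*", "", rownames(Q)))
  qsnx <- as.integer(sub(".* ", "", rownames(Q)))
  Qmat <- matrix(0, n_cls, N + 1L)
  Qmat[cbind(qrow, qsnx + 1L)] <- Q[, 1L]
  Qmat <- Qmat / rowSums(Qmat)
  # deduplicate conditional distributions across classes
  qkey <- apply(round(Qmat, 12L), 1L, paste, collapse = ",")
  qid <- match(qkey, unique(qkey))
  Qu <- Qmat[!duplicated(qid), , drop = FALSE][order(unique(qid)), ,
                                               drop = FALSE]
  # order classes by pair
  o <- order(cls_pair)
  pairs <- .pairs(N)
  pair_of <- pairs$S * (N + 1L) + pairs$A
  pair_start <- c(0L, cumsum(tabulate(match(cls_pair, pair_of),
                                      nbins = nrow(pairs))))
  list(N = N, pairs = pairs,
       class_w = W[o, , drop = FALSE],
       class_qid = qid[o] - 1L,
       pair_start = pair_start,
       Qu = Qu)
}

# reward matrix over (pair, grid point)
.reward_matrix <- function(pairs, grid, probs_list, spec, N) {
  ey_mod <- vapply(probs_list, function(p) {
    pairs$A * p$p_r + (pairs$S - pairs$A) * p$p_u
  }, numeric(nrow(pairs)))
  EY <- ey_mod %*% t(grid$points)
  if (spec$form == "cobb_douglas") {
    EY^spec$alpha * (N - pairs$A)^(1 - spec$alpha)
  } else {
    spec$alpha * EY + (1 - spec$alpha) * (N - pairs$A)
  }
}

#' Solve the certain-model restriction policy
#'
#' Standard infinite-horizon discounted MDP over the occupied-site count,
#' assuming one candidate disturbance model is true, at a fixed hare level.
#' Solved by policy iteration (exact policy evaluation, greedy improvement,
#' ties to the least restrictive action).  Under a no-disturbance model
#' (p_u = p_r) restrictions only cost access, so the optimal policy is A = 0
#' everywhere.
#'
#' @param case_obj An `uncertainty_case`.
#' @param model_index Which candidate model (1, 2, 3) is taken as true.
#' @param hare Hare abundance index at which to evaluate the success
#'   probabilities (default: the case's parameter value).
#' @param spec A `reward_spec`.
#' @return List with `policy` (optimal A for S = 0..N), `value` (length
#'   N + 1), `probs`.
#' @export
solve_certain <- function(case_obj, model_index, hare = NULL,
                          spec = reward_spec()) {
  sp <- case_success_probs(case_obj, hare = hare)[[model_index]]
  params <- case_obj$params
  N <- params$n_sites
  pairs <- .pairs(N)
  # occupied-next probability per site group, then convolved binomials
  qu <- (1 - sp$p_u) * params$p_n + sp$p_u * params$p_s
  qr <- (1 - sp$p_r) * params$p_n + sp$p_r * params$p_s
  TP <- t(vapply(seq_len(nrow(pairs)), function(p) {
    S <- pairs$S[p]; A <- pairs$A[p]
    v <- .conv(stats::dbinom(0:(S - A), S - A, qu),
               stats::dbinom(0:A, A, qr))
    .conv(v, stats::dbinom(0:(N - S), N - S, params$p_c))
  }, numeric(N + 1L)))
  ey <- pairs$A * sp$p_r + (pairs$S - pairs$A) * sp$p_u
  Rv <- .reward_value(ey, pairs$A, spec, N)
  sol <- .solve_mdp(pairs, TP, Rv, params$discount)
  c(sol, list(probs = sp))
}

# policy iteration for a count-state MDP: TP is (pair x S_next) transition,
# Rv reward per pair
.solve_mdp <- function(pairs, TP, Rv, discount, max_iter = 200L) {
  N <- max(pairs$S)
  nS <- N + 1L
  rows_of_S <- split(seq_len(nrow(pairs)), pairs$S)
  pol <- rep(0L, nS)   # action index offset: row = pair of (S, pol[S])
  for (it in seq_len(max_iter)) {
    rows <- vapply(1:nS, function(s) rows_of_S[[s]][pol[s] + 1L],
                   integer(1L))
    # exact evaluation: (I - delta P) v = r
    v <- solve(diag(nS) - discount * TP[rows, , drop = FALSE], Rv[rows])
    Q <- Rv + discount * as.vector(TP %*% v)
    new_pol <- vapply(1:nS, function(s) {
      q <- Q[rows_of_S[[s]]]
      # ties to the smallest A (least restrictive)
      as.integer(which(q > max(q) - 1e-10)[1L] - 1L)
    }, integer(1L))
    if (identical(new_pol, pol)) break
    pol <- new_pol
  }
  list(policy = pol, value = as.vector(v))
}

#' Solve the active adaptive-management strategy
#'
#' Value iteration on the belief-augmented state (S, B): at every grid point
#' the action maximizes current reward plus the discounted expectation of the
#' value at the realized next occupancy and the Bayes-updated belief, the
#' updated belief being projected onto the grid by barycentric
#' interpolation.  The backend uses modified policy iteration (greedy sweeps
#' interleaved with fixed-policy evaluation sweeps), which converges to the
#' same fixed point as plain value iteration; iteration stops when the
#' sup-norm change of a greedy sweep falls below `tol`.  Ties are broken
#' toward the least restrictive action.
#'
#' @param kernels List of 3 per-model `joint_kernel`s (one signal mode).
#' @param grid A `belief_grid`.
#' @param spec A `reward_spec`.
#' @param params A `site_params`.
#' @param tol Sup-norm convergence tolerance (default 1e-6).
#' @param max_iter Cap on greedy sweeps (default 5000).
#' @param eval_sweeps Fixed-policy evaluation sweeps between greedy sweeps
#'   (default 50; 0 gives plain value iteration).
#' @return Object of class `belief_policy`: list with `action` and `value`
#'   ((N+1) x n_grid matrices), `grid`, `mode`, `strategy = "active"`,
#'   `iterations`, `residual`.
#' @export
solve_active <- function(kernels, grid, spec = reward_spec(),
                         params = attr(kernels[[1L]], "params"),
                         tol = 1e-6, max_iter = 5000L, eval_sweeps = 50L) {
  comp <- .compress_kernels(kernels)
  N <- comp$N
  probs_list <- lapply(kernels, attr, "probs")
  Rmat <- .reward_matrix(comp$pairs, grid, probs_list, spec, N)
  res <- belief_vi(comp$pairs$S, comp$pairs$A, comp$pair_start,
                   comp$class_w, comp$class_qid, comp$Qu, Rmat,
                   grid$points, grid$order, params$discount,
                   tol, as.integer(max_iter), as.integer(eval_sweeps))
  if (res$residual >= tol && res$iterations >= max_iter) {
    stop(sprintf("value iteration did not converge: residual %.3g after %d sweeps",
                 res$residual, res$iterations))
  }
  structure(list(action = res$policy, value = res$value, grid = grid,
                 mode = attr(kernels[[1L]], "mode"), strategy = "active",
                 iterations = res$iterations, residual = res$residual,
                 residual_trace = res$residual_trace),
            class = "belief_policy")
}

#' Solve the passive adaptive-management strategy
#'
#' For every belief grid point, solves the standard MDP whose transition is
#' the belief-averaged occupancy kernel with the beliefs held fixed forever
#' (no anticipated learning), and records that MDP's decision rule at each
#' S.  At simplex vertices this coincides with the active strategy, since a
#' degenerate belief cannot move; elsewhere the difference between the two
#' strategies measures probing.
#'
#' @inheritParams solve_active
#' @return A `belief_policy` with `strategy = "passive"`.
#' @export
solve_passive <- function(kernels, grid, spec = reward_spec(),
                          params = attr(kernels[[1L]], "params"),
                          tol = 1e-6, max_iter = 200L) {
  N <- attr(kernels[[1L]], "n_sites")
  pairs <- .pairs(N)
  probs_list <- lapply(kernels, attr, "probs")
  # per-model state-transition kernels (signal marginalized out)
  TPs <- lapply(kernels, function(k) {
    nk <- garble(k, "none")
    df <- as.data.frame(nk)
    TP <- matrix(0, nrow(pairs), N + 1L)
    TP[cbind((df$S * (df$S + 1L)) %/% 2L + df$A + 1L, df$S_next + 1L)] <- df$prob
    TP
  })
  Rmat <- .reward_matrix(pairs, grid, probs_list, spec, N)
  action <- value <- matrix(0, N + 1L, grid$n)
  for (j in seq_len(grid$n)) {
    B <- grid$points[j, ]
    TPb <- B[1L] * TPs[[1L]] + B[2L] * TPs[[2L]] + B[3L] * TPs[[3L]]
    sol <- .solve_mdp(pairs, TPb, Rmat[, j], params$discount)
    action[, j] <- sol$policy
    value[, j] <- sol$value
  }
  structure(list(action = action, value = value, grid = grid,
                 mode = attr(kernels[[1L]], "mode"), strategy = "passive",
                 iterations = NA_integer_, residual = NA_real_),
            class = "belief_policy")
}

#' @export
print.belief_policy <- function(x, ...) {
  cat(sprintf("%s strategy, signal mode '%s': %d occupancy states x %d belief points\n",
              x$strategy, x$mode, nrow(x$action), ncol(x$action)))
  if (!is.na(x$iterations)) {
    cat(sprintf("  converged in %d greedy sweeps (residual %.2g)\n",
                x$iterations, x$residual))
  }
  invisible(x)
}

#' Percent value gain of one information structure over another
#'
#' Pointwise percent increase `100 (V_signal - V_nosignal) / V_nosignal`
#' of the value surface solved under a richer signal relative to a poorer
#' one, on a shared grid.  At simplex vertices there is nothing to learn and
#' the gain is zero.
#'
#' @param sol_signal,sol_nosignal `belief_policy` objects solved on the same
#'   grid.
#' @return Matrix of percent gains, dimension like `value`.
#' @export
value_gain <- function(sol_signal, sol_nosignal) {
  stopifnot(identical(dim(sol_signal$value), dim(sol_nosignal$value)),
            sol_signal$grid$order == sol_nosignal$grid$order)
  100 * (sol_signal$value - sol_nosignal$value) / sol_nosignal$value
}

#' Export a belief policy to long-format CSV
#'
#' Columns `S, b1, b2, b3, action, value`; one row per (occupancy, grid
#' point), ready for ternary plotting.
#'
#' @param sol A `belief_policy`.
#' @param path Output path.
#' @export
write_policy_csv <- function(sol, path) {
  g <- sol$grid$points
  N1 <- nrow(sol$action)
  df <- data.frame(
    S = rep(0:(N1 - 1L), times = ncol(sol$action)),
    b1 = rep(g[, 1L], each = N1),
    b2 = rep(g[, 2L], each = N1),
    b3 = rep(g[, 3L], each = N1),
    action = as.vector(sol$action),
    value = as.vector(sol$value)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
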