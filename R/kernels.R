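# Multi-site joint kernels by category-count aggregation.
#
# Sites are exchangeable, so the N-site state is the count S of occupied
# sites and the action the count A <= S of restricted sites.  The joint
# kernel P(Y1, Y2, S_next | S, A) is built by drawing the A restricted
# occupied, S - A unrestricted occupied, and N - S empty sites independently
# from their single-site event-table columns and convolving the per-group
# counts; assignments sharing a (signal, S_next) value are summed.

#' Signal modes
#'
#' The five monitoring regimes for the fledging-success signal:
#' `"full"` observes both Y1 (successes at unrestricted sites) and Y2
#' (successes at restricted sites); `"unrestricted_only"` and
#' `"restricted_only"` observe one of them; `"total"` observes only the sum
#' Y1 + Y2; `"none"` observes no success information (belief updating then
#' relies on the occupancy transition alone, the traditional
#' adaptive-management information set).  `"full"` refines every other mode.
#'
#' @return Character vector of mode names.
#' @export
signal_modes <- function() {
  c("full", "unrestricted_only", "restricted_only", "total", "none")
}

# modes reachable from `mode` by coarsening (including identity)
.coarsenings <- function(mode) {
  switch(mode,
    full = signal_modes(),
    unrestricted_only = c("unrestricted_only", "none"),
    restricted_only = c("restricted_only", "none"),
    total = c("total", "none"),
    none = "none"
  )
}

# which of the (Y1, Y2) columns carry a value in each mode; for "total" the
# summed count is stored in Y1 (the kernel's `mode` attribute disambiguates)
.signal_cols <- function(mode) {
  switch(mode,
    full = c("Y1", "Y2"),
    unrestricted_only = "Y1",
    restricted_only = "Y2",
    total = "Y1",
    none = character(0)
  )
}

# pmf convolution of two nonnegative-integer distributions
.conv <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# P(S_next | S occupied of which ytot successful), given N sites total:
# convolution of Binom(ytot, p_s), Binom(S - ytot, p_n), Binom(N - S, p_c).
# Returns a (S+1) x (N+1) matrix indexed [ytot + 1, S_next + 1].
.occupancy_given_successes <- function(S, params) {
  N <- params$n_sites
  emp <- stats::dbinom(0:(N - S), N - S, params$p_c)
  t(vapply(0:S, function(ytot) {
    v <- .conv(stats::dbinom(0:ytot, ytot, params$p_s),
               stats::dbinom(0:(S - ytot), S - ytot, params$p_n))
    .conv(v, emp)
  }, numeric(N + 1)))
}

#' Enumerate category-count assignments of sites
#'
#' All ways of assigning `n_sites` exchangeable sites to `n_categories`
#' outcome categories (compositions of `n_sites` into `n_categories`
#' nonnegative parts); there are `choose(n_sites + n_categories - 1,
#' n_categories - 1)` of them.  For the 4-category scheme the categories are
#' NE (restricted-or-unsuccessful, empty next year), SE
#' (unrestricted-successful, empty), NO (restricted-or-unsuccessful,
#' occupied), SO (unrestricted-successful, occupied) and each assignment is
#' mapped to its signal/next-state pair Y = SE + SO, S_next = NO + SO.
#' Distinct assignments can share a (Y, S_next) pair; the joint kernel sums
#' them.
#'
#' @param n_sites Number of sites (>= 0).
#' @param n_categories Number of outcome categories (4 for the
#'   single-signal scheme).
#' @return Data frame: one row per assignment with the category counts and,
#'   for `n_categories = 4`, columns `Y` and `S_next`.
#' @export
enumerate_assignments <- function(n_sites, n_categories = 4L) {
  stopifnot(n_sites >= 0, n_categories >= 1)
  comp <- .compositions(n_sites, n_categories)
  out <- as.data.frame(comp)
  if (n_categories == 4L) {
    names(out) <- c("NE", "SE", "NO", "SO")
    out$Y <- out$SE + out$SO
    out$S_next <- out$NO + out$SO
  } else {
    names(out) <- paste0("c", seq_len(n_categories))
  }
  out
}

# all compositions of n into k nonnegative parts, as a matrix (rows ordered
# lexicographically by the leading parts, largest first)
.compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, ncol = 1L))
  do.call(rbind, lapply(n:0, function(first) {
    rest <- .compositions(n - first, k - 1L)
    cbind(first, rest, deparse.level = 0)
  }))
}

#' Per-assignment probabilities for one multi-site column
#'
#' The unsummed decomposition of one (S, A) column of the joint kernel: every
#' combination of per-group outcome-category counts, with its multinomial
#' probability.  Occupied sites fall into four categories
#' (successful/unsuccessful x occupied/empty next year) with single-site
#' probabilities from [site_event_table()]; empty sites are colonized or not.
#' Useful for tracing which assignments sum into a given (Y1, Y2, S_next)
#' cell (exhaustive; intended for small N).
#'
#' @param probs A `success_probs` object.
#' @param params A `site_params` object.
#' @param S Number of occupied sites.
#' @param A Number of restricted sites (0 <= A <= S).
#' @return Data frame with per-group category counts (`u_so`, `u_se`, `u_no`,
#'   `u_ne` for unrestricted sites: successful/occupied, successful/empty,
#'   unsuccessful/occupied, unsuccessful/empty; `r_*` likewise for restricted
#'   sites; `e_o`, `e_e` for empty sites), the implied `Y1`, `Y2`, `S_next`,
#'   and `prob`.
#' @export
assignment_table <- function(probs, params, S, A) {
  N <- params$n_sites
  stopifnot(S >= 0, S <= N, A >= 0)
  if (A > S) stop("infeasible action: more restricted than occupied sites")
  if (N > 10) stop("assignment_table is exhaustive; use N <= 10")
  p4 <- function(p_succ) c(
    so = p_succ * params$p_s, se = p_succ * (1 - params$p_s),
    no = (1 - p_succ) * params$p_n, ne = (1 - p_succ) * (1 - params$p_n)
  )
  group <- function(n, pcat) {
    cnt <- .compositions(n, length(pcat))
    prob <- apply(cnt, 1L, function(x) stats::dmultinom(x, prob = pcat))
    cbind(as.data.frame(cnt), prob = prob)
  }
  gu <- group(S - A, p4(probs$p_u)); names(gu)[1:4] <- paste0("u_", names(p4(0)))
  gr <- group(A, p4(probs$p_r)); names(gr)[1:4] <- paste0("r_", names(p4(0)))
  ge <- group(N - S, c(o = params$p_c, e = 1 - params$p_c))
  names(ge)[1:2] <- c("e_o", "e_e")
  out <- merge(merge(gu, gr, by = NULL), ge, by = NULL)
  prob <- out$prob.x * out$prob.y * out$prob
  out <- out[, !grepl("^prob", names(out)), drop = FALSE]
  out$Y1 <- out$u_so + out$u_se
  out$Y2 <- out$r_so + out$r_se
  out$S_next <- out$u_so + out$u_no + out$r_so + out$r_no + out$e_o
  out$prob <- prob
  out[order(out$Y1, out$Y2, out$S_next), , drop = FALSE]
}

#' Build the joint signal/next-state kernel for N sites
#'
#' Exact joint distribution P(signal, S_next | S, A) for all feasible
#' state/action pairs (A <= S), under one candidate disturbance model, by
#' category-count aggregation: the success counts are binomial per group
#' (Y1 ~ Binom(S - A, p_u), Y2 ~ Binom(A, p_r)) and, given the successes,
#' next-year occupancy is the convolution of the per-group re-occupancy and
#' colonization binomials.  Assignments sharing a (signal, S_next) value are
#' summed, so each (S, A) column is a proper distribution over the feasible
#' (Y1 <= S - A, Y2 <= A, S_next <= N) cells.
#'
#' @param params A `site_params` object (supplies p_c, p_n, p_s, n_sites).
#' @param probs A `success_probs` object for the candidate model.
#' @param mode Signal mode; the canonical `"full"` kernel is built first and
#'   coarsened with [garble()] for any other mode.
#' @return An object of class `joint_kernel`: a data frame with columns
#'   `S, A, Y1, Y2, S_next, prob` (unobserved signal columns are `NA`; in
#'   mode `"total"` the summed count is stored in `Y1`), with attributes
#'   `n_sites`, `mode`, `probs`, `params`.
#' @export
build_kernel <- function(params, probs, mode = "full") {
  mode <- match.arg(mode, signal_modes())
  N <- params$n_sites
  cols <- lapply(0:N, function(S) {
    occ <- .occupancy_given_successes(S, params)
    do.call(rbind, lapply(0:S, function(A) {
      n1 <- S - A
      grid <- expand.grid(S_next = 0:N, Y2 = 0:A, Y1 = 0:n1)
      du <- stats::dbinom(grid$Y1, n1, probs$p_u)
      dr <- stats::dbinom(grid$Y2, A, probs$p_r)
      data.frame(S = S, A = A, Y1 = grid$Y1, Y2 = grid$Y2,
                 S_next = grid$S_next,
                 prob = du * dr * occ[cbind(grid$Y1 + grid$Y2 + 1L,
                                            grid$S_next + 1L)])
    }))
  })
  df <- do.call(rbind, cols)
  df <- df[order(df$S, df$A, df$Y1, df$Y2, df$S_next), , drop = FALSE]
  rownames(df) <- NULL
  k <- structure(df, n_sites = N, mode = "full", probs = probs,
                 params = params, class = c("joint_kernel", "data.frame"))
  if (mode != "full") k <- garble(k, mode) else k
}

#' Coarsen a kernel's signal
#'
#' Sums kernel probabilities over signal values that map to the same value of
#' a coarser signal mode.  Coarsening `"none"` discards the success signal
#' entirely, leaving the pure N-site state-transition kernel.  Refinement
#' requests (e.g. recovering `"full"` from `"total"`) are rejected.
#'
#' @param kernel A `joint_kernel`.
#' @param target_mode Signal mode to coarsen to (must be a coarsening of
#'   `kernel`'s mode).
#' @return A `joint_kernel` in the target mode.
#' @export
garble <- function(kernel, target_mode) {
  target_mode <- match.arg(target_mode, signal_modes())
  mode <- attr(kernel, "mode")
  if (!target_mode %in% .coarsenings(mode)) {
    stop(sprintf("cannot refine signal mode '%s' to '%s'", mode, target_mode))
  }
  if (target_mode == mode) return(kernel)
  df <- as.data.frame(kernel)
  # coarsened signal values; NA marks a discarded signal component
  y1 <- switch(target_mode,
    unrestricted_only = df$Y1,
    total = if (mode == "full") df$Y1 + df$Y2 else df$Y1,
    NA_integer_)
  y2 <- if (target_mode == "restricted_only") df$Y2 else NA_integer_
  # sum probabilities of rows sharing (S, A, signal, S_next) via an exact
  # integer key (NA encoded as 0 in a shifted digit)
  mx <- attr(kernel, "n_sites") + 3
  enc <- function(v) ifelse(is.na(v), 0L, v + 1L)
  key <- (((df$S * mx + df$A) * mx + enc(y1)) * mx + enc(y2)) * mx + df$S_next
  first <- !duplicated(key)
  prob <- rowsum(df$prob, key, reorder = TRUE)
  out <- data.frame(S = df$S[first], A = df$A[first],
                    Y1 = if (all(is.na(y1))) NA_integer_ else y1[first],
                    Y2 = if (all(is.na(y2))) NA_integer_ else y2[first],
                    S_next = df$S_next[first])
  out <- out[order(key[first]), , drop = FALSE]
  out$prob <- as.vector(prob)
  rownames(out) <- NULL
  structure(out, n_sites = attr(kernel, "n_sites"), mode = target_mode,
            probs = attr(kernel, "probs"), params = attr(kernel, "params"),
            class = c("joint_kernel", "data.frame"))
}

#' Extract one (S, A) column of a kernel
#'
#' @param kernel A `joint_kernel`.
#' @param S,A State and action counts; an action with `A > S` is infeasible
#'   (the number of restricted sites can never exceed the number of occupied
#'   sites) and raises an error.
#' @return Data frame of the column's (signal, S_next) cells and
#'   probabilities (sums to 1).
#' @export
kernel_column <- function(kernel, S, A) {
  N <- attr(kernel, "n_sites")
  stopifnot(S >= 0, S <= N, A >= 0)
  if (A > S) stop("infeasible action: more restricted than occupied sites")
  df <- as.data.frame(kernel)
  out <- df[df$S == S & df$A == A, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Kernels for all candidate models of an uncertainty case
#'
#' @param case_obj An `uncertainty_case`.
#' @param mode Signal mode.
#' @param rounded Passed to [case_success_probs()]; use `TRUE` to reproduce
#'   the reference printed tables.
#' @param hare Optional hare index override.
#' @return List of 3 `joint_kernel`s sharing one row scaffold.
#' @export
case_kernels <- function(case_obj, mode = "full", rounded = FALSE,
                         hare = NULL) {
  sp <- case_success_probs(case_obj, hare = hare, rounded = rounded)
  lapply(sp, function(p) build_kernel(case_obj$params, p, mode = mode))
}

#' Write a kernel to CSV
#'
#' Long-format exchange file with header `S, A, Y1, Y2, S_next, probability`.
#'
#' @param kernel A `joint_kernel`.
#' @param path Output path.
#' @export
write_kernel_csv <- function(kernel, path) {
  df <- as.data.frame(kernel)
  names(df)[names(df) == "prob"] <- "probability"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
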