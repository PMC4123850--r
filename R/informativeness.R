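# Blackwell comparison of information structures via garbling matrices.

#' Is one information structure at least as informative as another?
#'
#' Information structures are conditional probability arrays P(X | signal),
#' one column per signal outcome.  Signal W is at least as informative as Z
#' (in the Blackwell/garbling order) if there exists a column-stochastic
#' matrix T with `P_Z = P_W %*% T`: every Z-conditional distribution is a
#' mixture of W-conditional ones, so any decision achievable with Z is
#' achievable with W.  Existence is decided constructively by linear
#' programming: for each column z of `P_Z` the column of T minimizing the
#' max-norm residual of `P_W %*% t - z` subject to `t >= 0, sum(t) = 1` is
#' found with [boot::simplex()]; the structure pair is ordered iff every
#' minimized residual is at most `tol`.
#'
#' For the eagle model, knowing the fledging outcome (columns of
#' [signal_conditional_transition()]) is at least as informative about
#' next-year occupancy as knowing the action (columns of
#' [state_transition()]), with the explicit witness
#' [outcome_garbling_matrix()].
#'
#' @param P_W,P_Z Information structures over a common X space (equal row
#'   counts); columns must each sum to 1.
#' @param tol Feasibility tolerance (default 1e-8).
#' @return List: `informative` (logical), `T` (witness matrix if ordered,
#'   else `NULL`), `residual` (max-norm residual of the best T found).
#' @export
at_least_as_informative <- function(P_W, P_Z, tol = 1e-8) {
  P_W <- as.matrix(P_W); P_Z <- as.matrix(P_Z)
  if (nrow(P_W) != nrow(P_Z)) {
    stop("information structures must share the same X outcome space")
  }
  nW <- ncol(P_W)
  Tm <- matrix(0, nW, ncol(P_Z))
  eps_star <- 0
  for (col in seq_len(ncol(P_Z))) {
    z <- P_Z[, col]
    # variables x = (t_1..t_nW, eps); minimize eps subject to
    # |P_W t - z| <= eps, sum(t) = 1, x >= 0
    a <- c(rep(0, nW), 1)
    A1 <- rbind(cbind(P_W, -1), cbind(-P_W, -1))
    b1 <- c(z, -z)
    A3 <- matrix(c(rep(1, nW), 0), 1L)
    lp <- boot::simplex(a = a, A1 = A1, b1 = b1, A3 = A3, b3 = 1,
                        maxi = FALSE)
    if (lp$solved < 0) stop("linear program for garbling column failed")
    eps_star <- max(eps_star, lp$value)
    Tm[, col] <- lp$soln[seq_len(nW)]
  }
  if (eps_star > tol) {
    return(list(informative = FALSE, T = NULL, residual = eps_star))
  }
  # polish the witness: degenerate simplex bases can leave tiny negative
  # entries, so re-fit each column by nonnegative least squares with the
  # sum-to-one constraint enforced through a heavily weighted row
  lam <- 100
  Ab <- rbind(P_W, lam)
  for (col in seq_len(ncol(P_Z))) {
    t_col <- tryCatch(pracma::lsqnonneg(Ab, c(P_Z[, col], lam))$x,
                      error = function(e) pmax(Tm[, col], 0))
    Tm[, col] <- t_col / sum(t_col)
  }
  resid <- max(abs(P_W %*% Tm - P_Z))
  list(informative = resid <= tol, T = if (resid <= tol) Tm else NULL,
       residual = resid)
}

#' Verify a proposed garbling witness
#'
#' Checks that `T` is column-stochastic (within `tol`) and that
#' `P_W %*% T` reproduces `P_Z` with max-norm residual at most `tol`.
#'
#' @inheritParams at_least_as_informative
#' @param T Candidate garbling matrix.
#' @return List: `valid` (logical), `residual`.
#' @export
verify_garbling <- function(P_W, P_Z, T, tol = 1e-8) {
  stopifnot(nrow(T) == ncol(P_W), ncol(T) == ncol(P_Z))
  stoch <- all(T >= -tol) && all(abs(colSums(T) - 1) <= tol)
  residual <- max(abs(P_W %*% T - P_Z))
  list(valid = stoch && residual <= tol, residual = residual)
}
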