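# Discretized belief simplex over the three candidate models, with
# barycentric interpolation and Bayes updating of model weights.

#' Regular grid on the 3-model belief simplex
#'
#' All weight vectors with coordinates k/m summing to 1, where m is the grid
#' order.  Points are ordered lexicographically by (b1, b2); the three
#' vertices (complete certainty in one model) are always included.
#'
#' @param order Grid order m (points in steps of 1/m); default 100.
#' @return Object of class `belief_grid`: list with `order`, `points`
#'   (n x 3 matrix), and `n`.
#' @export
belief_grid <- function(order = 100L) {
  stopifnot(order >= 1, order == round(order))
  m <- as.integer(order)
  k1 <- rep(0:m, times = m + 1L - 0:m)
  k2 <- unlist(lapply(0:m, function(i) 0:(m - i)))
  pts <- cbind(b1 = k1, b2 = k2, b3 = m - k1 - k2) / m
  structure(list(order = m, points = pts, n = nrow(pts)),
            class = "belief_grid")
}

#' @export
print.belief_grid <- function(x, ...) {
  cat(sprintf("Belief simplex grid: order %d, %d points over 3 models\n",
              x$order, x$n))
  invisible(x)
}

# index of lattice point (i, j) = (m*b1, m*b2) in the belief_grid ordering
.grid_index <- function(m, i, j) {
  i * (m + 1L) - (i * (i - 1L)) %/% 2L + j + 1L
}

#' Nearest grid point to a belief vector
#'
#' Rounds m*B to the nearest lattice point on the simplex (largest-remainder
#' apportionment so the rounded coordinates still sum to m).  Used for policy
#' lookup during simulation; beliefs themselves are carried exactly.
#'
#' @param grid A `belief_grid`.
#' @param B Belief vector (length 3, sums to 1) or an n x 3 matrix of them.
#' @return Integer vector of grid-point indices.
#' @export
nearest_grid_point <- function(grid, B) {
  if (is.null(dim(B))) B <- matrix(B, ncol = 3L)
  m <- grid$order
  f <- B * m
  k <- floor(f)
  r <- f - k
  short <- m - rowSums(k)
  # hand the missing units to the largest fractional remainders
  ord <- t(apply(r, 1L, order, decreasing = TRUE))
  for (c in 1:3) {
    bump <- short >= c
    if (any(bump)) {
      idx <- cbind(which(bump), ord[bump, c])
      k[idx] <- k[idx] + 1
    }
  }
  .grid_index(m, as.integer(k[, 1L]), as.integer(k[, 2L]))
}

#' Barycentric interpolation weights on the belief grid
#'
#' Locates the simplex cell of the Kuhn triangulation containing a belief
#' vector and returns the three vertex indices and barycentric weights; a
#' value surface tabulated on the grid is interpolated as the weighted sum of
#' its vertex values.  Chosen over nearest-neighbour lookup because it is
#' exact for affine surfaces and preserves monotone orderings of value
#' surfaces up to O(1/m^2) curvature error.
#'
#' @param grid A `belief_grid`.
#' @param B Belief vector or n x 3 matrix.
#' @return List with `index` (n x 3 grid indices) and `w` (n x 3 weights
#'   summing to 1 per row).
#' @export
interp_weights <- function(grid, B) {
  if (is.null(dim(B))) B <- matrix(B, ncol = 3L)
  m <- grid$order
  f1 <- pmin(pmax(B[, 1L] * m, 0), m)
  f2 <- pmin(pmax(B[, 2L] * m, 0), m - f1)
  i <- pmin(floor(f1), m - 1e-9); i <- as.integer(i)
  j <- pmin(floor(f2), pmax(m - 1L - i, 0L)); j <- as.integer(j)
  r1 <- f1 - i
  r2 <- f2 - j
  upper <- (r1 + r2) > 1
  idx <- w <- matrix(0, nrow(B), 3L)
  lo <- !upper
  idx[lo, ] <- cbind(.grid_index(m, i[lo], j[lo]),
                     .grid_index(m, i[lo] + 1L, j[lo]),
                     .grid_index(m, i[lo], j[lo] + 1L))
  w[lo, ] <- cbind(1 - r1[lo] - r2[lo], r1[lo], r2[lo])
  if (any(upper)) {
    up <- upper
    idx[up, ] <- cbind(.grid_index(m, i[up] + 1L, j[up] + 1L),
                       .grid_index(m, i[up], j[up] + 1L),
                       .grid_index(m, i[up] + 1L, j[up]))
    w[up, ] <- cbind(r1[up] + r2[up] - 1, 1 - r1[up], 1 - r2[up])
  }
  list(index = idx, w = w)
}

#' Bayes update of model weights from an observed transition and signal
#'
#' Posterior weights B+ proportional to B_i * P_i(signal, S_next | S, A),
#' where P_i is candidate model i's joint kernel.  With identical kernels
#' the update is the identity; a degenerate prior is absorbing.
#'
#' @param B Prior weight vector over the candidate models.
#' @param kernels List of per-model `joint_kernel`s sharing one signal mode.
#' @param S,A Current occupancy and action counts.
#' @param Y Observed signal value(s): `c(Y1, Y2)` in mode `"full"`, a single
#'   count in modes `"unrestricted_only"`, `"restricted_only"`, `"total"`,
#'   and `NULL` in mode `"none"`.
#' @param S_next Observed next-year occupancy count.
#' @return Posterior weight vector (sums to 1).
#' @export
belief_update <- function(B, kernels, S, A, Y, S_next) {
  stopifnot(length(B) == length(kernels), all(B >= 0),
            abs(sum(B) - 1) < 1e-8)
  mode <- attr(kernels[[1L]], "mode")
  nsig <- length(.signal_cols(mode))
  if (length(Y) != nsig) {
    stop(sprintf("mode '%s' expects %d signal value(s), got %d",
                 mode, nsig, length(Y)))
  }
  sig_cols <- .signal_cols(mode)
  lik <- vapply(kernels, function(k) {
    df <- kernel_column(k, S, A)
    keep <- df$S_next == S_next
    for (ci in seq_along(sig_cols)) {
      keep <- keep & df[[sig_cols[ci]]] == Y[ci]
    }
    s <- df$prob[keep]
    if (length(s) != 1L) stop("observation outside the kernel's support")
    s
  }, numeric(1L))
  post <- B * lik
  total <- sum(post)
  if (total <= 0) {
    stop("observation has zero probability under every candidate model")
  }
  post / total
}
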