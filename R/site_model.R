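# Single-site probability model: the 6-row joint event table, its marginal
# state transition, and the fledging-outcome-conditional occupancy kernel.

# Canonical row/column layout of the single-site event table.  Rows are
# (Y1, Y2, S_next) triples: Y1 = success at an unrestricted site, Y2 = success
# at a restricted site, S_next = occupied next year.  Columns are the three
# feasible state/action pairs (restricting an empty site is not a logical
# action).
.site_rows <- data.frame(
  Y1 = c(0L, 0L, 1L, 0L, 0L, 1L),
  Y2 = c(0L, 1L, 0L, 0L, 1L, 0L),
  S_next = c(0L, 0L, 0L, 1L, 1L, 1L)
)
.site_cols <- c("empty_unrestricted", "occupied_unrestricted",
                "occupied_restricted")

#' Single-site joint event table
#'
#' The joint probability of the fledging-success signals and next-year
#' occupancy, conditional on the current state/action of one site.  Rows are
#' the six feasible (Y1, Y2, S_next) triples, where Y1 indicates successful
#' fledging at an unrestricted site and Y2 at a restricted site; columns are
#' the three state/action pairs: empty (necessarily unrestricted), occupied &
#' unrestricted, occupied & restricted.
#'
#' Structural zeros: an empty site can produce no success signal; Y2 is
#' impossible when unrestricted and Y1 impossible when restricted.  For an
#' empty site the column is (1 - p_c, p_c) over next-year occupancy; for an
#' occupied unrestricted site, e.g. P(Y1 = 1, occupied next) = p_u * p_s and
#' P(no success, empty next) = (1 - p_u)(1 - p_n).
#'
#' @param probs A `success_probs` object.
#' @param params A `site_params` object (supplies p_c, p_n, p_s).
#' @return 6 x 3 matrix with the (Y1, Y2, S_next) triples as an attribute
#'   `"events"`; each column sums to 1.
#' @export
site_event_table <- function(probs, params) {
  with(c(probs, params), {
    m <- cbind(
      empty_unrestricted = c(1 - p_c, 0, 0, p_c, 0, 0),
      occupied_unrestricted = c((1 - p_u) * (1 - p_n), 0, p_u * (1 - p_s),
                                (1 - p_u) * p_n, 0, p_u * p_s),
      occupied_restricted = c((1 - p_r) * (1 - p_n), p_r * (1 - p_s), 0,
                              (1 - p_r) * p_n, p_r * p_s, 0)
    )
    attr(m, "events") <- .site_rows
    m
  })
}

#' Single-site state transition matrix
#'
#' Marginalizes the joint event table over the success signals: a 2 x 3
#' matrix of P(S_next | state/action), rows (empty, occupied) next year,
#' columns as in [site_event_table()].  The occupied-next probability for an
#' occupied unrestricted site is (1 - p_u) p_n + p_u p_s (with p_r replacing
#' p_u when restricted); an empty site is colonized with probability p_c.
#'
#' @inheritParams site_event_table
#' @return 2 x 3 matrix with rows `empty_next`, `occupied_next`.
#' @export
state_transition <- function(probs, params) {
  et <- site_event_table(probs, params)
  ev <- attr(et, "events")
  m <- rbind(
    empty_next = colSums(et[ev$S_next == 0L, , drop = FALSE]),
    occupied_next = colSums(et[ev$S_next == 1L, , drop = FALSE])
  )
  colnames(m) <- .site_cols
  m
}

#' Occupancy kernel conditional on the fledging outcome
#'
#' P(S_next | outcome category) where the category records the site's fate
#' this season: empty (no breeding attempt), occupied & unsuccessful, or
#' occupied & successful.  Columns are (1 - p_c, p_c), (1 - p_n, p_n),
#' (1 - p_s, p_s).  Knowing the fledging outcome makes the management action
#' uninformative about next-year occupancy: composing this kernel with the
#' action-to-outcome garbling matrix of [outcome_garbling_matrix()]
#' reproduces [state_transition()] exactly.
#'
#' @param params A `site_params` object.
#' @return 2 x 3 matrix, rows (empty_next, occupied_next), columns
#'   (empty, occupied_unsuccessful, occupied_successful).
#' @export
signal_conditional_transition <- function(params) {
  m <- with(params, cbind(
    empty = c(1 - p_c, p_c),
    occupied_unsuccessful = c(1 - p_n, p_n),
    occupied_successful = c(1 - p_s, p_s)
  ))
  rownames(m) <- c("empty_next", "occupied_next")
  m
}

#' Garbling matrix from state/action to fledging outcome
#'
#' The column-stochastic matrix T mapping the outcome-conditional occupancy
#' kernel onto the action-conditional one:
#' `signal_conditional_transition() %*% T == state_transition()`.
#' Its columns give the distribution of the fledging-outcome category for
#' each state/action pair: an empty site stays in the empty category; an
#' occupied unrestricted site is successful with probability p_u, a
#' restricted one with probability p_r.  The existence of this matrix is a
#' Blackwell-ordering witness that the fledging outcome is at least as
#' informative as the action about next-year occupancy; see
#' [at_least_as_informative()].
#'
#' @param probs A `success_probs` object.
#' @return 3 x 3 column-stochastic matrix.
#' @export
outcome_garbling_matrix <- function(probs) {
  with(probs, {
    m <- cbind(
      empty_unrestricted = c(1, 0, 0),
      occupied_unrestricted = c(0, 1 - p_u, p_u),
      occupied_restricted = c(0, 1 - p_r, p_r)
    )
    rownames(m) <- c("empty", "occupied_unsuccessful", "occupied_successful")
    m
  })
}
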