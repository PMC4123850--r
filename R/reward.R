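#' Reward specification
#'
#' The management objective trades off expected fledging success against
#' hiker access.  The default Cobb-Douglas form is
#' \deqn{R(S, A, B) = E[Y | S, A, B]^{\alpha} (N - A)^{1-\alpha}}
#' with `alpha = 0.85`: smooth in both arguments, zero when either expected
#' success or access is zero, and increasing in both ("rewards more of
#' both").  A linear form `alpha * E[Y] + (1 - alpha) * (N - A)` is available
#' for sensitivity analysis.
#'
#' @param alpha Utility exponent (weight on breeding success), in (0,1).
#' @param form `"cobb_douglas"` (default) or `"linear"`.
#' @return Object of class `reward_spec`.
#' @export
reward_spec <- function(alpha = 0.85, form = c("cobb_douglas", "linear")) {
  form <- match.arg(form)
  stopifnot(alpha > 0, alpha < 1)
  structure(list(alpha = alpha, form = form), class = "reward_spec")
}

#' Expected one-year reward under model uncertainty
#'
#' The success count Y is replaced by its conditional expectation given the
#' state, action and beliefs:
#' `E[Y | S, A, B] = sum_i B_i (A p_r_i + (S - A) p_u_i)`.
#'
#' @param S Occupied-site count.
#' @param A Restricted-site count (A <= S).
#' @param B Belief vector over candidate models.
#' @param probs_list List of per-model `success_probs`.
#' @param spec A `reward_spec`.
#' @param params A `site_params` (supplies `n_sites`).
#' @return Scalar reward.
#' @export
expected_reward <- function(S, A, B, probs_list, spec, params) {
  stopifnot(A <= S, length(B) == length(probs_list))
  ey <- sum(vapply(seq_along(B), function(i) {
    B[i] * (A * probs_list[[i]]$p_r + (S - A) * probs_list[[i]]$p_u)
  }, numeric(1L)))
  .reward_value(ey, A, spec, params$n_sites)
}

.reward_value <- function(ey, A, spec, N) {
  if (spec$form == "cobb_douglas") {
    ey^spec$alpha * (N - A)^(1 - spec$alpha)
  } else {
    spec$alpha * ey + (1 - spec$alpha) * (N - A)
  }
}
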