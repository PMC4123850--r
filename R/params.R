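#' Site and management parameters
#'
#' Container for all single-site demographic parameters, the fledging-success
#' regression coefficients, and the management constants of the eagle
#' nest-restriction problem.
#'
#' @details
#' The occupancy process is a patch colonization/extinction Markov chain:
#' an empty territory is colonized next year with probability `p_c`; an
#' occupied territory is re-occupied with probability `p_n` after an
#' unsuccessful fledging season and `p_s` after a successful one.  Fledging
#' success at an occupied site follows a logistic regression on the arctic
#' hare abundance index `h`, with an additive disturbance effect `beta_dist`
#' (non-positive in all candidate models) applied only when hiker access is
#' unrestricted; see [success_probabilities()].
#'
#' Management constants: `n_sites` territories are managed jointly; the reward
#' trades expected fledging successes against hiker access with Cobb-Douglas
#' exponent `alpha`; future rewards are discounted by `discount` per year.
#'
#' @param p_c Colonization probability of an empty site.
#' @param p_n Re-occupancy probability after unsuccessful fledging.
#' @param p_s Re-occupancy probability after successful fledging.
#' @param beta_int Logistic intercept.
#' @param beta_hare Coefficient on the hare abundance index.
#' @param beta_dist Disturbance coefficient (applied at unrestricted sites).
#' @param hare Hare abundance index; default is the long-run mean 9.4.
#' @param n_sites Number of managed territories.
#' @param alpha Utility exponent in (0,1).
#' @param discount Annual discount factor in \[0,1).
#' @return An object of class `site_params` (a named list).
#' @examples
#' p <- site_params()
#' success_probabilities(p, -0.2)
#' @export
site_params <- function(p_c = 0.2315, p_n = 0.9427, p_s = 0.9573,
                        beta_int = -0.75, beta_hare = 0.06, beta_dist = -0.2,
                        hare = 9.4, n_sites = 25, alpha = 0.85,
                        discount = 0.98) {
  stopifnot(
    p_c >= 0, p_c <= 1, p_n >= 0, p_n <= 1, p_s >= 0, p_s <= 1,
    alpha > 0, alpha < 1, discount >= 0, discount < 1,
    n_sites >= 1, n_sites == round(n_sites), hare >= 0
  )
  structure(
    list(p_c = p_c, p_n = p_n, p_s = p_s,
         beta_int = beta_int, beta_hare = beta_hare, beta_dist = beta_dist,
         hare = hare, n_sites = as.integer(n_sites),
         alpha = alpha, discount = discount),
    class = "site_params"
  )
}

#' @export
print.site_params <- function(x, ...) {
  cat("Site/management parameters:\n")
  cat(sprintf("  occupancy: p_c = %.4f, p_n = %.4f, p_s = %.4f\n",
              x$p_c, x$p_n, x$p_s))
  cat(sprintf("  success logit: %.2f %+.2f*dist %+.2f*hare (h = %.1f)\n",
              x$beta_int, x$beta_dist, x$beta_hare, x$hare))
  cat(sprintf("  management: N = %d sites, alpha = %.2f, discount = %.2f\n",
              x$n_sites, x$alpha, x$discount))
  invisible(x)
}

#' Read site parameters from a plain-text configuration file
#'
#' Parses a `key = value` file with keys `p_c, p_n, p_s, beta_int, beta_hare,
#' beta_dist, hare, n_sites, alpha, discount`.  Missing keys fall back to the
#' defaults of [site_params()]; unknown keys are an error.  Lines starting
#' with `#` and blank lines are ignored.
#'
#' @param path Path to the configuration file.
#' @return A `site_params` object.
#' @export
read_site_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!all(grepl("=", lines, fixed = TRUE))) {
    stop("every non-comment line must have the form 'key = value'")
  }
  keys <- trimws(sub("=.*$", "", lines))
  vals <- as.numeric(trimws(sub("^[^=]*=", "", lines)))
  allowed <- c("p_c", "p_n", "p_s", "beta_int", "beta_hare", "beta_dist",
               "hare", "n_sites", "alpha", "discount")
  bad <- setdiff(keys, allowed)
  if (length(bad)) stop("unknown parameter key(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(keys)) stop("duplicated parameter key")
  if (anyNA(vals)) stop("non-numeric parameter value")
  do.call(site_params, as.list(stats::setNames(vals, keys)))
}

#' Candidate disturbance-effect models for one uncertainty assumption
#'
#' Returns the three candidate models (no / moderate / strong disturbance
#' effect) under one of the three assumption regimes about which success
#' probability is known:
#'
#' * `"pr_known"`: the restricted success probability is known; the three
#'   models share the intercept and differ in the disturbance coefficient
#'   (0, -0.2, -0.6).
#' * `"pu_known"`: the unrestricted success probability is known (all models
#'   share `beta_int + beta_dist = -0.95`); uncertainty is about the
#'   restricted probability.
#' * `"both_uncertain"`: intermediate case, both probabilities vary across
#'   models.
#'
#' @param case One of `"pr_known"`, `"both_uncertain"`, `"pu_known"`.
#' @param params A `site_params` object supplying the shared demographic and
#'   management constants (its `beta_*` fields are overridden per model).
#' @return An object of class `uncertainty_case`: list with elements `case`,
#'   `params`, `beta_int` (length 3), `beta_dist` (length 3), `model_names`,
#'   and `best_signal` (the signal mode that is most informative for the
#'   parameters left uncertain in that case).
#' @export
uncertainty_case <- function(case = c("pr_known", "both_uncertain", "pu_known"),
                             params = site_params()) {
  case <- match.arg(case)
  tab <- switch(case,
    pr_known = list(beta_int = c(-0.75, -0.75, -0.75),
                    beta_dist = c(0, -0.2, -0.6),
                    best_signal = "unrestricted_only"),
    both_uncertain = list(beta_int = c(-0.85, -0.75, -0.65),
                          beta_dist = c(0, -0.2, -0.5),
                          best_signal = "full"),
    pu_known = list(beta_int = c(-0.95, -0.75, -0.55),
                    beta_dist = c(0, -0.2, -0.4),
                    best_signal = "restricted_only")
  )
  structure(
    list(case = case, params = params,
         beta_int = tab$beta_int, beta_dist = tab$beta_dist,
         model_names = c("no_disturbance", "moderate", "strong"),
         best_signal = tab$best_signal),
    class = "uncertainty_case"
  )
}

#' @export
print.uncertainty_case <- function(x, ...) {
  cat(sprintf("Uncertainty case '%s' (3 candidate models):\n", x$case))
  sp <- case_success_probs(x)
  for (i in 1:3) {
    cat(sprintf("  %d) %-15s beta_int = %+.2f, beta_dist = %+.2f -> p_u = %.3f, p_r = %.3f\n",
                i, x$model_names[i], x$beta_int[i], x$beta_dist[i],
                sp[[i]]$p_u, sp[[i]]$p_r))
  }
  cat(sprintf("  best signal: %s\n", x$best_signal))
  invisible(x)
}

#' Success probabilities for every candidate model of a case
#'
#' @param case_obj An `uncertainty_case`.
#' @param hare Optional hare index overriding the case's parameter value.
#' @param rounded If `TRUE`, round each probability to 3 decimals (the
#'   precision at which the reference parameter table is printed); downstream
#'   multi-site tables in the source analysis were computed from the rounded
#'   values.
#' @return List of 3 `success_probs` objects.
#' @export
case_success_probs <- function(case_obj, hare = NULL, rounded = FALSE) {
  stopifnot(inherits(case_obj, "uncertainty_case"))
  p <- case_obj$params
  if (!is.null(hare)) p$hare <- hare
  lapply(1:3, function(i) {
    p$beta_int <- case_obj$beta_int[i]
    sp <- success_probabilities(p, case_obj$beta_dist[i])
    if (rounded) {
      sp$p_u <- round(sp$p_u, 3)
      sp$p_r <- round(sp$p_r, 3)
    }
    sp
  })
}

#' Fledging success probabilities under restriction and no restriction
#'
#' Logistic model for the probability that an occupied territory fledges
#' young, as a function of the hare abundance index and of hiker disturbance:
#' \deqn{p_r = \mathrm{logit}^{-1}(\beta_{INT} + \beta_{HARE} h)}
#' \deqn{p_u = \mathrm{logit}^{-1}(\beta_{INT} + \beta_{DIST} + \beta_{HARE} h)}
#' Restriction removes the disturbance term, so with `beta_dist <= 0` the
#' restricted probability is at least the unrestricted one.
#'
#' @param params A `site_params` object (supplies `beta_int`, `beta_hare`,
#'   `hare`).
#' @param model_beta_dist Disturbance coefficient of the candidate model;
#'   defaults to `params$beta_dist`.
#' @return An object of class `success_probs`: list with `p_u`, `p_r`.
#' @export
success_probabilities <- function(params, model_beta_dist = params$beta_dist) {
  eta <- params$beta_int + params$beta_hare * params$hare
  structure(
    list(p_u = stats::plogis(eta + model_beta_dist),
         p_r = stats::plogis(eta)),
    class = "success_probs"
  )
}

#' Construct success probabilities directly
#'
#' Wraps a given pair of probabilities as a `success_probs` object, e.g. the
#' 3-decimal printed values used to reproduce the reference multi-site tables.
#'
#' @param p_u,p_r Success probabilities in \[0,1\].
#' @export
success_probs <- function(p_u, p_r) {
  stopifnot(p_u >= 0, p_u <= 1, p_r >= 0, p_r <= 1)
  structure(list(p_u = p_u, p_r = p_r), class = "success_probs")
}

#' @export
print.success_probs <- function(x, ...) {
  cat(sprintf("Fledging success: p_u = %.4f (unrestricted), p_r = %.4f (restricted)\n",
              x$p_u, x$p_r))
  invisible(x)
}
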