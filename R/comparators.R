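# Comparator propensity-score methods: pooled main-effects logistic
# regression, per-subgroup logistic regression, and the just-identified
# covariate balancing propensity score (CBPS; overall balance conditions
# only). All are outcome-free and emit `ps_fit` objects so the same
# weighting, diagnostic and effect-estimation functions apply.

#' Pooled main-effects logistic propensity model
#'
#' Maximum-likelihood logistic regression of treatment on the subgroup
#' indicators and covariate main effects (design `[1, S, Z]`, rank-reduced).
#' Its score equations \eqn{\sum_i (T_i - \pi_i) X_i = 0} are the MLE normal
#' equations, not balance conditions: inverse-probability weights from this
#' fit balance covariates only asymptotically under a correctly specified
#' model.
#'
#' @param data A [subgroup_data()] object.
#' @param estimand `"ATE"` or `"ATT"` — recorded so [ps_weights()] builds the
#'   matching weights; the fitted probabilities are the same either way.
#' @return A `ps_fit` with `method = "logistic"`.
#' @export
logistic_ps <- function(data, estimand = c("ATE", "ATT")) {
  assert_subgroup_data(data)
  estimand <- match.arg(estimand)
  design <- reduce_rank(build_design(sg_covmatrix(data), sg_submatrix(data),
                                     interactions = FALSE))
  treat <- sg_treatment(data)
  fit <- glm.fit(design$matrix, treat, family = binomial())
  p <- clip_prob(fit$fitted.values)
  if (!fit$converged || any(p <= 1e-10 | p >= 1 - 1e-10)) {
    if (!fit$converged) {
      stop_sgbal("Logistic regression did not converge (possible separation).",
                 "sgbal_convergence_error")
    }
  }
  structure(
    list(theta = setNames(fit$coefficients, colnames(design$matrix)),
         probs = p, estimand = estimand,
         balance_residual = NA_real_, solver_path = "mle",
         loss_value = NA_real_, converged = fit$converged,
         iterations = fit$iter, design = design, treat = treat,
         method = "logistic"),
    class = "ps_fit"
  )
}

#' Per-subgroup logistic propensity models
#'
#' Fits a separate main-effects logistic regression (intercept + covariates)
#' within each subgroup and assembles the fitted probabilities by membership.
#' Defined only when the subgroups partition the sample; overlapping
#' subgroups would assign a subject several conflicting scores.
#'
#' @inheritParams logistic_ps
#' @return A `ps_fit` with `method = "logistic_s"` and a `subfits` element
#'   (per-subgroup coefficient vectors).
#' @export
logistic_subgroup_ps <- function(data, estimand = c("ATE", "ATT")) {
  assert_subgroup_data(data)
  estimand <- match.arg(estimand)
  counts <- subgroup_counts(data)
  if (!isTRUE(attr(counts, "is_partition"))) {
    stop_sgbal(
      "Per-subgroup logistic fitting requires mutually exclusive, exhaustive subgroups.",
      "sgbal_unsupported_scheme_error"
    )
  }
  S <- sg_submatrix(data)
  Z <- sg_covmatrix(data)
  treat <- sg_treatment(data)
  p <- rep(NA_real_, nrow(data))
  subfits <- list()
  ok <- TRUE
  iters <- 0
  for (k in seq_len(ncol(S))) {
    idx <- S[, k] == 1
    Xk <- cbind(`(intercept)` = 1, Z[idx, , drop = FALSE])
    fk <- glm.fit(Xk, treat[idx], family = binomial())
    p[idx] <- fk$fitted.values
    subfits[[colnames(S)[k]]] <- setNames(fk$coefficients, colnames(Xk))
    ok <- ok && fk$converged
    iters <- max(iters, fk$iter)
  }
  structure(
    list(theta = unlist(subfits), probs = clip_prob(p), estimand = estimand,
         balance_residual = NA_real_, solver_path = "mle",
         loss_value = NA_real_, converged = ok, iterations = iters,
         design = NULL, treat = treat, subfits = subfits,
         method = "logistic_s"),
    class = "ps_fit"
  )
}

#' Just-identified CBPS comparator
#'
#' The covariate balancing propensity score with main effects of the
#' covariates and the subgroup indicators only (design `[1, S, Z]`): exact
#' overall covariate balance and equal per-subgroup weight totals, but no
#' constraint on within-subgroup covariate means. Equivalent to
#' `balance_ps(data, estimand, interactions = FALSE)`.
#'
#' @inheritParams logistic_ps
#' @param control A [balance_control()] list.
#' @return A `ps_fit` with `method = "cbps"`.
#' @export
cbps_ps <- function(data, estimand = c("ATE", "ATT"),
                    control = balance_control()) {
  estimand <- match.arg(estimand)
  balance_ps(data, estimand, interactions = FALSE, control = control)
}
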