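# Hajek-normalized subgroup and overall treatment-effect estimates.

#' Subgroup and overall weighted treatment-effect estimates
#'
#' For each subgroup k the effect is the Hajek contrast
#' \deqn{\hat\tau_k = \frac{\sum_i S_{ik} w_i T_i Y_i}{\sum_i S_{ik} w_i T_i}
#'   - \frac{\sum_i S_{ik} w_i (1-T_i) Y_i}{\sum_i S_{ik} w_i (1-T_i)},}
#' i.e. the difference of weighted outcome means with weights normalized
#' within each subgroup-by-arm cell; the overall row uses the whole sample.
#' Hajek normalization makes the estimates invariant to rescaling all weights
#' by a positive constant. Whether the estimate targets the ATE or the ATT is
#' determined by how the weights were built.
#'
#' @param data A [subgroup_data()] object with an outcome column; missing
#'   outcomes are an error here (weights and balance never need Y, effect
#'   estimation does).
#' @param weights A `ps_weights` vector, a `ps_fit`, or a plain numeric
#'   vector of non-negative weights.
#' @return A tibble of class `effect_estimates`: one row per scope
#'   (`"overall"` then each subgroup) with `estimate`, weighted arm means
#'   `mean_treated` / `mean_untreated`, and arm weight totals `wsum_treated` /
#'   `wsum_untreated`. The weights' estimand (if known) is in the `estimand`
#'   attribute.
#' @examples
#' d <- sim_design(n_per_subgroup = 100)
#' dat <- simulate_subgroups(d, seed = 1)
#' subgroup_effects(dat, ps_weights(balance_ps(dat, "ATE")))
#' @export
subgroup_effects <- function(data, weights) {
  assert_subgroup_data(data)
  y <- sg_outcome(data)
  if (is.null(y)) {
    stop_sgbal("No outcome column declared; effect estimation needs Y.",
               "sgbal_config_error")
  }
  if (anyNA(y)) {
    stop_sgbal("Outcome contains missing values; effect estimation needs complete Y.",
               "sgbal_validation_error")
  }
  estimand <- NA_character_
  if (inherits(weights, "ps_fit")) {
    estimand <- weights$estimand
    weights <- ps_weights(weights)
  }
  if (inherits(weights, "ps_weights")) {
    estimand <- attr(weights, "estimand") %||% estimand
  }
  w <- as.numeric(weights)
  if (length(w) != nrow(data) || any(w < 0) || any(!is.finite(w))) {
    stop_sgbal("`weights` must be finite, non-negative, one per subject.",
               "sgbal_validation_error")
  }
  treat <- sg_treatment(data)
  S <- cbind(overall = rep(1, nrow(data)), sg_submatrix(data))

  out <- purrr::map_dfr(seq_len(ncol(S)), function(k) {
    s <- S[, k]
    w1 <- sum(s * w * treat)
    w0 <- sum(s * w * (1 - treat))
    if (w1 <= 0 || w0 <= 0) {
      stop_sgbal(
        paste0("Scope '", colnames(S)[k], "' has an arm with zero total weight."),
        "sgbal_empty_arm_error"
      )
    }
    m1 <- sum(s * w * treat * y) / w1
    m0 <- sum(s * w * (1 - treat) * y) / w0
    tibble(scope = colnames(S)[k], estimate = m1 - m0,
           mean_treated = m1, mean_untreated = m0,
           wsum_treated = w1, wsum_untreated = w0)
  })
  attr(out, "estimand") <- estimand
  class(out) <- c("effect_estimates", class(out))
  out
}
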