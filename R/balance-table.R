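# Weighted standardized-difference (S/D) balance diagnostics.

#' Weighted standardized difference between treatment arms
#'
#' The absolute difference in weighted means between treated and untreated
#' subjects, divided by the pooled standard deviation of the weighted data,
#' in percent: \eqn{100 |\bar m_1 - \bar m_0| / s_{pool}} with
#' \eqn{s_{pool} = \sqrt{(v_1 + v_0)/2}}. Means and variances use weights
#' normalized to sum 1 within each arm; variances use the population
#' (divide-by-total-weight) convention. 5% and 10% are the conventional
#' balance benchmarks.
#'
#' @param x Numeric vector (a covariate or transformation).
#' @param treat 0/1 treatment vector.
#' @param w Non-negative weights (unit weights give the unweighted S/D).
#' @return The S/D in percent; `Inf` (with a warning) when the pooled SD is
#'   zero but the means differ; 0 when both arms are constant and equal.
#' @examples
#' standardized_difference(c(1, 3, 0, 2), c(1, 1, 0, 0), rep(1, 4)) # 100
#' @export
standardized_difference <- function(x, treat, w) {
  stopifnot(length(x) == length(treat), length(x) == length(w))
  if (any(w < 0)) {
    stop_sgbal("Weights must be non-negative.", "sgbal_validation_error")
  }
  w1 <- sum(w[treat == 1])
  w0 <- sum(w[treat == 0])
  if (w1 <= 0 || w0 <= 0) {
    stop_sgbal("An arm has zero total weight; S/D undefined.",
               "sgbal_empty_arm_error")
  }
  arm_stats <- function(arm) {
    wi <- w[treat == arm] / sum(w[treat == arm])
    xi <- x[treat == arm]
    m <- sum(wi * xi)
    v <- sum(wi * (xi - m)^2)
    c(m, v)
  }
  s1 <- arm_stats(1)
  s0 <- arm_stats(0)
  diff <- abs(s1[1] - s0[1])
  s_pool <- sqrt((s1[2] + s0[2]) / 2)
  if (s_pool == 0) {
    if (diff == 0) return(0)
    warn("Pooled SD is zero with unequal weighted means; S/D is infinite.")
    return(Inf)
  }
  100 * diff / s_pool
}

#' Balance table: S/D per covariate, overall and within each subgroup
#'
#' Computes the weighted standardized difference of every covariate (and any
#' supplied transformation columns) between treatment arms, in the overall
#' sample and restricted to the members of each subgroup.
#'
#' @param data A [subgroup_data()] object.
#' @param weights A `ps_weights` vector, a `ps_fit` (its weights are used), or
#'   a plain numeric vector; unit weights give the unweighted table.
#' @param extra Optional named list of numeric vectors (covariate
#'   transformations, e.g. squares or products) to include alongside the
#'   covariates.
#' @return A tibble of class `balance_table` with columns `scope`
#'   (`"overall"` or a subgroup name), `covariate`, `sd_pct`, `mean_treated`,
#'   `mean_untreated`, `pool_sd`, and `flag` (`"zero-arm"` rows are kept,
#'   flagged, with `NA` statistics).
#' @examples
#' d <- sim_design(n_per_subgroup = 100)
#' dat <- simulate_subgroups(d, seed = 1)
#' balance_table(dat, rep(1, nrow(dat))) # unweighted
#' @export
balance_table <- function(data, weights, extra = NULL) {
  assert_subgroup_data(data)
  if (inherits(weights, "ps_fit")) weights <- ps_weights(weights)
  w <- as.numeric(weights)
  if (length(w) != nrow(data)) {
    stop_sgbal("`weights` must have one entry per subject.",
               "sgbal_config_error")
  }
  treat <- sg_treatment(data)
  Z <- sg_covmatrix(data)
  cols <- c(
    stats::setNames(lapply(seq_len(ncol(Z)), function(j) Z[, j]),
                    colnames(Z)),
    extra %||% list()
  )
  S <- sg_submatrix(data)
  scopes <- c(list(overall = rep(TRUE, nrow(data))),
              stats::setNames(lapply(seq_len(ncol(S)), function(k) S[, k] == 1),
                              colnames(S)))

  rows <- purrr::map_dfr(names(scopes), function(sc) {
    sel <- scopes[[sc]]
    purrr::map_dfr(names(cols), function(cv) {
      x <- cols[[cv]][sel]
      tr <- treat[sel]
      wi <- w[sel]
      if (sum(wi[tr == 1]) <= 0 || sum(wi[tr == 0]) <= 0) {
        return(tibble(scope = sc, covariate = cv, sd_pct = NA_real_,
                      mean_treated = NA_real_, mean_untreated = NA_real_,
                      pool_sd = NA_real_, flag = "zero-arm"))
      }
      m1 <- sum(wi[tr == 1] * x[tr == 1]) / sum(wi[tr == 1])
      m0 <- sum(wi[tr == 0] * x[tr == 0]) / sum(wi[tr == 0])
      v1 <- sum(wi[tr == 1] / sum(wi[tr == 1]) * (x[tr == 1] - m1)^2)
      v0 <- sum(wi[tr == 0] / sum(wi[tr == 0]) * (x[tr == 0] - m0)^2)
      sp <- sqrt((v1 + v0) / 2)
      sdp <- if (sp == 0) {
        if (abs(m1 - m0) == 0) 0 else Inf
      } else {
        100 * abs(m1 - m0) / sp
      }
      tibble(scope = sc, covariate = cv, sd_pct = sdp, mean_treated = m1,
             mean_untreated = m0, pool_sd = sp,
             flag = if (is.infinite(sdp)) "degenerate-sd" else NA_character_)
    })
  })
  class(rows) <- c("balance_table", class(rows))
  rows
}

#' Boxplot-style balance display
#'
#' Dot plot of the standardized differences per covariate, faceted by scope,
#' with the conventional 5% and 10% reference lines.
#'
#' @param object A `balance_table`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.balance_table <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[is.finite(df$sd_pct), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sd_pct, y = .data$covariate)) +
    ggplot2::geom_vline(xintercept = c(5, 10),
                        linetype = c("dashed", "solid"),
                        colour = c("darkgreen", "red"), linewidth = 0.3) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~scope) +
    ggplot2::labs(x = "standardized difference (%)", y = NULL) +
    ggplot2::theme_bw()
}
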