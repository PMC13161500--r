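# Nonparametric subgroup-balancing fit: Gaussian kernel PCA features with
# balance-driven bandwidth selection. For each candidate bandwidth the
# kernel feature block replaces the raw covariates in the subgroup-interaction
# design; the bandwidth is chosen by the balance it induces on the ORIGINAL
# covariates — best subgroup balance subject to overall-balance control.
# Tuning never sees the outcome.

candidate_diagnostics <- function(data, fit) {
  w <- ps_weights(fit, allow_unconverged = TRUE)
  bt <- balance_table(data, w)
  overall <- bt$sd_pct[bt$scope == "overall"]
  subgrp <- bt$sd_pct[bt$scope != "overall"]
  list(
    overall_max = max(overall),
    subgroup_max = max(subgrp),
    subgroup_mean = mean(subgrp)
  )
}

# Selection rule on a candidate table with columns sigma, converged,
# feasible, overall_max, subgroup_max, subgroup_mean: among feasible
# candidates minimize the worst subgroup S/D (ties: mean subgroup S/D, then
# smaller sigma); with no feasible candidate, fall back to the converged
# candidate with the smallest overall S/D ("infeasible-relaxed").
select_bandwidth <- function(cand) {
  pool <- which(cand$feasible)
  if (length(pool) > 0) {
    ord <- order(cand$subgroup_max[pool], cand$subgroup_mean[pool],
                 cand$sigma[pool])
    return(list(index = pool[ord[1]], selection = "feasible"))
  }
  conv_idx <- which(cand$converged)
  ord <- order(cand$overall_max[conv_idx], cand$sigma[conv_idx])
  list(index = conv_idx[ord[1]], selection = "infeasible-relaxed")
}

#' Kernelized subgroup-balancing propensity fit with bandwidth tuning
#'
#' Runs the exact-balance fit of [balance_ps()] on Gaussian kernel
#' principal-component features (99% eigenvalue mass by default) for each
#' candidate bandwidth, evaluates the weighted standardized differences of
#' the original covariates overall and within each subgroup, and selects the
#' bandwidth that minimizes the worst subgroup S/D among candidates whose
#' overall S/D stays within `tau_overall`. Ties are broken by the mean
#' subgroup S/D, then by the smaller bandwidth. If no converged candidate
#' meets the overall-balance constraint, the converged candidate with the
#' smallest overall S/D is selected and flagged `"infeasible-relaxed"`.
#'
#' Covariates are standardized (mean 0, sd 1 per column) before distances and
#' kernel evaluation; subgroup indicators enter only through the design
#' expansion, not the kernel.
#'
#' @param data A [subgroup_data()] object.
#' @param estimand `"ATE"` or `"ATT"`.
#' @param grid Candidate bandwidths; default [bandwidth_grid()] on the
#'   standardized covariates (20 log-spaced values between the 0.1/0.9
#'   pairwise-distance quantiles).
#' @param tau_overall Overall-balance feasibility threshold in S/D percent
#'   (default 5).
#' @param variance_target Eigenvalue mass retained by the kernel features.
#' @param control A [balance_control()] list passed to the inner fits. The
#'   default disables the GMM fallback during the candidate scan: bandwidths
#'   whose feature designs admit no finite balance solution (separation-like
#'   geometry, typical at the small-bandwidth end where the feature count
#'   approaches N) are simply recorded as unconverged candidates.
#' @return A `kernel_ps_fit` (also a `ps_fit`, usable with [ps_weights()],
#'   [balance_table()], [subgroup_effects()]): the selected fit plus
#'   `sigma` (selected bandwidth), `candidates` (one-row-per-bandwidth
#'   tibble: `sigma`, `converged`, `overall_max`, `subgroup_max`,
#'   `subgroup_mean`, `feasible`, `selected`), `selection` (`"feasible"` or
#'   `"infeasible-relaxed"`), `tau_overall`, and `kernel` (the selected
#'   [kernel_features()]).
#' @examples
#' \donttest{
#' d <- sim_design(n_per_subgroup = 50)
#' dat <- simulate_subgroups(d, seed = 1)
#' kfit <- kernel_balance_ps(dat, "ATE", grid = c(2, 4, 8))
#' kfit$sigma
#' }
#' @export
kernel_balance_ps <- function(data, estimand = c("ATE", "ATT"), grid = NULL,
                              tau_overall = 5, variance_target = 0.99,
                              control = balance_control(max_iter = 80,
                                                        gmm_fallback = FALSE)) {
  assert_subgroup_data(data)
  estimand <- match.arg(estimand)
  Zs <- standardize_cols(sg_covmatrix(data))
  grid <- grid %||% bandwidth_grid(Zs)
  if (length(grid) == 0) {
    stop_sgbal("Bandwidth grid is empty.", "sgbal_config_error")
  }

  fits <- vector("list", length(grid))
  kf_list <- vector("list", length(grid))
  rows <- vector("list", length(grid))
  failures <- character(0)
  for (j in seq_along(grid)) {
    sigma <- grid[j]
    rec <- tryCatch({
      kf <- kernel_features(gaussian_kernel(Zs, sigma),
                            variance_target = variance_target, sigma = sigma)
      fit <- balance_ps(data, estimand, base_block = kf$features,
                        control = control)
      diag <- candidate_diagnostics(data, fit)
      fits[[j]] <- fit
      kf_list[[j]] <- kf
      tibble(sigma = sigma, n_features = kf$n_features,
             converged = fit$converged,
             overall_max = diag$overall_max,
             subgroup_max = diag$subgroup_max,
             subgroup_mean = diag$subgroup_mean)
    }, error = function(e) {
      failures <<- c(failures,
                     sprintf("sigma=%.4g: %s", sigma, conditionMessage(e)))
      tibble(sigma = sigma, n_features = NA_integer_, converged = FALSE,
             overall_max = NA_real_, subgroup_max = NA_real_,
             subgroup_mean = NA_real_)
    })
    rows[[j]] <- rec
  }
  cand <- dplyr::bind_rows(rows)
  cand$feasible <- cand$converged & !is.na(cand$overall_max) &
    cand$overall_max <= tau_overall

  conv_idx <- which(cand$converged)
  if (length(conv_idx) == 0) {
    stop_sgbal(
      paste0("No bandwidth candidate converged.\n",
             paste(failures, collapse = "\n")),
      "sgbal_convergence_error"
    )
  }
  chosen <- select_bandwidth(cand)
  sel <- chosen$index
  selection <- chosen$selection
  cand$selected <- seq_len(nrow(cand)) == sel

  out <- fits[[sel]]
  out$method <- "kernel_balance"
  out$sigma <- cand$sigma[sel]
  out$candidates <- cand
  out$selection <- selection
  out$tau_overall <- tau_overall
  out$kernel <- kf_list[[sel]]
  class(out) <- c("kernel_ps_fit", "ps_fit")
  out
}

#' @export
print.kernel_ps_fit <- function(x, ...) {
  cat(sprintf(
    "<kernel_ps_fit> estimand=%s, sigma=%.4g (%s; %d candidates), %d kernel features\n  max subgroup S/D %.2f%%, max overall S/D %.2f%%\n",
    x$estimand, x$sigma, x$selection, nrow(x$candidates),
    x$kernel$n_features,
    x$candidates$subgroup_max[x$candidates$selected],
    x$candidates$overall_max[x$candidates$selected]
  ))
  invisible(x)
}

#' @export
tidy.kernel_ps_fit <- function(x, ...) {
  as_tibble(x$candidates)
}

#' Bandwidth-tuning trace plot
#'
#' Overall and worst-subgroup S/D per candidate bandwidth, with the
#' feasibility threshold and the selected bandwidth marked.
#'
#' @param object A `kernel_ps_fit`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.kernel_ps_fit <- function(object, ...) {
  cand <- object$candidates
  df <- tidyr::pivot_longer(
    cand, c("overall_max", "subgroup_max"),
    names_to = "scope", values_to = "sd_pct"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sigma, y = .data$sd_pct,
                                   colour = .data$scope)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$converged)) +
    ggplot2::geom_hline(yintercept = object$tau_overall, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$sigma, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "bandwidth", y = "max S/D (%)") +
    ggplot2::theme_bw()
}
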