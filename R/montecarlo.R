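# Monte-Carlo harness: repeatedly draw from a simulation design, fit the
# requested propensity methods on the same dataset within each repetition
# (paired comparison), estimate subgroup effects, and aggregate percent bias
# and RMSE against the known true effects.

mc_method_fit <- function(method, data, estimand, kernel_args, control) {
  switch(
    method,
    logistic = logistic_ps(data, estimand),
    logistic_s = logistic_subgroup_ps(data, estimand),
    cbps = cbps_ps(data, estimand, control = control),
    balance = balance_ps(data, estimand, control = control),
    kernel_balance = do.call(
      kernel_balance_ps,
      c(list(data = data, estimand = estimand), kernel_args)
    ),
    stop_sgbal(paste0("Unknown method '", method, "'. Valid: logistic, ",
                      "logistic_s, cbps, balance, kernel_balance."),
               "sgbal_config_error")
  )
}

#' Run a Monte-Carlo simulation scenario
#'
#' Draws `n_reps` datasets from `design` (per-repetition seed =
#' `seed + repetition index`), fits each requested method on the same data
#' within a repetition, estimates subgroup effects from the implied weights,
#' and summarizes percent bias `100 * mean(tau_hat - eta_k) / eta_k` and
#' RMSE `sqrt(mean((tau_hat - eta_k)^2))` per method and subgroup over the
#' converged repetitions. True effects use their exact rational values.
#'
#' @param design A [sim_design()].
#' @param methods Character subset of `c("logistic", "logistic_s", "cbps",
#'   "balance", "kernel_balance")`.
#' @param n_reps Number of Monte-Carlo repetitions.
#' @param seed Base seed; repetition r uses seed + r.
#' @param kernel_args Named list of extra arguments for
#'   [kernel_balance_ps()] (e.g. `tau_overall`).
#' @param control A [balance_control()] list for the balance-based fits.
#' @param keep_balance Also record each repetition's subgroup/overall maximum
#'   S/D per method (slower; used for balance boxplots).
#' @return An `mc_result` list: `summary` (tibble: method, subgroup, eta,
#'   n_converged, bias, pct_bias, rmse), `estimates` (per-repetition long
#'   tibble with convergence flags), `balance` (long S/D tibble or `NULL`),
#'   `design`, `n_reps`, `seed`, and `failures` (method x repetition error
#'   messages). A method failing or not converging in more than 5% of
#'   repetitions is flagged in `summary$flag`.
#' @examples
#' d <- sim_design(n_per_subgroup = 100)
#' res <- run_scenario(d, methods = c("logistic", "balance"),
#'                     n_reps = 5, seed = 7)
#' res$summary
#' @export
run_scenario <- function(design, methods = c("logistic", "cbps", "balance"),
                         n_reps = 500, seed = 1, kernel_args = list(),
                         control = balance_control(),
                         keep_balance = FALSE) {
  stopifnot(inherits(design, "sim_design"))
  methods <- match.arg(methods,
                       c("logistic", "logistic_s", "cbps", "balance",
                         "kernel_balance"),
                       several.ok = TRUE)
  estimand <- design$estimand
  est_rows <- list()
  bal_rows <- list()
  failures <- list()

  for (r in seq_len(n_reps)) {
    dat <- simulate_subgroups(design, seed = seed + r)
    truth <- attr(dat, "truth")
    for (m in methods) {
      res <- tryCatch({
        fit <- mc_method_fit(m, dat, estimand, kernel_args, control)
        w <- ps_weights(fit, allow_unconverged = TRUE)
        eff <- subgroup_effects(dat, w)
        eff <- eff[eff$scope != "overall", c("scope", "estimate")]
        names(eff) <- c("subgroup", "estimate")
        eff$converged <- isTRUE(fit$converged)
        if (keep_balance) {
          bt <- balance_table(dat, w)
          bal_rows[[length(bal_rows) + 1]] <- dplyr::mutate(
            dplyr::summarise(dplyr::group_by(bt, .data$scope),
                             max_sd = max(.data$sd_pct), .groups = "drop"),
            method = m, rep = r
          )
        }
        eff
      }, error = function(e) {
        failures[[length(failures) + 1]] <<- tibble(
          method = m, rep = r, message = conditionMessage(e)
        )
        NULL
      })
      if (!is.null(res)) {
        res$method <- m
        res$rep <- r
        est_rows[[length(est_rows) + 1]] <- res
      }
    }
  }

  estimates <- dplyr::bind_rows(est_rows)
  truth <- tibble(subgroup = paste0("g", seq_len(design$K)), eta = design$eta)
  summary <- estimates |>
    dplyr::filter(.data$converged) |>
    dplyr::left_join(truth, by = "subgroup") |>
    dplyr::group_by(.data$method, .data$subgroup, .data$eta) |>
    dplyr::summarise(
      n_converged = dplyr::n(),
      bias = mean(.data$estimate - .data$eta),
      pct_bias = 100 * mean(.data$estimate - .data$eta) / .data$eta[1],
      rmse = sqrt(mean((.data$estimate - .data$eta)^2)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      flag = ifelse(.data$n_converged < 0.95 * n_reps,
                    "high-failure-rate", NA_character_)
    )

  structure(
    list(summary = summary, estimates = estimates,
         balance = if (keep_balance) dplyr::bind_rows(bal_rows) else NULL,
         design = design, n_reps = n_reps, seed = seed,
         failures = dplyr::bind_rows(failures)),
    class = "mc_result"
  )
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf(
    "<mc_result> %s/%s %s, %d reps, methods: %s\n",
    x$design$ps_model, x$design$outcome_model, x$design$estimand, x$n_reps,
    paste(unique(x$summary$method), collapse = ", ")
  ))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.mc_result <- function(x, ...) {
  tidyr::pivot_longer(x$summary, c("pct_bias", "rmse"),
                      names_to = "metric", values_to = "value")
}

#' @export
glance.mc_result <- function(x, ...) {
  tibble(
    ps_model = x$design$ps_model,
    outcome_model = x$design$outcome_model,
    estimand = x$design$estimand,
    n_reps = x$n_reps,
    n_methods = length(unique(x$summary$method)),
    n_failures = nrow(x$failures)
  )
}

#' Monte-Carlo performance plot
#'
#' Percent bias (points) per subgroup and method.
#'
#' @param object An `mc_result`.
#' @param metric `"pct_bias"` or `"rmse"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mc_result <- function(object, metric = c("pct_bias", "rmse"), ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$subgroup, y = .data[[metric]],
                               colour = .data$method, group = .data$method)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(y = if (metric == "pct_bias") "percent bias" else "RMSE") +
    ggplot2::theme_bw()
}
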