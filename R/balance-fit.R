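# Covariate-balancing propensity fit with subgroup interactions.
#
# The propensity model is logistic in the expanded design X = [1,S,B,S*B]
# (see build_design). The coefficients are estimated not by maximum
# likelihood but by maximizing a concave scoring-rule loss whose stationarity
# conditions are exactly the inverse-probability-weighted mean-balance
# equations on every design column — so a converged fit balances each
# covariate between arms overall AND within every subgroup, at numerical
# zero ("exact balance").

design_matrix_of <- function(X) {
  if (inherits(X, "balance_design")) X$matrix else as.matrix(X)
}

check_fit_args <- function(theta, treat, Xm) {
  if (length(theta) != ncol(Xm)) {
    stop_sgbal(sprintf("theta has length %d but the design has %d columns.",
                       length(theta), ncol(Xm)), "sgbal_config_error")
  }
  if (length(treat) != nrow(Xm)) {
    stop_sgbal("treatment vector and design rows differ in length.",
               "sgbal_config_error")
  }
  if (any(!is.finite(theta))) {
    stop_sgbal("theta must be finite.", "sgbal_validation_error")
  }
}

# eta capped only where exp() would overflow; probabilities clipped as an
# evaluation guard (fits sitting at the clip boundary are not converged fits)
eta_of <- function(theta, Xm) {
  eta <- drop(Xm %*% theta)
  pmin(pmax(eta, -500), 500)
}

#' Balance loss, score and Hessian
#'
#' The concave objective whose maximizer solves the covariate-balancing
#' estimating equations. For the ATE,
#' \deqn{L = \sum_i T_i[\log\frac{\pi_i}{1-\pi_i} - \frac{1}{\pi_i}]
#'   + (1-T_i)[\log\frac{1-\pi_i}{\pi_i} - \frac{1}{1-\pi_i}],}
#' with score \eqn{\sum_i (T_i/\pi_i - (1-T_i)/(1-\pi_i)) X_i} (zero at exact
#' balance) and Hessian \eqn{-\sum_i [T_i e^{-X_i\theta} + (1-T_i)e^{X_i\theta}]
#' X_i X_i^\top}. For the ATT, \eqn{L = \sum_i T_i X_i\theta -
#' (1-T_i)/(1-\pi_i)}, score \eqn{\sum_i (T_i - (1-T_i)\pi_i/(1-\pi_i)) X_i},
#' Hessian \eqn{-\sum_i (1-T_i) e^{X_i\theta} X_i X_i^\top}. Both Hessians are
#' negative semi-definite, so the loss is globally concave.
#'
#' @param theta Coefficient vector over the design columns.
#' @param treat 0/1 treatment vector.
#' @param design A `balance_design` or plain numeric matrix.
#' @param estimand `"ATE"` or `"ATT"`.
#' @return `balance_loss()` a scalar; `balance_score()` a vector (one entry
#'   per design column, the unnormalized balance residuals);
#'   `balance_hessian()` a matrix.
#' @export
balance_loss <- function(theta, treat, design, estimand = c("ATE", "ATT")) {
  estimand <- match.arg(estimand)
  Xm <- design_matrix_of(design)
  check_fit_args(theta, treat, Xm)
  eta <- eta_of(theta, Xm)
  p <- clip_prob(expit(eta))
  if (estimand == "ATE") {
    sum(treat * (eta - 1 / p) + (1 - treat) * (-eta - 1 / (1 - p)))
  } else {
    sum(treat * eta - (1 - treat) / (1 - p))
  }
}

#' @rdname balance_loss
#' @export
balance_score <- function(theta, treat, design, estimand = c("ATE", "ATT")) {
  estimand <- match.arg(estimand)
  Xm <- design_matrix_of(design)
  check_fit_args(theta, treat, Xm)
  eta <- eta_of(theta, Xm)
  p <- clip_prob(expit(eta))
  v <- if (estimand == "ATE") {
    treat / p - (1 - treat) / (1 - p)
  } else {
    treat - (1 - treat) * p / (1 - p)
  }
  drop(crossprod(Xm, v))
}

#' @rdname balance_loss
#' @export
balance_hessian <- function(theta, treat, design, estimand = c("ATE", "ATT")) {
  estimand <- match.arg(estimand)
  Xm <- design_matrix_of(design)
  check_fit_args(theta, treat, Xm)
  eta <- eta_of(theta, Xm)
  d <- if (estimand == "ATE") {
    treat * exp(-eta) + (1 - treat) * exp(eta)
  } else {
    (1 - treat) * exp(eta)
  }
  -crossprod(Xm * sqrt(d))
}

#' Solver options for balance fitting
#'
#' @param tol Convergence tolerance on the mean estimating function: converged
#'   when `max(abs(score)) / N <= tol`.
#' @param step_tol Stop when the Newton step norm falls below this.
#' @param max_iter Maximum Newton iterations.
#' @param gmm_fallback Use a quasi-Newton GMM minimization of
#'   \eqn{\bar B^\top \Sigma^+ \bar B} with \eqn{\Sigma = X X^\top} when
#'   Newton fails to reach tolerance.
#' @param gmm_weight Weight matrix for the fallback objective: `"xtx"`
#'   (\eqn{\Sigma = X^\top X}, the simple numerically robust choice, default)
#'   or `"continuous"` (the continuous-updating variance weighting
#'   \eqn{\sum_i X_i X_i^\top \pi_i(1-\pi_i)/N}).
#' @param ridge Relative ridge jitter applied to the Hessian solve when it is
#'   numerically singular.
#' @return A list of options for [balance_ps()].
#' @export
balance_control <- function(tol = 1e-8, step_tol = 1e-10, max_iter = 200,
                            gmm_fallback = TRUE,
                            gmm_weight = c("xtx", "continuous"),
                            ridge = 1e-10) {
  list(tol = tol, step_tol = step_tol, max_iter = max_iter,
       gmm_fallback = gmm_fallback, gmm_weight = match.arg(gmm_weight),
       ridge = ridge)
}

solve_newton <- function(treat, Xm, estimand, ctrl) {
  N <- nrow(Xm)
  P <- ncol(Xm)
  theta <- rep(0, P)
  loss <- balance_loss(theta, treat, Xm, estimand)
  loss_path <- loss
  converged <- FALSE
  iter <- 0
  diverged <- FALSE
  while (iter < ctrl$max_iter) {
    iter <- iter + 1
    g <- balance_score(theta, treat, Xm, estimand)
    res <- max(abs(g)) / N
    if (res <= ctrl$tol) {
      converged <- TRUE
      break
    }
    H <- balance_hessian(theta, treat, Xm, estimand)
    step <- tryCatch(solve(H, -g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      jit <- ctrl$ridge * max(abs(diag(H)), 1)
      step <- tryCatch(solve(H - jit * diag(P), -g), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
    }
    # backtracking line search on the concave loss; strict improvement so a
    # flat plateau (no finite maximizer in this direction) terminates the loop
    t <- 1
    ok <- FALSE
    for (bt in 1:60) {
      cand <- theta + t * step
      lc <- balance_loss(cand, treat, Xm, estimand)
      if (is.finite(lc) && lc > loss) {
        theta <- cand
        loss <- lc
        ok <- TRUE
        break
      }
      t <- t / 2
    }
    loss_path <- c(loss_path, loss)
    if (!ok) {
      diverged <- TRUE
      break
    }
    if (sqrt(sum((t * step)^2)) <= ctrl$step_tol) {
      g <- balance_score(theta, treat, Xm, estimand)
      converged <- max(abs(g)) / N <= ctrl$tol
      break
    }
  }
  g <- balance_score(theta, treat, Xm, estimand)
  list(theta = theta, loss = loss, loss_path = loss_path,
       residual = max(abs(g)) / N, converged = converged,
       diverged = diverged, iterations = iter)
}

solve_gmm <- function(theta0, treat, Xm, estimand, ctrl) {
  N <- nrow(Xm)
  Sig <- crossprod(Xm) / N
  # pseudoinverse via eigendecomposition (Sigma is symmetric PSD)
  pinv_of <- function(S) {
    ev <- eigen(S, symmetric = TRUE)
    pos <- ev$values > 1e-12 * max(ev$values, 0)
    ev$vectors[, pos, drop = FALSE] %*%
      (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
  }
  W_fixed <- pinv_of(Sig)
  obj <- function(th) {
    b <- balance_score(th, treat, Xm, estimand) / N
    W <- if (ctrl$gmm_weight == "continuous") {
      p <- clip_prob(expit(eta_of(th, Xm)))
      pinv_of(crossprod(Xm * sqrt(p * (1 - p))) / N)
    } else {
      W_fixed
    }
    drop(t(b) %*% W %*% b)
  }
  grad <- function(th) {
    b <- balance_score(th, treat, Xm, estimand) / N
    J <- balance_hessian(th, treat, Xm, estimand) / N
    drop(2 * J %*% (W_fixed %*% b))
  }
  res <- if (ctrl$gmm_weight == "xtx") {
    optim(theta0, obj, grad, method = "BFGS",
          control = list(maxit = 500, reltol = 1e-14))
  } else {
    optim(theta0, obj, method = "BFGS", control = list(maxit = 500))
  }
  th <- res$par
  g <- balance_score(th, treat, Xm, estimand)
  list(theta = th, loss = balance_loss(th, treat, Xm, estimand),
       residual = max(abs(g)) / N,
       converged = max(abs(g)) / N <= ctrl$tol, iterations = res$counts[1])
}

fit_balance_core <- function(treat, design, estimand, control = balance_control()) {
  Xm <- design_matrix_of(design)
  N <- nrow(Xm)
  if (sum(treat) == 0 || sum(1 - treat) == 0) {
    stop_sgbal("Both treatment arms must be non-empty.", "sgbal_empty_arm_error")
  }
  # equilibrate columns to unit norm: Newton is affine-invariant, so this
  # changes nothing mathematically but keeps the Hessian solve well
  # conditioned when column scales vary by orders of magnitude (kernel
  # features); the balance residual becomes per-unit-norm-column, scale-free
  nrm <- sqrt(colSums(Xm^2))
  nrm[nrm == 0] <- 1
  Xs <- sweep(Xm, 2, nrm, "/")
  colnames(Xs) <- colnames(Xm)
  fit_balance_scaled(treat, Xs, estimand, control, rescale = nrm)
}

fit_balance_scaled <- function(treat, Xm, estimand, control, rescale = NULL) {
  N <- nrow(Xm)
  nw <- solve_newton(treat, Xm, estimand, control)
  path <- "newton"
  fit <- nw
  if (!nw$converged && control$gmm_fallback &&
      (!isTRUE(nw$diverged) || nw$residual < 1e-3)) {
    gm <- solve_gmm(nw$theta, treat, Xm, estimand, control)
    if (gm$residual < nw$residual) {
      fit <- gm
      path <- "gmm_fallback"
    }
  }
  p <- clip_prob(expit(eta_of(fit$theta, Xm)))
  # a clipped probability invalidates the fit only when the weight inverts
  # it: pi ~ 0 for a treated subject (ATE) or pi ~ 1 for an untreated one
  at_boundary <- if (estimand == "ATE") {
    any(treat == 1 & p <= 1e-12) || any(treat == 0 & p >= 1 - 1e-12)
  } else {
    any(treat == 0 & p >= 1 - 1e-12)
  }
  theta_out <- if (is.null(rescale)) fit$theta else fit$theta / rescale
  list(theta = setNames(theta_out, colnames(Xm)), probs = p,
       estimand = estimand, balance_residual = fit$residual,
       solver_path = path, loss_value = fit$loss,
       loss_path = fit$loss_path %||% NULL,
       converged = fit$converged && !at_boundary,
       iterations = fit$iterations)
}

#' Fit subgroup-balancing propensity score weights
#'
#' Estimates logistic propensity-score coefficients by solving the covariate
#' balancing estimating equations on the subgroup-interaction design
#' `[1, S, Z, S1*Z, ..., SK*Z]` (after dropping linearly dependent columns).
#' At convergence the implied inverse-probability weights equalize the
#' weighted mean of every retained design column between treatment arms —
#' exact balance of each covariate overall and within every subgroup. With
#' `interactions = FALSE` the design is `[1, S, Z]` and only overall balance
#' (plus subgroup weight totals) is enforced; this is the just-identified
#' covariate balancing propensity score (CBPS) comparator.
#'
#' The solver is a damped Newton ascent of the globally concave loss from
#' `theta = 0`, falling back to quasi-Newton GMM minimization of the
#' quadratic-form objective when Newton stalls.
#'
#' @param data A [subgroup_data()] object.
#' @param estimand `"ATE"` or `"ATT"`.
#' @param interactions Include the subgroup-by-covariate interaction block
#'   (subgroup balance constraints)? Default `TRUE`.
#' @param base_block Optional replacement for the raw covariates as the base
#'   block of the design (used by [kernel_balance_ps()] to pass kernel
#'   features). Default: the covariate matrix.
#' @param control A [balance_control()] list.
#' @return A `ps_fit` object with elements `theta` (named), `probs`,
#'   `estimand`, `balance_residual` (max component of the mean estimating
#'   function), `solver_path`, `loss_value`, `converged`, `iterations`,
#'   `design`, `treat`, and `method`.
#' @examples
#' d <- sim_design(n_per_subgroup = 100)
#' dat <- simulate_subgroups(d, seed = 1)
#' fit <- balance_ps(dat, "ATE")
#' glance(fit)
#' @export
balance_ps <- function(data, estimand = c("ATE", "ATT"), interactions = TRUE,
                       base_block = NULL, control = balance_control()) {
  assert_subgroup_data(data)
  estimand <- match.arg(estimand)
  B <- base_block %||% sg_covmatrix(data)
  S <- sg_submatrix(data)
  design <- reduce_rank(build_design(B, S, interactions = interactions))
  treat <- sg_treatment(data)
  core <- fit_balance_core(treat, design, estimand, control)
  structure(
    c(core, list(design = design, treat = treat,
                 method = if (interactions) "balance" else "cbps")),
    class = "ps_fit"
  )
}

#' Inverse-probability weights from a propensity fit
#'
#' ATE weights are \eqn{T/\pi + (1-T)/(1-\pi)}; ATT weights are
#' \eqn{T + (1-T)\pi/(1-\pi)}. No trimming is applied.
#'
#' @param fit A `ps_fit` (from [balance_ps()], [kernel_balance_ps()],
#'   [logistic_ps()], ...).
#' @param allow_unconverged Return weights even when the fit did not converge.
#' @return A numeric weight vector of class `ps_weights` with attributes
#'   `estimand` and `probs`.
#' @export
ps_weights <- function(fit, allow_unconverged = FALSE) {
  stopifnot(inherits(fit, "ps_fit"))
  if (!isTRUE(fit$converged) && !allow_unconverged) {
    stop_sgbal("Fit did not converge; pass allow_unconverged = TRUE to override.",
               "sgbal_convergence_error")
  }
  p <- fit$probs
  tr <- fit$treat
  w <- if (fit$estimand == "ATE") {
    tr / p + (1 - tr) / (1 - p)
  } else {
    tr + (1 - tr) * p / (1 - p)
  }
  structure(w, estimand = fit$estimand, probs = p, class = "ps_weights")
}

#' @export
print.ps_fit <- function(x, ...) {
  cat(sprintf(
    "<ps_fit> method=%s estimand=%s, %d coefficients\n  converged: %s (%s, %d iterations), balance residual %.3g\n",
    x$method, x$estimand, length(x$theta), x$converged,
    x$solver_path %||% "mle", x$iterations %||% NA_integer_,
    x$balance_residual %||% NA_real_
  ))
  invisible(x)
}

#' @export
tidy.ps_fit <- function(x, ...) {
  lab <- if (!is.null(x$design) && inherits(x$design, "balance_design")) {
    x$design$labels[x$design$kept, , drop = FALSE]
  } else {
    tibble(block = NA_character_, subgroup = NA_character_,
           base = NA_character_, label = names(x$theta))[rep(1, length(x$theta)), ]
  }
  tibble(
    term = names(x$theta) %||% paste0("b", seq_along(x$theta)),
    estimate = as.numeric(x$theta),
    block = lab$block,
    subgroup = lab$subgroup,
    base = lab$base
  )
}

#' @export
glance.ps_fit <- function(x, ...) {
  tibble(
    method = x$method,
    estimand = x$estimand,
    n = length(x$probs),
    n_terms = length(x$theta),
    converged = x$converged,
    solver = x$solver_path %||% "mle",
    iterations = as.integer(x$iterations %||% NA),
    balance_residual = x$balance_residual %||% NA_real_,
    loss = x$loss_value %||% NA_real_
  )
}
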