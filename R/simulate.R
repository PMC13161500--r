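# Synthetic data generator for the simulation study: K one-hot subgroups,
# four covariates, a logistic treatment model with subgroup-specific
# intercepts (optionally with quadratic and interaction terms the analyst
# does not model), and a linear outcome model with subgroup-specific
# treatment effects (optionally with extra nonlinear terms).

#' Simulation design configuration
#'
#' Describes one data-generating process of the simulation study. Defaults
#' reproduce the main study conditions: K = 4 equally sized subgroups of 500
#' subjects; covariates X1 ~ N(mu_k, 1) with subgroup means
#' mu_k = 3 - 3(k-1)/(K-1), X2 ~ Uniform(0,1), X3 ~ N(0,1),
#' X4 ~ Bernoulli(0.4); treatment from
#' logit(pi) = delta_k + beta' f(X) with subgroup intercepts
#' delta_k = -1 + 2(k-1)/(K-1), where f(X) is the four main effects under
#' `ps_model = "PS1"` and additionally X1^2 and X1*X4 under `"PS2"` (the
#' model the analyst misspecifies by fitting main effects only); outcomes
#' Y = 200 + sum_k eta_k 1(G=k) T + 20 X1 + 10 X2 + 10 X3 + 10 X4 + epsilon
#' with subgroup effects eta_k = -10 + 20(k-1)/(K-1) and N(0,1) noise, plus
#' the extra terms -5 X1^2 + 10 X1 X4 under `outcome_model = "OM2"`.
#'
#' @param K Number of subgroups (>= 2; the subgroup formulas divide by K-1).
#' @param n_per_subgroup Subjects per subgroup; scalar or length-K vector.
#' @param ps_model `"PS1"` (main effects) or `"PS2"` (adds quadratic and
#'   interaction terms).
#' @param outcome_model `"OM1"` (linear main effects) or `"OM2"` (adds
#'   -5 X1^2 + 10 X1 X4).
#' @param estimand `"ATE"` or `"ATT"`; under `"PS2"` the default `beta`
#'   differs by estimand.
#' @param beta Treatment-model slopes: length 4 for PS1 (default
#'   (-0.2, -0.2, 0.4, -0.4)), length 6 for PS2 (default
#'   (-1.5, -0.5, 0.5, -0.5, 0.5, 0.5) for ATE,
#'   (-1.5, -0.8, 0.2, -0.8, 0.5, 0.5) for ATT).
#' @param sd_noise Outcome noise standard deviation (default 1).
#' @return A `sim_design` list with the resolved parameter vectors `delta`,
#'   `eta`, `mu` alongside the arguments.
#' @export
sim_design <- function(K = 4, n_per_subgroup = 500,
                       ps_model = c("PS1", "PS2"),
                       outcome_model = c("OM1", "OM2"),
                       estimand = c("ATE", "ATT"),
                       beta = NULL, sd_noise = 1) {
  ps_model <- match.arg(ps_model)
  outcome_model <- match.arg(outcome_model)
  estimand <- match.arg(estimand)
  if (K < 2) {
    stop_sgbal("K must be at least 2 (subgroup parameters divide by K-1).",
               "sgbal_config_error")
  }
  n_per_subgroup <- rep(n_per_subgroup, length.out = K)
  if (any(n_per_subgroup < 2)) {
    stop_sgbal("Each subgroup needs at least 2 subjects.", "sgbal_config_error")
  }
  if (is.null(beta)) {
    beta <- if (ps_model == "PS1") {
      c(-0.2, -0.2, 0.4, -0.4)
    } else if (estimand == "ATE") {
      c(-1.5, -0.5, 0.5, -0.5, 0.5, 0.5)
    } else {
      c(-1.5, -0.8, 0.2, -0.8, 0.5, 0.5)
    }
  }
  needed <- if (ps_model == "PS1") 4 else 6
  if (length(beta) != needed) {
    stop_sgbal(sprintf("`beta` must have length %d for %s.", needed, ps_model),
               "sgbal_config_error")
  }
  k <- seq_len(K)
  structure(
    list(
      K = K, n_per_subgroup = n_per_subgroup, ps_model = ps_model,
      outcome_model = outcome_model, estimand = estimand, beta = beta,
      sd_noise = sd_noise,
      delta = -1 + 2 * (k - 1) / (K - 1),
      eta = -10 + 20 * (k - 1) / (K - 1),
      mu = 3 - 3 * (k - 1) / (K - 1)
    ),
    class = "sim_design"
  )
}

#' Shrink one subgroup of a simulation design
#'
#' Returns the design with a single subgroup's sample size replaced (the
#' small-subgroup stress variant: 40 units in subgroup 2 by default), all
#' other settings unchanged.
#'
#' @param design A [sim_design()].
#' @param subgroup Index of the subgroup to shrink.
#' @param n New sample size for that subgroup.
#' @return The modified `sim_design`.
#' @export
small_subgroup_design <- function(design, subgroup = 2, n = 40) {
  stopifnot(inherits(design, "sim_design"))
  if (subgroup < 1 || subgroup > design$K) {
    stop_sgbal("`subgroup` out of range.", "sgbal_config_error")
  }
  design$n_per_subgroup[subgroup] <- n
  design
}

#' Draw one dataset from a simulation design
#'
#' Generates subgroup labels, covariates, treatment, both potential outcomes
#' and the observed outcome, and returns a ready-to-fit [subgroup_data()]
#' tibble. The true subgroup effects, the noise draws and the true
#' propensities are attached as attributes/columns for diagnostic use
#' (`.epsilon`, `.prob_true`; attribute `truth`).
#'
#' @param design A [sim_design()].
#' @param seed Integer seed; the draw is reproducible given `(design, seed)`.
#' @return A `subgroup_data` tibble with columns `G`, `X1`–`X4`, `g1`–`gK`
#'   (one-hot subgroup indicators), `T`, `Y`, `.epsilon`, `.prob_true`, and
#'   attribute `truth` (tibble of `subgroup`, `eta`).
#' @export
simulate_subgroups <- function(design, seed) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(as.integer(seed))
  K <- design$K
  n <- design$n_per_subgroup
  G <- rep(seq_len(K), times = n)
  N <- length(G)

  X1 <- rnorm(N, mean = design$mu[G], sd = 1)
  X2 <- runif(N)
  X3 <- rnorm(N)
  X4 <- rbinom(N, 1, 0.4)

  b <- design$beta
  lin <- design$delta[G] + b[1] * X1 + b[2] * X2 + b[3] * X3 + b[4] * X4
  if (design$ps_model == "PS2") {
    lin <- lin + b[5] * X1^2 + b[6] * X1 * X4
  }
  p_true <- expit(lin)
  treat <- rbinom(N, 1, p_true)

  eps <- rnorm(N, 0, design$sd_noise)
  y0 <- 200 + 20 * X1 + 10 * X2 + 10 * X3 + 10 * X4 + eps
  if (design$outcome_model == "OM2") {
    y0 <- y0 - 5 * X1^2 + 10 * X1 * X4
  }
  y1 <- y0 + design$eta[G]
  y <- treat * y1 + (1 - treat) * y0

  S <- matrix(0, N, K, dimnames = list(NULL, paste0("g", seq_len(K))))
  S[cbind(seq_len(N), G)] <- 1

  df <- tibble(
    G = G, X1 = X1, X2 = X2, X3 = X3, X4 = X4,
    T = treat, Y = y, .epsilon = eps, .prob_true = p_true
  )
  df <- dplyr::bind_cols(df, as_tibble(S))
  out <- subgroup_data(df, treatment = "T",
                       covariates = c("X1", "X2", "X3", "X4"),
                       subgroups = colnames(S), outcome = "Y")
  attr(out, "truth") <- tibble(subgroup = colnames(S), eta = design$eta)
  attr(out, "design") <- design
  out
}
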