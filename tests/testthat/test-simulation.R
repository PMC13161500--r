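test_that("design defaults resolve to the stated subgroup parameters", {
  d <- sim_design()
  expect_equal(d$mu, c(3, 2, 1, 0))
  expect_equal(d$delta, c(-1, -1 / 3, 1 / 3, 1))
  expect_equal(d$eta, c(-10, -10 / 3, 10 / 3, 10))
  expect_equal(d$beta, c(-0.2, -0.2, 0.4, -0.4))
  expect_equal(sim_design(ps_model = "PS2")$beta,
               c(-1.5, -0.5, 0.5, -0.5, 0.5, 0.5))
  expect_equal(sim_design(ps_model = "PS2", estimand = "ATT")$beta,
               c(-1.5, -0.8, 0.2, -0.8, 0.5, 0.5))
  expect_error(sim_design(K = 1), class = "sgbal_config_error")
})

test_that("generation is deterministic and the small-subgroup variant resizes", {
  des <- sim_design(n_per_subgroup = 100)
  d1 <- simulate_subgroups(des, seed = 9)
  d2 <- simulate_subgroups(des, seed = 9)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  d3 <- simulate_subgroups(des, seed = 10)
  expect_false(identical(d1$Y, d3$Y))

  small <- small_subgroup_design(sim_design(), subgroup = 2, n = 40)
  expect_equal(sum(small$n_per_subgroup), 1540)
  dsmall <- simulate_subgroups(small, seed = 1)
  expect_equal(nrow(dsmall), 1540)
  expect_equal(subgroup_counts(dsmall)$n[2], 40)
})

test_that("per-subgroup treated fractions match an independent oracle", {
  des <- sim_design(n_per_subgroup = 4000)
  d <- simulate_subgroups(des, seed = 13)
  # independent large-sample oracle: average the treatment probability over
  # fresh covariate draws, never through the generator under test
  set.seed(999)
  M <- 200000
  for (k in 1:4) {
    x1 <- rnorm(M, des$mu[k]); x2 <- runif(M); x3 <- rnorm(M)
    x4 <- rbinom(M, 1, 0.4)
    p_k <- mean(plogis(des$delta[k] - 0.2 * x1 - 0.2 * x2 + 0.4 * x3 -
                         0.4 * x4))
    obs <- mean(d$T[d$G == k])
    se <- sqrt(p_k * (1 - p_k) / 4000)
    expect_lt(abs(obs - p_k), 4 * se)
  }
})

test_that("the outcome model embeds the declared effects and noise", {
  des <- sim_design(n_per_subgroup = 50, outcome_model = "OM2")
  d <- simulate_subgroups(des, seed = 21)
  # reconstruct Y deterministically from the stored pieces
  y0 <- 200 + 20 * d$X1 + 10 * d$X2 + 10 * d$X3 + 10 * d$X4 -
    5 * d$X1^2 + 10 * d$X1 * d$X4 + d$.epsilon
  y <- y0 + d$T * des$eta[d$G]
  expect_equal(d$Y, y)
})

test_that("run_scenario aggregates converged repetitions into %bias and RMSE", {
  des <- sim_design(n_per_subgroup = 100)
  res <- run_scenario(des, methods = c("logistic", "balance"), n_reps = 5,
                      seed = 3)
  expect_equal(nrow(res$summary), 2 * 4)
  expect_true(all(res$summary$n_converged == 5))
  expect_true(all(res$summary$rmse >= abs(res$summary$bias)))
  # percent bias uses the exact rational true values
  expect_equal(res$summary$pct_bias,
               100 * res$summary$bias / res$summary$eta)
  # reproducible bit-for-bit
  res2 <- run_scenario(des, methods = c("logistic", "balance"), n_reps = 5,
                       seed = 3)
  expect_identical(res$summary, res2$summary)
})

test_that("the small-subgroup variant still reaches exact subgroup balance", {
  des <- small_subgroup_design(sim_design(n_per_subgroup = 150), 2, 40)
  d <- simulate_subgroups(des, seed = 31)
  fit <- balance_ps(d, "ATE")
  expect_true(fit$converged)
  bt <- balance_table(d, ps_weights(fit))
  expect_lt(max(bt$sd_pct[bt$scope == "g2"]), 1e-4)
})

test_that("estimation error equals the weighted noise contrast under OM1", {
  # with exact within-subgroup balance of X1-X4 and equal arm weight totals,
  # all covariate terms cancel and only the noise contrast remains
  d <- simulate_subgroups(sim_design(n_per_subgroup = 200), seed = 41)
  des <- attr(d, "design")
  # solve the balance equations sharply so the identity is visible at 1e-8
  fit <- balance_ps(d, "ATE", control = balance_control(tol = 1e-12))
  expect_true(fit$converged)
  w <- ps_weights(fit)
  eff <- subgroup_effects(d, w)
  S <- as.matrix(d[attr(d, "subgroups")])
  for (k in 1:4) {
    s <- S[, k]
    eps_contrast <- sum(s * w * d$T * d$.epsilon) / sum(s * w * d$T) -
      sum(s * w * (1 - d$T) * d$.epsilon) / sum(s * w * (1 - d$T))
    err <- eff$estimate[eff$scope == paste0("g", k)] - des$eta[k]
    expect_lt(abs(err - eps_contrast), 1e-8)
  }
})
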