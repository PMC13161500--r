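test_that("loss has the closed-form value at theta = 0", {
  d <- random_dataset(21, N = 50, M = 2, K = 2)
  des <- reduce_rank(build_design(as.matrix(d[attr(d, "covariates")]),
                                  as.matrix(d[attr(d, "subgroups")])))
  trt <- d$trt
  th0 <- rep(0, ncol(des$matrix))
  # pi = 1/2 everywhere: every ATE term is log(1) - 2
  expect_equal(balance_loss(th0, trt, des, "ATE"), -2 * nrow(d))
  expect_equal(balance_loss(th0, trt, des, "ATT"), -2 * sum(1 - trt))
  # ATT score at theta = 0: odds are 1, so score = sum (2T-1) X
  expect_equal(balance_score(th0, trt, des, "ATT"),
               drop(crossprod(des$matrix, 2 * trt - 1)),
               ignore_attr = TRUE)
  expect_error(balance_loss(rep(0, 3), trt, des, "ATE"),
               class = "sgbal_config_error")
})

test_that("score and hessian match central-difference oracles", {
  set.seed(31)
  X <- cbind(1, matrix(rnorm(40), 20, 2))
  trt <- rep(c(0, 1), 10)
  for (est in c("ATE", "ATT")) {
    theta <- rnorm(3, sd = 0.3)
    g_num <- pracma::grad(function(th) balance_loss(th, trt, X, est), theta)
    g <- balance_score(theta, trt, X, est)
    expect_lt(max(abs(g - g_num)) / max(abs(g)), 1e-6)
    H_num <- pracma::jacobian(function(th) balance_score(th, trt, X, est),
                              theta)
    H <- balance_hessian(theta, trt, X, est)
    expect_lt(max(abs(H - H_num)) / max(abs(H)), 1e-5)
  }
})

test_that("hessians are negative semi-definite with the stated theta=0 form", {
  set.seed(32)
  X <- cbind(1, matrix(rnorm(60), 30, 2))
  trt <- rbinom(30, 1, 0.5)
  for (est in c("ATE", "ATT")) {
    ev <- eigen(balance_hessian(rnorm(3), trt, X, est),
                symmetric = TRUE, only.values = TRUE)$values
    expect_lte(max(ev), 1e-8 * abs(min(ev)))
  }
  # at theta=0 the ATE curvature weight is exp(0) = 1 for every subject
  expect_equal(balance_hessian(rep(0, 3), trt, X, "ATE"), -crossprod(X))
})

test_that("perfectly paired data are solved exactly at theta = 0", {
  d <- make_paired_data(n_pairs = 12, M = 3)
  des <- reduce_rank(build_design(as.matrix(d[attr(d, "covariates")]),
                                  as.matrix(d[attr(d, "subgroups")])))
  expect_equal(max(abs(balance_score(rep(0, ncol(des$matrix)), d$trt, des,
                                     "ATE"))), 0)
  fit <- balance_ps(d, "ATE")
  expect_true(fit$converged)
  expect_lt(max(abs(fit$theta)), 1e-6)
  expect_lt(fit$balance_residual, 1e-8)
})

test_that("one binary covariate reduces to the closed-form 2x2 solution", {
  # 2x2 table (first index T, second Z): n11=30, n10=20, n01=20, n00=30
  df <- data.frame(
    trt = rep(c(1, 1, 0, 0), times = c(30, 20, 20, 30)),
    z = rep(c(1, 0, 1, 0), times = c(30, 20, 20, 30)),
    g1 = 1
  )
  d <- subgroup_data(df, "trt", "z", "g1")
  fit <- balance_ps(d, "ATE")
  expect_true(fit$converged)
  # exact-balance probabilities are the cellwise empirical shares
  expect_equal(unique(round(fit$probs[df$z == 1], 10)), 0.6)
  expect_equal(unique(round(fit$probs[df$z == 0], 10)), 0.4)
  # independent grid-search oracle on the two estimating equations
  des <- fit$design
  obj <- function(th) max(abs(balance_score(th, df$trt, des, "ATE")))
  center <- c(0, 0); width <- 4
  for (refine in 1:12) {
    gr <- as.matrix(expand.grid(
      a = center[1] + seq(-width, width, length.out = 11),
      b = center[2] + seq(-width, width, length.out = 11)
    ))
    vals <- apply(gr, 1, obj)
    center <- gr[which.min(vals), ]
    width <- width / 4
  }
  expect_lt(obj(center), 1e-6)
  expect_equal(unname(fit$theta), unname(center), tolerance = 1e-4)
})

test_that("brute-force oracle agrees with Newton on small instances", {
  for (seed in c(101, 102)) {
    d <- random_dataset(seed, N = 100, M = 3, K = 1)
    fit <- balance_ps(d, "ATE")
    expect_true(fit$converged)
    des <- fit$design
    # derivative-free multi-start oracle, independent of the Newton path
    neg_loss <- function(th) -balance_loss(th, d$trt, des, "ATE")
    best <- NULL
    for (s in 1:3) {
      set.seed(seed + s)
      o <- optim(rnorm(length(fit$theta), sd = 0.2), neg_loss,
                 method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-14))
      o <- optim(o$par, neg_loss, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-14))
      if (is.null(best) || o$value < best$value) best <- o
    }
    expect_equal(unname(fit$theta), unname(best$par), tolerance = 1e-4)
  }
})

test_that("Newton and GMM solve just-identified instances identically", {
  d <- random_dataset(55, N = 50, M = 3, K = 1)
  fit <- balance_ps(d, "ATE")
  expect_identical(fit$solver_path, "newton")
  Xm <- fit$design$matrix
  gm <- sgbal:::solve_gmm(rep(0, ncol(Xm)), d$trt, Xm, "ATE",
                          balance_control())
  expect_lt(max(abs(fit$theta - gm$theta)), 1e-6)
})

test_that("weights follow the estimand formulas and reproduce exact balance", {
  d <- make_paired_data(n_pairs = 8, M = 2)
  fit <- balance_ps(d, "ATE")
  w <- ps_weights(fit)
  expect_equal(as.numeric(w), rep(2, nrow(d))) # pi = 1/2 everywhere
  fit_att <- balance_ps(d, "ATT")
  expect_equal(as.numeric(ps_weights(fit_att)), rep(1, nrow(d)))

  d2 <- random_dataset(77, N = 300, M = 4, K = 3, partition = FALSE)
  for (est in c("ATE", "ATT")) {
    f <- balance_ps(d2, est)
    expect_true(f$converged)
    w2 <- ps_weights(f)
    expect_true(all(w2 > 0))
    # Eq-style identity: weighted sums agree columnwise between arms
    Xk <- f$design$matrix
    for (j in seq_len(ncol(Xk))) {
      expect_lt(abs(sum(w2 * d2$trt * Xk[, j]) -
                    sum(w2 * (1 - d2$trt) * Xk[, j])) /
                  max(sum(abs(Xk[, j])), 1), 1e-6)
    }
  }
  f_bad <- balance_ps(d2, "ATE",
                      control = balance_control(max_iter = 1,
                                                gmm_fallback = FALSE))
  if (!f_bad$converged) {
    expect_error(ps_weights(f_bad), class = "sgbal_convergence_error")
  }
})

test_that("the loss is concave and its recorded path is monotone", {
  d <- random_dataset(88, N = 150, M = 3, K = 2)
  des <- reduce_rank(build_design(as.matrix(d[attr(d, "covariates")]),
                                  as.matrix(d[attr(d, "subgroups")])))
  P <- ncol(des$matrix)
  set.seed(88)
  for (i in 1:20) {
    th1 <- rnorm(P, sd = 0.5); th2 <- rnorm(P, sd = 0.5)
    lam <- runif(1)
    expect_gte(
      balance_loss(lam * th1 + (1 - lam) * th2, d$trt, des, "ATE"),
      lam * balance_loss(th1, d$trt, des, "ATE") +
        (1 - lam) * balance_loss(th2, d$trt, des, "ATE") - 1e-8
    )
  }
  fit <- balance_ps(d, "ATE")
  expect_true(all(diff(fit$loss_path) >= 0))
})

test_that("self-simulation recovers the generating coefficients", {
  err_at <- function(nk, seed) {
    d <- simulate_subgroups(sim_design(n_per_subgroup = nk), seed)
    fit <- balance_ps(d, "ATE")
    lab <- fit$design$labels[fit$design$kept, ]
    design <- attr(d, "design")
    truth <- ifelse(
      lab$block == "subgroup", design$delta[match(lab$subgroup, paste0("g", 1:4))],
      design$beta[match(lab$base, paste0("X", 1:4))]
    )
    max(abs(fit$theta - truth))
  }
  e_small <- mean(vapply(1:3, function(s) err_at(500, s), numeric(1)))
  e_large <- mean(vapply(1:3, function(s) err_at(5000, s), numeric(1)))
  expect_lt(e_large, e_small) # shrinking with N
  expect_lt(e_large, 0.25)
})
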