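test_that("the expansion has (1+K)(1+M) labeled columns with exact interactions", {
  set.seed(1)
  B <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  S <- cbind(g1 = rep(c(1, 0), 5), g2 = rep(c(0, 1), 5))
  d <- build_design(B, S)
  expect_equal(ncol(d$matrix), 9)
  expect_equal(d$nominal_dim, 9)
  expect_equal(table(d$labels$block)[["interaction"]], 4)
  # every interaction column is the elementwise product of its parents
  for (j in which(d$labels$block == "interaction")) {
    sj <- d$matrix[, d$labels$subgroup[j]]
    bj <- B[, d$labels$base[j]]
    expect_equal(d$matrix[, j], sj * bj)
  }
  # the main-study shape
  d4 <- build_design(matrix(rnorm(40), 10, 4), matrix(1, 10, 4) * diag(4)[rep(1:4, length.out = 10), ])
  expect_equal(ncol(d4$matrix), 25)
  # an all-zero subgroup column gives identically zero interactions
  S0 <- cbind(g1 = rep(1, 10), g2 = rep(0, 10))
  d0 <- build_design(B, S0)
  zero_cols <- d0$labels$block == "interaction" & d0$labels$subgroup == "g2"
  expect_true(all(d0$matrix[, zero_cols] == 0))
  expect_error(build_design(matrix(c(1, NA), 2, 1), matrix(1, 2, 1)),
               class = "sgbal_validation_error")
})

test_that("rank reduction drops intercept and base columns for a partition", {
  set.seed(2)
  N <- 60
  G <- rep(1:4, each = 15)
  S <- matrix(0, N, 4, dimnames = list(NULL, paste0("g", 1:4)))
  S[cbind(1:N, G)] <- 1
  B <- matrix(rnorm(N * 4), N, 4, dimnames = list(NULL, paste0("x", 1:4)))
  d <- reduce_rank(build_design(B, S))
  # oracle: rank of the full expansion by plain QR
  expect_equal(qr(d$full_matrix)$rank, 20)
  expect_equal(length(d$kept), 20)
  dropped_blocks <- d$labels$block[d$dropped]
  expect_setequal(unique(dropped_blocks), c("intercept", "base"))
  expect_equal(sum(dropped_blocks == "base"), 4)
  # dropped columns are reconstructible from kept ones
  fit <- lm.fit(d$matrix, d$full_matrix[, d$dropped])
  expect_lt(max(abs(fit$residuals)), 1e-8)
})

test_that("overlapping subgroups keep the intercept; duplicates collapse", {
  d <- make_overlap_data()
  S <- as.matrix(d[attr(d, "subgroups")])
  expect_gt(max(rowSums(S)), 1)
  des <- reduce_rank(build_design(as.matrix(d[attr(d, "covariates")]), S))
  expect_true("intercept" %in% des$labels$block[des$kept])
  # duplicated covariate column: exactly one survives
  B <- cbind(x1 = d$x1, x1_copy = d$x1)
  des2 <- reduce_rank(build_design(B, S))
  base_kept <- sum(des2$labels$block[des2$kept] == "base")
  expect_equal(base_kept, 1)
})

test_that("build_design is deterministic and row-permutation equivariant", {
  set.seed(3)
  B <- matrix(rnorm(30), 10, 3)
  S <- cbind(g1 = rbinom(10, 1, 0.5))
  S[S[, 1] == 0, 1] <- 0 # keep 0/1
  S <- cbind(S, g2 = 1 - S[, 1])
  d1 <- build_design(B, S)
  d2 <- build_design(B, S)
  expect_identical(d1$matrix, d2$matrix)
  perm <- sample(10)
  dp <- build_design(B[perm, ], S[perm, ])
  expect_equal(dp$matrix, d1$matrix[perm, ])
})

test_that("balance on retained columns carries to dropped columns", {
  d <- simulate_subgroups(sim_design(n_per_subgroup = 100), seed = 9)
  fit <- balance_ps(d, "ATE")
  w <- ps_weights(fit)
  des <- fit$design
  trt <- d$T
  scale_cols <- apply(des$full_matrix, 2, function(x) max(abs(x), 1))
  for (j in des$dropped) {
    expect_lt(abs(wmd(des$full_matrix[, j], trt, w)) / scale_cols[j], 1e-6)
  }
})
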