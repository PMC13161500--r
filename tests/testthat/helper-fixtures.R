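# Fixtures are built in code; no data files.

# every covariate row appears once treated and once untreated, so theta = 0
# solves the balance equations exactly
make_paired_data <- function(n_pairs = 10, M = 2, seed = 42) {
  set.seed(seed)
  Z <- matrix(rnorm(n_pairs * M), n_pairs, M,
              dimnames = list(NULL, paste0("x", seq_len(M))))
  df <- as.data.frame(rbind(Z, Z))
  df$trt <- rep(c(1, 0), each = n_pairs)
  df$g1 <- 1
  subgroup_data(df, treatment = "trt", covariates = colnames(Z),
                subgroups = "g1")
}

# hand-built overlapping-subgroup example: membership patterns (1,0), (0,1)
# and (1,1) all occur, so neither the intercept nor the base columns lie in
# the span of the subgroup/interaction blocks
make_overlap_data <- function() {
  df <- data.frame(
    trt = rep(c(1, 0), 6),
    x1 = c(0.5, -0.2, 1.1, 0.3, -0.7, 0.9, 0.2, -1.3, 0.8, -0.4, 1.5, -0.9),
    x2 = c(1, 0, 1, 1, 0, 0, 1, 0, 1, 0, 0, 1),
    g1 = c(1, 1, 1, 1, 0, 0, 0, 0, 1, 1, 1, 1),
    g2 = c(0, 0, 0, 0, 1, 1, 1, 1, 1, 1, 1, 1)
  )
  subgroup_data(df, treatment = "trt", covariates = c("x1", "x2"),
                subgroups = c("g1", "g2"))
}

# random dataset with a partition or overlapping scheme and guaranteed
# non-empty arms per subgroup
random_dataset <- function(seed, N = 200, M = 3, K = 3, partition = TRUE,
                           outcome = FALSE) {
  set.seed(seed)
  repeat {
    Z <- matrix(rnorm(N * M), N, M, dimnames = list(NULL, paste0("x", 1:M)))
    G <- sample.int(K, N, replace = TRUE)
    S <- matrix(0, N, K, dimnames = list(NULL, paste0("g", 1:K)))
    S[cbind(1:N, G)] <- 1
    if (!partition) {
      extra <- matrix(rbinom(N * K, 1, 0.3), N, K)
      S <- pmin(S + extra, 1)
    }
    trt <- rbinom(N, 1, plogis(0.3 * Z[, 1]))
    ok <- all(colSums(S * trt) >= 2) && all(colSums(S * (1 - trt)) >= 2)
    if (ok) break
  }
  df <- data.frame(Z, trt = trt, S)
  if (outcome) df$y <- rnorm(N, 1 + Z %*% rep(1, M) + trt)
  subgroup_data(df, treatment = "trt", covariates = colnames(Z),
                subgroups = colnames(S),
                outcome = if (outcome) "y" else NULL)
}

# normalized weighted mean difference of x between arms
wmd <- function(x, trt, w) {
  sum(w * trt * x) / sum(w * trt) - sum(w * (1 - trt) * x) / sum(w * (1 - trt))
}
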