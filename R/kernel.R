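# Gaussian-kernel principal-component features for the nonparametric
# propensity fit. Covariates are standardized (mean 0, sd 1 per column,
# binary columns included) before any distance computation; the kernel is
# k(z_i, z_j) = exp(-||z_i - z_j||^2 / sigma), i.e. the squared distance is
# divided by sigma itself, not 2*sigma^2. The kernel matrix is eigendecomposed
# WITHOUT centering, K = P D P', and the feature block is omega = P D^{1/2}
# truncated at 99% cumulative eigenvalue mass.

standardize_cols <- function(Z) {
  Z <- as.matrix(Z)
  storage.mode(Z) <- "double"
  mu <- colMeans(Z)
  sdv <- apply(Z, 2, sd)
  sdv[sdv == 0] <- 1 # constant columns carry no distance information
  Zs <- sweep(sweep(Z, 2, mu, "-"), 2, sdv, "/")
  attr(Zs, "center") <- mu
  attr(Zs, "scale") <- sdv
  Zs
}

#' Gaussian kernel matrix
#'
#' Computes \eqn{K_{ij} = \exp(-\|z_i - z_j\|^2 / \sigma)} on the rows of
#' `Zstd` (typically standardized covariates). Note the bandwidth convention:
#' the squared Euclidean distance is divided by `sigma`.
#'
#' @param Zstd Numeric matrix of (standardized) covariates, one row per
#'   subject.
#' @param sigma Positive bandwidth.
#' @return A symmetric N x N matrix with unit diagonal and entries in (0, 1].
#' @export
gaussian_kernel <- function(Zstd, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) ||
      sigma <= 0) {
    stop_sgbal("`sigma` must be a positive number.", "sgbal_config_error")
  }
  Z <- as.matrix(Zstd)
  sq <- rowSums(Z^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(Z)
  D2[D2 < 0] <- 0
  Km <- exp(-D2 / sigma)
  diag(Km) <- 1
  (Km + t(Km)) / 2
}

#' Kernel principal-component features
#'
#' Eigendecomposes a symmetric kernel matrix `K = P D P'`, clips negative
#' eigenvalues to zero, and returns the feature block
#' \eqn{\omega = P D^{1/2}} truncated to the smallest number of leading
#' columns whose eigenvalue mass reaches `variance_target` (default 99%) of
#' the total. Before truncation \eqn{\omega\omega^\top} reconstructs the
#' kernel matrix.
#'
#' @param kernel Symmetric N x N kernel matrix.
#' @param variance_target Cumulative eigenvalue fraction to retain.
#' @param sigma Optional bandwidth recorded for bookkeeping.
#' @return A `kernel_features` object: list with `features` (N x L),
#'   `eigenvalues` (all N, descending, negatives clipped to 0), `n_features`,
#'   `variance_fraction` (achieved), `sigma`.
#' @export
kernel_features <- function(kernel, variance_target = 0.99, sigma = NA_real_) {
  Km <- as.matrix(kernel)
  if (max(abs(Km - t(Km))) > 1e-8 * max(abs(Km), 1)) {
    stop_sgbal("Kernel matrix is not symmetric.", "sgbal_validation_error")
  }
  ev <- eigen((Km + t(Km)) / 2, symmetric = TRUE)
  vals <- ev$values
  vals[vals < 1e-10 * max(vals, 0)] <- 0
  total <- sum(vals)
  if (total <= 0) {
    stop_sgbal("Kernel matrix has no positive eigenvalue mass.",
               "sgbal_validation_error")
  }
  cum <- cumsum(vals) / total
  L <- which(cum >= variance_target)[1]
  vecs <- ev$vectors[, seq_len(L), drop = FALSE]
  # eigenvectors are sign-indeterminate; fix the entry of largest magnitude
  # to be positive so features are deterministic across platforms
  for (j in seq_len(L)) {
    pivot <- which.max(abs(vecs[, j]))
    if (vecs[pivot, j] < 0) vecs[, j] <- -vecs[, j]
  }
  feats <- vecs %*% diag(sqrt(vals[seq_len(L)]), L)
  colnames(feats) <- paste0("kpc", seq_len(L))
  structure(
    list(features = feats, eigenvalues = vals, n_features = L,
         variance_fraction = cum[L], variance_target = variance_target,
         sigma = sigma),
    class = "kernel_features"
  )
}

#' @export
print.kernel_features <- function(x, ...) {
  cat(sprintf(
    "<kernel_features> %d features (%.2f%% eigenvalue mass), sigma = %.4g\n",
    x$n_features, 100 * x$variance_fraction, x$sigma
  ))
  invisible(x)
}

#' Candidate bandwidth grid for the Gaussian kernel
#'
#' Returns 20 candidate bandwidths equally spaced on the log scale between
#' the 0.1 and 0.9 quantiles (type-7, linear interpolation) of the
#' N(N-1)/2 pairwise Euclidean distances between subjects.
#'
#' @param Zstd Numeric matrix of (standardized) covariates.
#' @param n_candidates Number of grid points (20 by default).
#' @param probs Lower/upper distance quantiles bounding the grid.
#' @return Numeric vector of `n_candidates` bandwidths, non-decreasing.
#' @export
bandwidth_grid <- function(Zstd, n_candidates = 20, probs = c(0.1, 0.9)) {
  Z <- as.matrix(Zstd)
  if (nrow(Z) < 2) {
    stop_sgbal("Need at least two subjects for a distance grid.",
               "sgbal_config_error")
  }
  dvec <- as.numeric(dist(Z))
  if (all(dvec == 0)) {
    stop_sgbal("All subjects identical: pairwise distances are all zero.",
               "sgbal_validation_error")
  }
  q <- quantile(dvec, probs = probs, names = FALSE, type = 7)
  if (q[1] <= 0) q[1] <- min(dvec[dvec > 0])
  exp(seq(log(q[1]), log(q[2]), length.out = n_candidates))
}
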