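#' Build the subgroup-interaction balance basis
#'
#' Expands a base block of columns B (raw covariates for the parametric
#' estimator, kernel principal-component features for the nonparametric one)
#' and K subgroup indicators into the design
#' \deqn{X = [1, S_1, \dots, S_K, B, S_1 B, \dots, S_K B],}
#' whose balance conditions control, respectively, the total weight in each
#' arm, the per-subgroup weight totals, the overall covariate means, and the
#' within-subgroup covariate means. With K subgroups and M base columns the
#' expansion has (1 + K)(1 + M) columns.
#'
#' @param base_block Numeric matrix (N x M) of base columns; all entries must
#'   be finite. Column names are used as labels (defaults are generated).
#' @param subgroups Numeric 0/1 matrix (N x K) of subgroup indicators,
#'   row-aligned with `base_block`.
#' @param interactions Include the subgroup-by-base interaction block?
#'   `FALSE` gives the overall-balance design `[1, S, B]` used by the CBPS
#'   comparator.
#' @return A `balance_design` object: a list with `matrix` (N x P), `labels`
#'   (tibble with `block`, `subgroup`, `base` per column), `kept`, `dropped`
#'   (column indices after rank reduction; all kept until [reduce_rank()] is
#'   called), and `nominal_dim` = (1+K)(1+M).
#' @seealso [reduce_rank()]
#' @examples
#' Z <- matrix(rnorm(20), 10, 2)
#' S <- cbind(g1 = rep(c(1, 0), 5), g2 = rep(c(0, 1), 5))
#' d <- build_design(Z, S)
#' ncol(d$matrix) # (1+2)*(1+2) = 9
#' @export
build_design <- function(base_block, subgroups, interactions = TRUE) {
  B <- as.matrix(base_block)
  S <- as.matrix(subgroups)
  storage.mode(B) <- "double"
  storage.mode(S) <- "double"
  if (nrow(B) != nrow(S)) {
    stop_sgbal("`base_block` and `subgroups` must have the same number of rows.",
               "sgbal_config_error")
  }
  if (any(!is.finite(B))) {
    stop_sgbal("`base_block` contains non-finite entries.",
               "sgbal_validation_error")
  }
  M <- ncol(B)
  K <- ncol(S)
  bnames <- colnames(B) %||% paste0("b", seq_len(M))
  snames <- colnames(S) %||% paste0("s", seq_len(K))

  if (interactions) {
    inter <- matrix(0, nrow(B), K * M)
    for (k in seq_len(K)) {
      inter[, (k - 1) * M + seq_len(M)] <- S[, k] * B
    }
    X <- cbind(1, S, B, inter)
    labels <- tibble(
      block = c("intercept", rep("subgroup", K), rep("base", M),
                rep("interaction", K * M)),
      subgroup = c(NA, snames, rep(NA, M),
                   rep(snames, each = M)),
      base = c(NA, rep(NA, K), bnames, rep(bnames, times = K))
    )
  } else {
    X <- cbind(1, S, B)
    labels <- tibble(
      block = c("intercept", rep("subgroup", K), rep("base", M)),
      subgroup = c(NA, snames, rep(NA, M)),
      base = c(NA, rep(NA, K), bnames)
    )
  }
  labels$label <- with(labels, ifelse(
    block == "intercept", "(intercept)",
    ifelse(block == "subgroup", subgroup,
           ifelse(block == "base", base, paste0(subgroup, ":", base)))
  ))
  colnames(X) <- labels$label

  structure(
    list(
      matrix = X,
      labels = labels,
      kept = seq_len(ncol(X)),
      dropped = integer(0),
      nominal_dim = if (interactions) (1 + K) * (1 + M) else 1 + K + M,
      reduced = FALSE
    ),
    class = "balance_design"
  )
}

#' Drop linearly dependent columns from a balance design
#'
#' For mutually exclusive, exhaustive subgroups the full expansion is exactly
#' singular: the intercept is the sum of the subgroup indicators and each base
#' column is the sum of its interactions. A maximal linearly independent
#' column subset is therefore selected before fitting, preferring to drop the
#' intercept and base columns so that the subgroup-level balance conditions
#' are preserved verbatim. Keep-priority order: subgroup indicators,
#' interactions, intercept, base columns; within a block, survivors are chosen
#' by column-pivoted QR on the component orthogonal to the columns already
#' kept.
#'
#' @param design A `balance_design` from [build_design()].
#' @param tol Relative tolerance: a column is dropped when the norm of its
#'   orthogonal residual is below `tol` times the largest column norm.
#' @return The design with `kept`/`dropped` filled in and `matrix` restricted
#'   to the kept columns (`full_matrix` retains the original). Balance on the
#'   kept columns implies balance on the dropped ones, which are exact linear
#'   combinations of the kept set.
#' @export
reduce_rank <- function(design, tol = 1e-8) {
  stopifnot(inherits(design, "balance_design"))
  X <- design$full_matrix %||% design$matrix
  P <- ncol(X)
  scale0 <- max(sqrt(colSums(X^2)))
  if (scale0 == 0) {
    design$kept <- integer(0)
    design$dropped <- seq_len(P)
    design$full_matrix <- X
    design$matrix <- X[, 0, drop = FALSE]
    design$reduced <- TRUE
    return(design)
  }
  thresh <- tol * scale0

  blk <- design$labels$block
  priority <- list(
    which(blk == "subgroup"),
    which(blk == "interaction"),
    which(blk == "intercept"),
    which(blk == "base")
  )

  Q <- matrix(0, nrow(X), 0)
  kept <- integer(0)
  for (idx in priority) {
    if (length(idx) == 0) next
    Bk <- X[, idx, drop = FALSE]
    # residual orthogonal to the columns already kept
    if (ncol(Q) > 0) Bk <- Bk - Q %*% (crossprod(Q, Bk))
    qrk <- qr(Bk, LAPACK = TRUE)
    d <- abs(diag(qr.R(qrk)))
    r <- sum(d > thresh)
    if (r > 0) {
      sel <- qrk$pivot[seq_len(r)]
      kept <- c(kept, idx[sel])
      Qk <- qr.Q(qrk)[, seq_len(r), drop = FALSE]
      # re-orthogonalize against Q for numerical hygiene
      if (ncol(Q) > 0) {
        Qk <- Qk - Q %*% crossprod(Q, Qk)
        Qk <- qr.Q(qr(Qk))
      }
      Q <- cbind(Q, Qk)
    }
  }
  kept <- sort(kept)
  design$kept <- kept
  design$dropped <- setdiff(seq_len(P), kept)
  design$full_matrix <- X
  design$matrix <- X[, kept, drop = FALSE]
  design$reduced <- TRUE
  design
}

#' @export
print.balance_design <- function(x, ...) {
  cat(sprintf(
    "<balance_design> %d x %d (nominal %d columns%s)\n",
    nrow(x$matrix), ncol(x$matrix), x$nominal_dim,
    if (x$reduced) sprintf(", %d dropped as dependent", length(x$dropped)) else ""
  ))
  invisible(x)
}
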