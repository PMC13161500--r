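#' Assemble and validate a subject-level dataset for subgroup-balanced weighting
#'
#' Takes one row per subject and the names of the treatment, covariate,
#' subgroup-indicator and (optionally) outcome columns, validates them, and
#' returns a `subgroup_data` tibble that the fitting, diagnostic and
#' effect-estimation functions consume. Subgroups are pre-specified 0/1
#' membership indicators; they may overlap (a subject can belong to several)
#' but every subject must belong to at least one.
#'
#' @param data A data frame with one row per subject.
#' @param treatment Name of the binary treatment column (0 = untreated,
#'   1 = treated). Both arms must be non-empty.
#' @param covariates Character vector of numeric covariate column names; no
#'   missing or non-finite values are allowed.
#' @param subgroups Character vector of 0/1 subgroup indicator column names.
#'   Every subgroup must have at least one subject in each treatment arm,
#'   otherwise the weighted contrast is undefined there.
#' @param outcome Optional name of a numeric outcome column. May contain `NA`
#'   when only weights or balance are requested; effect estimation will then
#'   error.
#'
#' @return A tibble of class `subgroup_data` containing the named columns,
#'   with the column roles stored in attributes (`treatment`, `covariates`,
#'   `subgroups`, `outcome`).
#'
#' @examples
#' df <- data.frame(trt = c(0, 1, 0, 1), x = c(1.2, 0.3, -1, 2), g = 1)
#' sd <- subgroup_data(df, treatment = "trt", covariates = "x", subgroups = "g")
#' subgroup_counts(sd)
#' @export
subgroup_data <- function(data, treatment, covariates, subgroups,
                          outcome = NULL) {
  if (!is.data.frame(data)) {
    stop_sgbal("`data` must be a data frame.", "sgbal_config_error")
  }
  if (nrow(data) < 2) {
    stop_sgbal("`data` must have at least 2 rows.", "sgbal_validation_error")
  }
  needed <- c(treatment, covariates, subgroups, outcome)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop_sgbal(
      paste0("Missing column(s): ", paste(missing_cols, collapse = ", "), "."),
      "sgbal_config_error"
    )
  }

  tr <- data[[treatment]]
  if (!is_binary01(tr)) {
    bad <- which(!(tr %in% c(0, 1)) | !is.finite(tr))[1]
    stop_sgbal(
      paste0("Treatment column '", treatment, "' is not 0/1 (first offending row ",
             bad, ")."),
      "sgbal_validation_error"
    )
  }
  if (sum(tr) == 0 || sum(1 - tr) == 0) {
    stop_sgbal("Both treatment arms must be non-empty.",
               "sgbal_validation_error")
  }

  for (cv in covariates) {
    x <- data[[cv]]
    if (!is.numeric(x) || any(!is.finite(x))) {
      bad <- which(!is.finite(as.numeric(x)))[1]
      stop_sgbal(
        paste0("Covariate '", cv, "' has missing/non-finite value at row ",
               bad, "."),
        "sgbal_validation_error"
      )
    }
  }

  S <- as.matrix(data[subgroups])
  storage.mode(S) <- "double"
  for (j in seq_along(subgroups)) {
    if (!is_binary01(S[, j])) {
      bad <- which(!(S[, j] %in% c(0, 1)))[1]
      stop_sgbal(
        paste0("Subgroup column '", subgroups[j], "' is not 0/1 (row ", bad, ")."),
        "sgbal_validation_error"
      )
    }
  }
  if (any(rowSums(S) < 1)) {
    bad <- which(rowSums(S) < 1)[1]
    stop_sgbal(
      paste0("Every subject must belong to at least one subgroup (row ", bad,
             " belongs to none)."),
      "sgbal_validation_error"
    )
  }
  for (j in seq_along(subgroups)) {
    n1k <- sum(S[, j] * tr)
    n0k <- sum(S[, j] * (1 - tr))
    if (n1k == 0 || n0k == 0) {
      stop_sgbal(
        paste0("Subgroup '", subgroups[j], "' has an empty ",
               if (n1k == 0) "treated" else "untreated",
               " arm; weighted contrasts are undefined there."),
        "sgbal_empty_arm_error"
      )
    }
  }

  if (!is.null(outcome) && !is.numeric(data[[outcome]])) {
    stop_sgbal(paste0("Outcome '", outcome, "' must be numeric."),
               "sgbal_validation_error")
  }

  out <- as_tibble(data)
  class(out) <- setdiff(class(out), "subgroup_data")
  structure(
    out,
    treatment = treatment,
    covariates = covariates,
    subgroups = subgroups,
    outcome = outcome,
    class = c("subgroup_data", class(out))
  )
}

sg_roles <- function(data) {
  list(
    treatment = attr(data, "treatment"),
    covariates = attr(data, "covariates"),
    subgroups = attr(data, "subgroups"),
    outcome = attr(data, "outcome")
  )
}

assert_subgroup_data <- function(data) {
  if (!inherits(data, "subgroup_data")) {
    stop_sgbal("Expected a `subgroup_data` object; see subgroup_data().",
               "sgbal_config_error")
  }
  invisible(data)
}

sg_treatment <- function(data) as.numeric(data[[attr(data, "treatment")]])

sg_covmatrix <- function(data) {
  Z <- as.matrix(data[attr(data, "covariates")])
  storage.mode(Z) <- "double"
  Z
}

sg_submatrix <- function(data) {
  S <- as.matrix(data[attr(data, "subgroups")])
  storage.mode(S) <- "double"
  S
}

sg_outcome <- function(data) {
  oc <- attr(data, "outcome")
  if (is.null(oc)) NULL else as.numeric(data[[oc]])
}

#' Per-subgroup sample counts
#'
#' @param data A `subgroup_data` object.
#' @return A tibble with one row per subgroup: `subgroup`, `n` (total members),
#'   `n_treated`, `n_untreated`, plus an `is_partition` attribute that is
#'   `TRUE` iff the subgroup indicators sum to exactly 1 for every subject
#'   (mutually exclusive and exhaustive).
#' @examples
#' df <- data.frame(trt = c(0, 1, 0, 1), x = rnorm(4), g = 1)
#' subgroup_counts(subgroup_data(df, "trt", "x", "g"))
#' @export
subgroup_counts <- function(data) {
  assert_subgroup_data(data)
  S <- sg_submatrix(data)
  tr <- sg_treatment(data)
  out <- tibble(
    subgroup = attr(data, "subgroups"),
    n = as.numeric(colSums(S)),
    n_treated = as.numeric(colSums(S * tr)),
    n_untreated = as.numeric(colSums(S * (1 - tr)))
  )
  attr(out, "is_partition") <- all(rowSums(S) == 1)
  out
}

#' @export
print.subgroup_data <- function(x, ...) {
  roles <- sg_roles(x)
  cat(sprintf(
    "<subgroup_data> %d subjects, %d covariates, %d subgroups%s\n",
    nrow(x), length(roles$covariates), length(roles$subgroups),
    if (is.null(roles$outcome)) "" else ", outcome present"
  ))
  NextMethod()
}
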