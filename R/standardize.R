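#' Log10-transform and z-scale a cohort
#'
#' Computes `(log10(intensity) - mean) / sd` per analyte. When `params` is
#' missing, means and SDs are computed from this cohort (zero-variance
#' analytes are dropped with a warning) and returned for reuse; when
#' supplied (e.g. training-set parameters applied to a test or transfer
#' cohort), they are applied as-is.
#'
#' @param cohort a [proteomic_cohort()].
#' @param params optional `standardization_params` from a previous call.
#' @return A list with `z` (subjects x analytes matrix) and `params` (a
#'   `standardization_params` data.frame: `analyte_id`, `mean`, `sd`).
#' @export
log_standardize <- function(cohort, params = NULL) {
  stopifnot(inherits(cohort, "proteomic_cohort"))
  L <- log10(cohort$intensities)
  if (is.null(params)) {
    mu <- colMeans(L)
    s <- apply(L, 2, sd)
    drop <- s == 0
    if (any(drop)) {
      warning(sprintf("dropping %d zero-variance analyte(s)", sum(drop)),
              call. = FALSE)
      L <- L[, !drop, drop = FALSE]
      mu <- mu[!drop]
      s <- s[!drop]
    }
    params <- data.frame(analyte_id = colnames(L), mean = unname(mu),
                         sd = unname(s), stringsAsFactors = FALSE)
    class(params) <- c("standardization_params", "data.frame")
  } else {
    missing <- setdiff(params$analyte_id, colnames(L))
    if (length(missing))
      stop("cohort lacks analyte(s) required by the standardization: ",
           paste(head(missing, 5), collapse = ", "), call. = FALSE)
    L <- L[, params$analyte_id, drop = FALSE]
  }
  z <- sweep(sweep(L, 2, params$mean, "-"), 2, params$sd, "/")
  list(z = z, params = params)
}

#' Random train/test partition of a cohort
#'
#' Uniform random split, deterministic given the seed; the training set has
#' `round(fraction * n)` subjects.
#'
#' @param cohort a [proteomic_cohort()].
#' @param fraction training fraction in (0, 1); default 2/3.
#' @param seed integer seed.
#' @return A `train_test_split` list: `train_ids`, `test_ids`, `fraction`,
#'   `seed`.
#' @export
split_train_test <- function(cohort, fraction = 2/3, seed = 1) {
  stopifnot(inherits(cohort, "proteomic_cohort"))
  check_scalar_number(fraction, "fraction")
  if (fraction <= 0 || fraction >= 1)
    stop_field("fraction", "must lie strictly between 0 and 1")
  n <- nrow(cohort$intensities)
  if (n < 3L) stop("need at least 3 subjects to split", call. = FALSE)
  ids <- subject_ids(cohort)
  n_train <- round(fraction * n)
  train <- with_seed(seed, sample(ids, n_train))
  structure(list(train_ids = sort(train),
                 test_ids = sort(setdiff(ids, train)),
                 fraction = fraction, seed = seed),
            class = "train_test_split")
}

#' @export
print.train_test_split <- function(x, ...) {
  cat(sprintf("<train_test_split> %d train / %d test (fraction %.3f, seed %d)\n",
              length(x$train_ids), length(x$test_ids), x$fraction, x$seed))
  invisible(x)
}

# subset a cohort to a set of subject ids (internal)
subset_subjects <- function(cohort, ids) {
  sel <- match(ids, subject_ids(cohort))
  if (anyNA(sel)) stop("unknown subject id(s) in split", call. = FALSE)
  cohort$intensities <- cohort$intensities[sel, , drop = FALSE]
  cohort$subjects <- cohort$subjects[sel, , drop = FALSE]
  rownames(cohort$subjects) <- NULL
  cohort
}
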