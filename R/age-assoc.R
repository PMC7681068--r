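#' Per-analyte age-association regression
#'
#' Fits, for every analyte, an ordinary least-squares regression of log10
#' intensity on age (optionally adjusting for sex), and reports the per-year
#' age coefficient, its standard error, and the two-sided t-test p-value on
#' the age slope. q-values are left unset; see [adjust_fdr()].
#'
#' Analytes with zero variance are not an error: they get slope 0, p-value 1
#' and `constant = TRUE`.
#'
#' @param cohort a [proteomic_cohort()].
#' @param covariates `NULL` (default; model `log10(y) ~ age`) or `"sex"` to
#'   add the sex code as a covariate.
#' @return An `age_association` data.frame with columns `analyte_id`,
#'   `age_coefficient`, `std_error`, `p_value`, `q_value` (NA), `direction`
#'   (NA), `constant`.
#' @export
fit_age_regression <- function(cohort, covariates = NULL) {
  stopifnot(inherits(cohort, "proteomic_cohort"))
  n <- nrow(cohort$intensities)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  age <- cohort$subjects$age
  if (var(age) == 0) stop("ages are all equal; slope not identifiable",
                          call. = FALSE)
  X <- cbind(1, age = age)
  if (!is.null(covariates)) {
    covariates <- match.arg(covariates, "sex")
    if (is.null(cohort$subjects$sex))
      stop("cohort has no 'sex' column", call. = FALSE)
    X <- cbind(X, sex = cohort$subjects$sex)
  }
  k <- ncol(X)
  if (n <= k) stop("too few subjects for the requested model", call. = FALSE)

  Y <- log10(cohort$intensities)
  const <- apply(Y, 2, function(v) all(v == v[1]))

  fit <- stats::lm.fit(X, Y)
  cf <- fit$coefficients
  if (is.null(dim(cf))) cf <- matrix(cf, ncol = 1, dimnames = list(names(cf)))
  beta <- cf["age", ]
  res <- as.matrix(fit$residuals)
  df <- n - k
  sigma2 <- colSums(res^2) / df
  xtx_inv_age <- chol2inv(qr.R(fit$qr))[2, 2]
  se <- sqrt(sigma2 * xtx_inv_age)
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df)

  beta[const] <- 0
  se[const] <- NA_real_
  p[const] <- 1

  out <- data.frame(analyte_id = analyte_ids(cohort),
                    age_coefficient = unname(beta),
                    std_error = unname(se),
                    p_value = unname(p),
                    q_value = NA_real_,
                    direction = NA_character_,
                    constant = unname(const),
                    stringsAsFactors = FALSE)
  class(out) <- c("age_association", "data.frame")
  out
}

#' False-discovery-rate adjustment
#'
#' Benjamini-Hochberg step-up q-values (default), or the BH values scaled by
#' a Storey-type null-proportion estimate `pi0 = min(1, mean(p > 0.5)/0.5)`.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` (default) or `"storey"`.
#' @return q-values, in the input order.
#' @export
adjust_fdr <- function(p_values, method = c("BH", "storey")) {
  method <- match.arg(method)
  if (!is.numeric(p_values) || any(!is.finite(p_values)) ||
      any(p_values < 0 | p_values > 1))
    stop("p-values must be numbers in [0, 1]", call. = FALSE)
  q <- p.adjust(p_values, method = "BH")
  if (method == "storey") {
    pi0 <- min(1, mean(p_values > 0.5) / 0.5)
    q <- pmin(1, pi0 * q)
  }
  q
}

#' Classify per-analyte age trends at a q-value threshold
#'
#' Fills the `q_value` (if unset) and `direction` columns of an
#' `age_association` table: `increasing`/`decreasing` for analytes
#' significant at `q_threshold`, `none` otherwise.
#'
#' @param assoc an `age_association` from [fit_age_regression()].
#' @param q_threshold significance threshold on the q-value (default 0.05).
#' @param fdr_method passed to [adjust_fdr()] when q-values are unset.
#' @return The table with `q_value` and `direction` filled.
#' @export
classify_directions <- function(assoc, q_threshold = 0.05, fdr_method = "BH") {
  stopifnot(inherits(assoc, "age_association"))
  if (anyNA(assoc$q_value))
    assoc$q_value <- adjust_fdr(assoc$p_value, method = fdr_method)
  sig <- assoc$q_value < q_threshold
  assoc$direction <- ifelse(!sig, "none",
                            ifelse(assoc$age_coefficient > 0,
                                   "increasing", "decreasing"))
  assoc
}

#' Count significant age trends by direction
#'
#' @param assoc an `age_association`; q-values are computed if unset.
#' @param q_threshold significance threshold (default 0.05).
#' @return A list with `n_total`, `n_significant`, `n_increasing`,
#'   `n_decreasing`, `n_none`, and `pct_increasing`/`pct_decreasing` as
#'   percentages of the significant analytes.
#' @export
summarize_directions <- function(assoc, q_threshold = 0.05) {
  assoc <- classify_directions(assoc, q_threshold = q_threshold)
  n_inc <- sum(assoc$direction == "increasing")
  n_dec <- sum(assoc$direction == "decreasing")
  n_sig <- n_inc + n_dec
  out <- list(n_total = nrow(assoc),
              n_significant = n_sig,
              n_increasing = n_inc,
              n_decreasing = n_dec,
              n_none = nrow(assoc) - n_sig,
              pct_increasing = if (n_sig > 0) 100 * n_inc / n_sig else NA_real_,
              pct_decreasing = if (n_sig > 0) 100 * n_dec / n_sig else NA_real_,
              q_threshold = q_threshold)
  class(out) <- "direction_summary"
  out
}

#' @export
print.direction_summary <- function(x, ...) {
  cat(sprintf("%d of %d analytes significant at q < %g\n",
              x$n_significant, x$n_total, x$q_threshold))
  if (x$n_significant > 0)
    cat(sprintf("  increasing: %d (%.2f%%)   decreasing: %d (%.2f%%)\n",
                x$n_increasing, x$pct_increasing,
                x$n_decreasing, x$pct_decreasing))
  invisible(x)
}
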