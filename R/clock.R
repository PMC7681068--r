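new_aging_clock <- function(alpha, lambda, intercept, beta, standardization,
                            training = NULL, fit = NULL, split = NULL,
                            evaluation = NULL) {
  structure(list(alpha = alpha, lambda = lambda, intercept = intercept,
                 beta = beta, standardization = standardization,
                 training = training, fit = fit, split = split,
                 evaluation = evaluation),
            class = "aging_clock")
}

#' Train a proteomic aging clock
#'
#' Fits a penalized linear predictor of chronological age from z-scaled
#' log10 intensities: the cohort is partitioned into training and test sets
#' (2/3-1/3 by default), standardization parameters are estimated on the
#' training set (or the whole cohort with `scaling = "global"`), and a ridge
#' (`alpha = 0`) or LASSO (`alpha = 1`) model is fitted with the penalty
#' selected by tenfold cross-validation over a 100-value lambda path
#' (`lambda.min` rule). Training- and test-set performance (Pearson r and
#' median absolute error) is evaluated and stored.
#'
#' @param cohort a [proteomic_cohort()].
#' @param features optional analyte ids to restrict the predictor set
#'   (e.g. a pathway); default all analytes.
#' @param alpha elastic-net mixing: 0 = ridge (default), 1 = LASSO.
#' @param split optional [split_train_test()] result to reuse; built from
#'   `fraction` and `seed` when missing.
#' @param fraction training fraction when `split` is missing (default 2/3).
#' @param seed integer seed for the split and CV folds.
#' @param n_lambda,n_folds,lambda_min_ratio,tol passed to
#'   [fit_penalized_clock()].
#' @param scaling `"train"` (default; standardization estimated on the
#'   training subjects only, no leakage) or `"global"` (whole cohort).
#' @return An object of class `aging_clock` with components `alpha`,
#'   `lambda`, `intercept`, `beta` (weights on the standardized scale),
#'   `standardization`, `split`, `fit` (the underlying [fit_penalized_clock()]
#'   object) and `evaluation` (`$train`, `$test`).
#' @seealso [predict.aging_clock()], [evaluate_clock()],
#'   [write_clock_model()]
#' @export
train_clock <- function(cohort, features = NULL, alpha = 0, split = NULL,
                        fraction = 2/3, seed = 1, n_lambda = 100,
                        n_folds = 10, lambda_min_ratio = NULL, tol = 1e-7,
                        scaling = c("train", "global")) {
  stopifnot(inherits(cohort, "proteomic_cohort"))
  scaling <- match.arg(scaling)
  if (!is.null(features)) {
    features <- as.character(features)
    unknown <- setdiff(features, analyte_ids(cohort))
    if (length(unknown))
      stop("unknown feature analyte(s): ",
           paste(head(unknown, 5), collapse = ", "), call. = FALSE)
    cohort <- apply_platform_mask(cohort, features)
  }
  if (is.null(split)) split <- split_train_test(cohort, fraction, seed)
  train <- subset_subjects(cohort, split$train_ids)
  test <- subset_subjects(cohort, split$test_ids)

  ref <- if (scaling == "train") train else cohort
  std <- log_standardize(ref)
  z_train <- log_standardize(train, std$params)$z
  z_test <- log_standardize(test, std$params)$z

  fit <- fit_penalized_clock(z_train, train$subjects$age, alpha = alpha,
                             n_lambda = n_lambda, n_folds = n_folds,
                             lambda_min_ratio = lambda_min_ratio,
                             seed = seed, tol = tol)

  clock <- new_aging_clock(
    alpha = alpha, lambda = fit$lambda, intercept = fit$intercept,
    beta = fit$beta, standardization = std$params,
    training = list(n_train = length(split$train_ids),
                    n_test = length(split$test_ids),
                    fraction = split$fraction, seed = seed,
                    scaling = scaling),
    fit = fit, split = split)

  pred_train <- predict(clock, train)
  pred_test <- predict(clock, test)
  clock$evaluation <- list(
    train = evaluate_clock(pred_train, train$subjects$age, label = "train"),
    test = evaluate_clock(pred_test, test$subjects$age, label = "test"))
  clock
}

#' Predict chronological age from a cohort
#'
#' Applies the clock's stored standardization to the cohort's log10
#' intensities and evaluates `b0 + sum_j beta_j z_j`. With `features`, only
#' the listed analytes contribute: the weights of missing features are
#' simply omitted (equivalent to imputing the training mean on the z scale),
#' the no-refit rule used when a clock is carried to a smaller measurement
#' panel. Such restricted predictions are attenuated; see
#' [estimate_correction()].
#'
#' @param object an `aging_clock`.
#' @param cohort a [proteomic_cohort()] containing the model's features (all
#'   of them, or at least `features` when given).
#' @param features optional subset of the clock's analytes to use.
#' @param ... unused.
#' @return Named numeric vector of predicted ages (years).
#' @export
predict.aging_clock <- function(object, cohort, features = NULL, ...) {
  stopifnot(inherits(cohort, "proteomic_cohort"))
  model_features <- object$standardization$analyte_id
  if (is.null(features)) {
    missing <- setdiff(model_features, analyte_ids(cohort))
    if (length(missing))
      stop(sprintf(paste0("cohort lacks %d clock feature(s) (e.g. %s); pass ",
                          "'features' with the available subset to predict ",
                          "without refitting"),
                   length(missing), paste(head(missing, 3), collapse = ", ")),
           call. = FALSE)
    features <- model_features
  } else {
    features <- as.character(features)
    bad <- setdiff(features, model_features)
    if (length(bad))
      stop("feature(s) not part of the clock: ",
           paste(head(bad, 5), collapse = ", "), call. = FALSE)
    features <- intersect(features, analyte_ids(cohort))
    if (length(features) == 0L)
      stop("no overlap between requested features and cohort analytes",
           call. = FALSE)
  }
  std <- object$standardization
  std <- std[std$analyte_id %in% features, , drop = FALSE]
  z <- log_standardize(cohort, params = std)$z
  beta <- object$beta[std$analyte_id]
  drop(z %*% beta) + object$intercept
}

#' @export
coef.aging_clock <- function(object, nonzero = FALSE, ...) {
  b <- object$beta
  if (nonzero) b <- b[b != 0]
  c("(Intercept)" = object$intercept, b)
}

#' @export
print.aging_clock <- function(x, ...) {
  kind <- if (x$alpha == 0) "ridge" else if (x$alpha == 1) "LASSO"
          else sprintf("elastic net (alpha = %g)", x$alpha)
  cat(sprintf("<aging_clock> %s over %d analytes (%d nonzero), lambda = %.4g\n",
              kind, length(x$beta), sum(x$beta != 0), x$lambda))
  if (!is.null(x$evaluation)) {
    tr <- x$evaluation$train; te <- x$evaluation$test
    cat(sprintf("  train: r = %.3f, MAE = %.2f y (n = %d)\n", tr$r, tr$mae, tr$n))
    cat(sprintf("  test:  r = %.3f, MAE = %.2f y (n = %d)\n", te$r, te$mae, te$n))
  }
  invisible(x)
}

#' @export
summary.aging_clock <- function(object, ...) {
  print(object)
  b <- object$beta[object$beta != 0]
  if (length(b)) {
    cat(sprintf("  weights (standardized scale): min %.3g, median %.3g, max %.3g\n",
                min(b), median(b), max(b)))
    top <- sort(abs(b), decreasing = TRUE)
    cat("  largest |weight|:",
        paste(sprintf("%s (%.3g)", names(top)[seq_len(min(5, length(top)))],
                      b[names(top)[seq_len(min(5, length(top)))]]),
              collapse = ", "), "\n")
  }
  invisible(object)
}

#' Plot an aging clock
#'
#' `which = "cv"` draws the cross-validation curve (mean CV squared error
#' against log lambda, selected penalty marked); `which = "prediction"`
#' draws predicted vs chronological age for a cohort.
#'
#' @param x an `aging_clock` trained with [train_clock()].
#' @param which `"cv"` or `"prediction"`.
#' @param cohort cohort to predict on when `which = "prediction"`.
#' @param ... passed to the underlying plot call.
#' @export
plot.aging_clock <- function(x, which = c("cv", "prediction"), cohort = NULL,
                             ...) {
  which <- match.arg(which)
  if (which == "cv") {
    if (is.null(x$fit)) stop("no CV path stored in this clock", call. = FALSE)
    graphics::plot(log(x$fit$lambda_path), x$fit$cvm, type = "l",
                   xlab = "log(lambda)", ylab = "mean CV squared error", ...)
    graphics::abline(v = log(x$lambda), lty = 2)
  } else {
    if (is.null(cohort)) stop("'cohort' required for a prediction plot",
                              call. = FALSE)
    pred <- predict(x, cohort)
    age <- cohort$subjects$age
    graphics::plot(age, pred, xlab = "chronological age (years)",
                   ylab = "predicted age (years)", ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}

#' Evaluate age predictions
#'
#' Pearson correlation between predicted and chronological age, and the
#' median absolute error in years.
#'
#' @param predicted,chronological numeric vectors of equal length >= 2.
#' @param label optional split label carried in the result.
#' @return A `clock_evaluation` list: `r`, `mae`, `n`, `label`. `r` is `NA`
#'   when the predictions are constant (e.g. a clock with no active
#'   weights).
#' @export
evaluate_clock <- function(predicted, chronological, label = NULL) {
  if (length(predicted) != length(chronological))
    stop("predicted and chronological must have equal length", call. = FALSE)
  if (length(predicted) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (var(chronological) == 0)
    stop("chronological ages are constant; correlation undefined",
         call. = FALSE)
  # a clock with no active weights predicts a constant: r is undefined
  r <- if (var(predicted) == 0) NA_real_ else cor(predicted, chronological)
  structure(list(r = r,
                 mae = median(abs(predicted - chronological)),
                 n = length(predicted), label = label),
            class = "clock_evaluation")
}

#' @export
print.clock_evaluation <- function(x, ...) {
  cat(sprintf("%sr = %.3f, MAE = %.2f years (n = %d)\n",
              if (is.null(x$label)) "" else paste0(x$label, ": "),
              x$r, x$mae, x$n))
  invisible(x)
}
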