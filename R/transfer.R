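#' Estimate a slope-offset correction for a feature-restricted clock
#'
#' When a clock is applied without refitting to a cohort that measures only
#' a subset of its analytes (see [predict.aging_clock()] with `features`),
#' the restricted predictions are attenuated: they regress towards the
#' training-mean age with a slope below 1. This procedure quantifies that
#' attenuation on a learning cohort that has the full panel: restricted
#' predictions `y_r` are regressed on chronological age, `y_r = a + b *
#' age`, and the correction coefficient `kappa = 1/b` is reported.
#'
#' @param model an `aging_clock`.
#' @param learning_cohort cohort with all clock features (typically the
#'   training cohort).
#' @param features the analyte subset available on the target platform.
#' @return A `transfer_correction` list: `features` (shared set), `a`
#'   (intercept, years), `b` (slope), `kappa` (= 1/b), `n_learning`.
#' @seealso [apply_correction()]
#' @export
estimate_correction <- function(model, learning_cohort, features) {
  stopifnot(inherits(model, "aging_clock"),
            inherits(learning_cohort, "proteomic_cohort"))
  pred_r <- predict(model, learning_cohort, features = features)
  age <- learning_cohort$subjects$age
  if (sd(pred_r) < 1e-12)
    stop("restricted predictions are (near-)constant; degenerate sub-clock",
         call. = FALSE)
  fit <- lm(pred_r ~ age)
  b <- unname(coef(fit)[2])
  a <- unname(coef(fit)[1])
  if (abs(b) < 1e-8)
    stop("learning-set slope is within 1e-8 of zero; degenerate sub-clock",
         call. = FALSE)
  structure(list(features = intersect(model$standardization$analyte_id,
                                      as.character(features)),
                 a = a, b = b, kappa = 1 / b,
                 n_learning = length(age)),
            class = "transfer_correction")
}

#' Correct restricted-clock predictions for slope attenuation
#'
#' Inverts the learning-set line: `y_corr = (y_r - a) / b` (default), so
#' that corrected predictions regressed on age have slope 1 and intercept 0
#' on the learning set. `method = "multiplier"` instead applies the bare
#' correction coefficient, `y_corr = kappa * y_r`.
#'
#' @param predictions restricted predictions (years).
#' @param correction a `transfer_correction` from [estimate_correction()].
#' @param method `"affine"` (default) or `"multiplier"`.
#' @return Corrected predicted ages (years).
#' @export
apply_correction <- function(predictions, correction,
                             method = c("affine", "multiplier")) {
  stopifnot(inherits(correction, "transfer_correction"))
  method <- match.arg(method)
  switch(method,
         affine = (predictions - correction$a) / correction$b,
         multiplier = correction$kappa * predictions)
}

#' @export
print.transfer_correction <- function(x, ...) {
  cat(sprintf("<transfer_correction> %d shared features\n", length(x$features)))
  cat(sprintf("  learning fit: pred = %.3f + %.3f * age (n = %d)\n",
              x$a, x$b, x$n_learning))
  cat(sprintf("  correction coefficient kappa = %.3f\n", x$kappa))
  invisible(x)
}
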