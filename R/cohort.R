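#' Construct a proteomic cohort
#'
#' Bundles a subject-by-analyte intensity matrix (raw relative-fluorescence
#' scale, strictly positive so that log10 is defined) with subject metadata
#' (age in years, sex code, group label) and analyte annotations.
#'
#' @param intensities numeric matrix, subjects in rows and analytes in
#'   columns, with row names equal to `subjects$subject_id` and column names
#'   equal to `analytes$analyte_id`. All values must be strictly positive.
#' @param subjects data.frame with columns `subject_id`, `age`, and
#'   optionally `sex` (0/1) and `group`.
#' @param analytes data.frame with columns `analyte_id` and optionally
#'   `protein_id`, `gene_symbol`.
#' @return An object of class `proteomic_cohort`: a list with elements
#'   `intensities`, `subjects`, `analytes`.
#' @export
proteomic_cohort <- function(intensities, subjects, analytes) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("'intensities' must be a numeric matrix", call. = FALSE)
  if (!is.data.frame(subjects) || !all(c("subject_id", "age") %in% names(subjects)))
    stop("'subjects' must be a data.frame with subject_id and age", call. = FALSE)
  if (!is.data.frame(analytes) || !"analyte_id" %in% names(analytes))
    stop("'analytes' must be a data.frame with analyte_id", call. = FALSE)
  subjects$subject_id <- as.character(subjects$subject_id)
  analytes$analyte_id <- as.character(analytes$analyte_id)

  if (anyDuplicated(subjects$subject_id))
    stop("duplicate subject_id in subject metadata", call. = FALSE)
  if (anyDuplicated(analytes$analyte_id))
    stop("duplicate analyte_id in analyte metadata", call. = FALSE)
  if (nrow(intensities) != nrow(subjects))
    stop("intensity rows do not match subject metadata rows", call. = FALSE)
  if (ncol(intensities) != nrow(analytes))
    stop("intensity columns do not match analyte metadata rows", call. = FALSE)
  if (is.null(rownames(intensities))) rownames(intensities) <- subjects$subject_id
  if (is.null(colnames(intensities))) colnames(intensities) <- analytes$analyte_id
  if (!identical(rownames(intensities), subjects$subject_id))
    stop("intensity row names do not match subject_id order", call. = FALSE)
  if (!identical(colnames(intensities), analytes$analyte_id))
    stop("intensity column names do not match analyte_id order", call. = FALSE)
  if (!all(is.finite(intensities)) || any(intensities <= 0))
    stop("intensities must be finite and strictly positive (log10 scale must be defined)",
         call. = FALSE)
  if (!is.numeric(subjects$age) || !all(is.finite(subjects$age)))
    stop("subject ages must be finite numbers", call. = FALSE)

  structure(list(intensities = intensities, subjects = subjects,
                 analytes = analytes),
            class = "proteomic_cohort")
}

#' @export
print.proteomic_cohort <- function(x, ...) {
  cat(sprintf("<proteomic_cohort> %d subjects x %d analytes\n",
              nrow(x$intensities), ncol(x$intensities)))
  cat(sprintf("  age: %.1f-%.1f years (median %.1f)\n",
              min(x$subjects$age), max(x$subjects$age),
              median(x$subjects$age)))
  if (!is.null(x$subjects$group)) {
    tab <- table(x$subjects$group)
    cat("  groups:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.proteomic_cohort <- function(x) dim(x$intensities)

#' Analyte and subject identifiers of a cohort
#'
#' @param cohort a [proteomic_cohort()].
#' @return Character vector of ids, in matrix column (row) order.
#' @export
analyte_ids <- function(cohort) cohort$analytes$analyte_id

#' @rdname analyte_ids
#' @export
subject_ids <- function(cohort) cohort$subjects$subject_id
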