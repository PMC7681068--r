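#' Specify a synthetic plasma-proteome aging cohort
#'
#' Defines the generative model for [generate_cohort()]. Each analyte p has a
#' log10-scale baseline mu_p ~ Normal(3, 0.5) (RFUs in the thousands), a true
#' per-year age coefficient beta_p, a sex effect gamma_p ~ Normal(0,
#' `sex_effect_sd`), and i.i.d. Gaussian noise with standard deviation
#' `noise_sd`. A fraction `frac_informative` of analytes carries a nonzero
#' beta_p whose magnitude is drawn log-uniformly over `beta_range` and whose
#' sign is positive with probability `frac_increasing`; the remaining
#' analytes are age-null.
#'
#' Defaults emulate a large donor cohort: ages 18-76 years, ~3000 analytes,
#' 15% age-informative with a 76/24 increasing/decreasing split, and
#' per-year log10 coefficients spanning 3.24e-4 to 1.64e-2.
#'
#' @param n_subjects,n_analytes cohort dimensions.
#' @param age_range length-2 numeric, min < max, in years.
#' @param frac_informative fraction of analytes with a true age trend.
#' @param frac_increasing fraction of informative analytes trending upward.
#' @param beta_range length-2 positive increasing numeric; per-year change in
#'   log10 intensity. Magnitudes are drawn log-uniformly over this range.
#' @param noise_sd residual standard deviation on the log10 scale.
#' @param sex_effect_sd standard deviation of per-analyte sex effects
#'   (log10 scale); 0 disables sex effects.
#' @param age_dist `"uniform"` (default) or `"triangular"`; the triangular
#'   option skews sampling towards `age_median` (default 45 years) to mimic
#'   a blood-donor age pyramid.
#' @param age_median target median for the triangular option.
#' @param seed integer seed; all draws are reproducible given the seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 3000, n_analytes = 3000,
                        age_range = c(18, 76),
                        frac_informative = 0.15,
                        frac_increasing = 0.7584,
                        beta_range = c(3.24e-4, 1.64e-2),
                        noise_sd = 0.05, sex_effect_sd = 0.02,
                        age_dist = c("uniform", "triangular"),
                        age_median = 45, seed = 1) {
  spec <- list(
    n_subjects = check_count(n_subjects, "n_subjects"),
    n_analytes = check_count(n_analytes, "n_analytes", min = 1L),
    age_range = age_range,
    frac_informative = check_fraction(frac_informative, "frac_informative"),
    frac_increasing = check_fraction(frac_increasing, "frac_increasing"),
    beta_range = beta_range,
    noise_sd = check_scalar_number(noise_sd, "noise_sd"),
    sex_effect_sd = check_scalar_number(sex_effect_sd, "sex_effect_sd"),
    age_dist = match.arg(age_dist),
    age_median = check_scalar_number(age_median, "age_median"),
    seed = check_count(seed, "seed")
  )
  if (!is.numeric(age_range) || length(age_range) != 2L ||
      !all(is.finite(age_range)) || age_range[1] >= age_range[2])
    stop_field("age_range", "must be two finite values with min < max")
  if (!is.numeric(beta_range) || length(beta_range) != 2L ||
      any(beta_range <= 0) || beta_range[1] > beta_range[2])
    stop_field("beta_range", "bounds must be positive and ordered")
  if (spec$noise_sd < 0) stop_field("noise_sd", "must be >= 0")
  if (spec$sex_effect_sd < 0) stop_field("sex_effect_sd", "must be >= 0")
  structure(spec, class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d subjects x %d analytes, ages %g-%g (%s)\n",
              x$n_subjects, x$n_analytes, x$age_range[1], x$age_range[2],
              x$age_dist))
  cat(sprintf("  informative: %.1f%% (%.2f%% increasing), |beta| in [%.3g, %.3g]/yr\n",
              100 * x$frac_informative, 100 * x$frac_increasing,
              x$beta_range[1], x$beta_range[2]))
  cat(sprintf("  noise_sd %.3g, sex_effect_sd %.3g, seed %d\n",
              x$noise_sd, x$sex_effect_sd, x$seed))
  invisible(x)
}

# inverse-CDF sampler for a triangular distribution on [a, b] whose median
# equals `med` (the mode is solved from the median)
sample_triangular <- function(n, a, b, med) {
  c1 <- a + 2 * (med - a)^2 / (b - a)       # valid when mode right of median
  c2 <- b - 2 * (b - med)^2 / (b - a)       # valid when mode left of median
  mode <- if ((c1 - a) / (b - a) >= 0.5) c1 else c2
  u <- runif(n)
  fc <- (mode - a) / (b - a)
  ifelse(u < fc,
         a + sqrt(u * (b - a) * (mode - a)),
         b - sqrt((1 - u) * (b - a) * (b - mode)))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a cohort from the generative model of [cohort_spec()]:
#' `log10(intensity)[i, p] = mu_p + beta_p * (age_i - age_center) +
#' gamma_p * sex_i + eps[i, p]` with `eps ~ Normal(0, noise_sd^2)`, returned
#' on the raw (power-of-ten) intensity scale. Exactly
#' `round(frac_informative * n_analytes)` analytes receive a nonzero
#' `beta_p`, of which a `frac_increasing` share is positive. All draws are
#' deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param truth optional `cohort_truth` from a previous call; when supplied,
#'   the per-analyte parameters (baselines, true coefficients, sex effects,
#'   age centering) are reused so the new cohort is an independent draw of
#'   *subjects* from the same generative process — the basis for transfer and
#'   validation experiments.
#' @param group label stored in the subject metadata `group` column.
#' @return A list with elements `cohort` (a [proteomic_cohort()]) and `truth`
#'   (a `cohort_truth` data.frame with per-analyte `true_beta`,
#'   `informative`, `direction`, plus the baselines and sex effects; the age
#'   centering constant is kept as an attribute).
#' @export
generate_cohort <- function(spec, truth = NULL, group = "all") {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  p <- spec$n_analytes
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "cohort_truth"))
    if (nrow(truth) != p)
      stop("supplied truth has a different analyte count than the spec",
           call. = FALSE)
  }

  with_seed(spec$seed, {
    ages <- switch(spec$age_dist,
      uniform = runif(n, spec$age_range[1], spec$age_range[2]),
      triangular = sample_triangular(n, spec$age_range[1], spec$age_range[2],
                                     spec$age_median))
    sex <- rbinom(n, 1L, 0.5)

    if (is.null(truth)) {
      n_inf <- round(spec$frac_informative * p)
      informative <- logical(p)
      informative[sample.int(p, n_inf)] <- TRUE
      beta <- numeric(p)
      if (n_inf > 0) {
        mag <- exp(runif(n_inf, log(spec$beta_range[1]), log(spec$beta_range[2])))
        n_pos <- round(spec$frac_increasing * n_inf)
        sign <- rep(-1, n_inf)
        sign[sample.int(n_inf, n_pos)] <- 1
        beta[informative] <- mag * sign
      }
      mu <- rnorm(p, 3, 0.5)
      gamma <- if (spec$sex_effect_sd > 0) rnorm(p, 0, spec$sex_effect_sd) else numeric(p)
      age_center <- mean(ages)

      wid <- max(4L, nchar(as.character(p)))
      analyte_id <- sprintf("SOMA.%0*d", wid, seq_len(p))
      # a few proteins are covered by more than one reagent, as on real panels
      n_prot <- max(1L, round(p * 2978 / 3283))
      prot_idx <- sort(rep_len(seq_len(n_prot), p))
      analytes <- data.frame(
        analyte_id = analyte_id,
        protein_id = sprintf("UP%0*d", wid, prot_idx),
        gene_symbol = sprintf("G%0*d", wid, prot_idx),
        stringsAsFactors = FALSE)

      truth <- data.frame(
        analyte_id = analyte_id,
        true_beta = beta,
        informative = informative,
        direction = sign(beta),
        mu = mu,
        sex_effect = gamma,
        stringsAsFactors = FALSE)
      attr(truth, "age_center") <- age_center
      attr(truth, "noise_sd") <- spec$noise_sd
      attr(truth, "analyte_meta") <- analytes
      class(truth) <- c("cohort_truth", "data.frame")
    } else {
      analytes <- attr(truth, "analyte_meta")
      age_center <- attr(truth, "age_center")
    }

    eps <- if (spec$noise_sd > 0)
      matrix(rnorm(n * p, 0, spec$noise_sd), n, p) else matrix(0, n, p)
    logI <- eps +
      matrix(truth$mu, n, p, byrow = TRUE) +
      (ages - age_center) %o% truth$true_beta +
      sex %o% truth$sex_effect

    wid_s <- max(4L, nchar(as.character(n)))
    sid <- sprintf("S%0*d", wid_s, seq_len(n))
    intens <- 10^logI
    dimnames(intens) <- list(sid, truth$analyte_id)
    subjects <- data.frame(subject_id = sid, age = ages, sex = sex,
                           group = group, stringsAsFactors = FALSE)

    list(cohort = proteomic_cohort(intens, subjects, analytes),
         truth = truth)
  })
}

#' Shift selected subjects along their true aging trajectory
#'
#' Adds `true_beta * delta_years` to the log10 intensity of every analyte for
#' the selected subjects — i.e. makes their proteome look `delta_years` older
#' (or younger, if negative) while leaving chronological ages untouched. This
#' is the synthetic analog of a group whose biology runs ahead of its
#' calendar age.
#'
#' @param cohort a [proteomic_cohort()].
#' @param truth the matching `cohort_truth`.
#' @param subject_ids subjects to shift; must exist in the cohort.
#' @param delta_years shift in years (may be negative).
#' @return The shifted cohort.
#' @export
inject_aging_shift <- function(cohort, truth, subject_ids, delta_years) {
  stopifnot(inherits(cohort, "proteomic_cohort"), inherits(truth, "cohort_truth"))
  check_scalar_number(delta_years, "delta_years")
  subject_ids <- as.character(subject_ids)
  unknown <- setdiff(subject_ids, subject_ids(cohort))
  if (length(unknown))
    stop("unknown subject id(s): ", paste(head(unknown, 5), collapse = ", "),
         call. = FALSE)
  idx <- match(colnames(cohort$intensities), truth$analyte_id)
  if (anyNA(idx))
    stop("cohort contains analytes absent from the ground truth", call. = FALSE)
  fac <- 10^(truth$true_beta[idx] * delta_years)
  sel <- match(subject_ids, rownames(cohort$intensities))
  cohort$intensities[sel, ] <- cohort$intensities[sel, , drop = FALSE] *
    matrix(fac, length(sel), ncol(cohort$intensities), byrow = TRUE)
  cohort
}

#' Restrict a cohort to a measurement panel
#'
#' Keeps only the listed analytes, preserving the cohort's column order —
#' the synthetic analog of applying a clock to an assay version that
#' measures a smaller panel.
#'
#' @param cohort a [proteomic_cohort()].
#' @param keep_analytes analyte ids to retain (non-empty, all present).
#' @return The masked cohort.
#' @export
apply_platform_mask <- function(cohort, keep_analytes) {
  stopifnot(inherits(cohort, "proteomic_cohort"))
  keep_analytes <- as.character(keep_analytes)
  if (length(keep_analytes) == 0L)
    stop("'keep_analytes' must be non-empty", call. = FALSE)
  unknown <- setdiff(keep_analytes, analyte_ids(cohort))
  if (length(unknown))
    stop("unknown analyte id(s): ", paste(head(unknown, 5), collapse = ", "),
         call. = FALSE)
  keep <- analyte_ids(cohort) %in% keep_analytes
  cohort$intensities <- cohort$intensities[, keep, drop = FALSE]
  cohort$analytes <- cohort$analytes[keep, , drop = FALSE]
  rownames(cohort$analytes) <- NULL
  cohort
}

#' Generate a synthetic pathway collection
#'
#' Draws `n_pathways` analyte sets of sizes uniform over `size_range`. The
#' first `n_enriched` sets are "enriched": a fraction `enriched_frac` of
#' their members is drawn from age-informative analytes, so that a clock
#' restricted to such a set predicts age well while random sets do not.
#'
#' @param analyte_meta analyte annotation table (from a cohort or truth).
#' @param truth the matching `cohort_truth`.
#' @param n_pathways number of sets.
#' @param size_range length-2 integer range of set sizes, within the panel.
#' @param n_enriched how many sets to bias towards informative analytes.
#' @param enriched_frac target informative fraction within enriched sets.
#' @param seed integer seed.
#' @return A `pathway_collection` (see [read_gmt()]); enriched pathway ids
#'   are recorded in the `enriched` attribute.
#' @export
generate_pathway_collection <- function(analyte_meta, truth,
                                        n_pathways = 50,
                                        size_range = c(5, 50),
                                        n_enriched = 1,
                                        enriched_frac = 0.8,
                                        seed = 1) {
  stopifnot(inherits(truth, "cohort_truth"))
  n_pathways <- check_count(n_pathways, "n_pathways", min = 1L)
  n_enriched <- check_count(n_enriched, "n_enriched")
  check_fraction(enriched_frac, "enriched_frac")
  p <- nrow(analyte_meta)
  if (!is.numeric(size_range) || length(size_range) != 2L ||
      size_range[1] < 1 || size_range[2] > p || size_range[1] > size_range[2])
    stop_field("size_range", sprintf("must lie within [1, %d] and be ordered", p))
  if (n_enriched > n_pathways)
    stop_field("n_enriched", "cannot exceed n_pathways")

  ids <- analyte_meta$analyte_id
  inf_ids <- truth$analyte_id[truth$informative]
  null_ids <- truth$analyte_id[!truth$informative]

  with_seed(seed, {
    sizes <- sample(seq(size_range[1], size_range[2]), n_pathways, replace = TRUE)
    entries <- vector("list", n_pathways)
    wid <- max(3L, nchar(as.character(n_pathways)))
    nm <- sprintf("PW%0*d", wid, seq_len(n_pathways))
    for (k in seq_len(n_pathways)) {
      if (k <= n_enriched && length(inf_ids) > 0) {
        n_inf <- min(round(enriched_frac * sizes[k]), length(inf_ids))
        n_other <- sizes[k] - n_inf
        members <- c(sample(inf_ids, n_inf),
                     if (n_other > 0) sample(null_ids, min(n_other, length(null_ids))))
        desc <- "synthetic age-enriched set"
      } else {
        members <- sample(ids, sizes[k])
        desc <- "synthetic random set"
      }
      entries[[k]] <- list(description = desc, members = unique(members))
    }
    names(entries) <- nm
    structure(entries, class = "pathway_collection",
              enriched = nm[seq_len(n_enriched)])
  })
}
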