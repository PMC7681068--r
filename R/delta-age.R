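#' Per-subject delta age and group summaries
#'
#' Delta age is predicted minus chronological age in years; positive values
#' read as "biologically older". Group summaries report mean and SD of
#' chronological age, predicted age, and delta age.
#'
#' @param predicted,chronological aligned numeric vectors (years); missing
#'   values are an error.
#' @param groups group label per subject (default a single group).
#' @param subject_ids optional subject identifiers.
#' @return A `delta_age` object: `$table` (per-subject) and `$summary`
#'   (per-group mean/SD).
#' @export
compute_delta_age <- function(predicted, chronological, groups = NULL,
                              subject_ids = NULL) {
  n <- length(predicted)
  if (length(chronological) != n)
    stop("predicted and chronological must be aligned", call. = FALSE)
  if (anyNA(predicted) || anyNA(chronological))
    stop("subject missing a predicted or chronological age", call. = FALSE)
  if (is.null(groups)) groups <- rep("all", n)
  if (length(groups) != n)
    stop("groups must be aligned with the age vectors", call. = FALSE)
  if (is.null(subject_ids)) subject_ids <- names(predicted) %||%
      sprintf("S%04d", seq_len(n))

  tab <- data.frame(subject_id = as.character(subject_ids),
                    group = as.character(groups),
                    chronological = as.numeric(chronological),
                    predicted = as.numeric(predicted),
                    delta = as.numeric(predicted) - as.numeric(chronological),
                    stringsAsFactors = FALSE)
  sm <- do.call(rbind, lapply(split(tab, tab$group), function(g) {
    data.frame(group = g$group[1], n = nrow(g),
               chron_mean = mean(g$chronological), chron_sd = sd(g$chronological),
               pred_mean = mean(g$predicted), pred_sd = sd(g$predicted),
               delta_mean = mean(g$delta), delta_sd = sd(g$delta),
               stringsAsFactors = FALSE)
  }))
  rownames(sm) <- NULL
  structure(list(table = tab, summary = sm), class = "delta_age")
}

#' @export
print.delta_age <- function(x, ...) {
  cat("<delta_age>\n")
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("  %s (n = %d): chronological %.2f ± %.2f, predicted %.2f ± %.2f, delta %.2f ± %.2f years\n",
                s$group, s$n, s$chron_mean, s$chron_sd,
                s$pred_mean, s$pred_sd, s$delta_mean, s$delta_sd))
  }
  invisible(x)
}

#' Compare delta age between two groups
#'
#' Two-sided Wilcoxon test on the per-subject delta ages: the two-sample
#' rank-sum test by default (the groups are independent samples), or the
#' paired signed-rank test (requires equal group sizes; subjects are paired
#' by their order within each group). Exact p-values are used when the
#' combined sample size is at most 25 and there are no ties; otherwise the
#' normal approximation with continuity correction (and mid-rank tie
#' handling) applies.
#'
#' @param delta a `delta_age` from [compute_delta_age()] with exactly two
#'   groups.
#' @param test `"rank_sum"` (default) or `"signed_rank"`.
#' @return A `group_comparison` list: `statistic`, `p_value`, `test`,
#'   `groups`, `ns`, `pred_mean_diff` (difference of group mean predicted
#'   ages, years), `delta_mean_diff`.
#' @export
compare_groups <- function(delta, test = c("rank_sum", "signed_rank")) {
  stopifnot(inherits(delta, "delta_age"))
  test <- match.arg(test)
  grp <- unique(delta$table$group)
  if (length(grp) != 2L)
    stop("exactly two groups are required", call. = FALSE)
  x <- delta$table$delta[delta$table$group == grp[1]]
  y <- delta$table$delta[delta$table$group == grp[2]]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 subjects", call. = FALSE)

  if (test == "signed_rank") {
    if (length(x) != length(y))
      stop(paste("signed_rank pairs subjects by order and requires equal",
                 "group sizes; use test = 'rank_sum' for independent groups"),
           call. = FALSE)
    ties <- anyDuplicated(abs(x - y)) > 0 || any(x == y)
    exact <- (2L * length(x) <= 25L) && !ties
    wt <- suppressWarnings(
      wilcox.test(x, y, paired = TRUE, exact = exact, correct = TRUE))
    name <- "Wilcoxon signed-rank"
  } else {
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- (length(x) + length(y) <= 25L) && !ties
    wt <- suppressWarnings(
      wilcox.test(x, y, exact = exact, correct = TRUE))
    name <- "Wilcoxon rank-sum"
  }
  sm <- delta$summary
  pm <- stats::setNames(sm$pred_mean, sm$group)
  dm <- stats::setNames(sm$delta_mean, sm$group)
  structure(list(statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 test = name, exact = exact,
                 groups = grp,
                 ns = c(length(x), length(y)),
                 pred_mean_diff = unname(pm[grp[1]] - pm[grp[2]]),
                 delta_mean_diff = unname(dm[grp[1]] - dm[grp[2]])),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s test (%s): %s vs %s (n = %d, %d)\n", x$test,
              if (x$exact) "exact" else "normal approximation",
              x$groups[1], x$groups[2], x$ns[1], x$ns[2]))
  cat(sprintf("  statistic = %g, p = %.3g\n", x$statistic, x$p_value))
  cat(sprintf("  difference of mean predicted ages = %.2f years\n",
              x$pred_mean_diff))
  invisible(x)
}
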