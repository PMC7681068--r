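#' Resolve pathway members to panel analytes
#'
#' Matches each pathway's members against the panel by analyte id, gene
#' symbol, or protein id (in that order of precedence). A gene covered by
#' several analytes resolves to the first annotation listed; unmapped
#' members are dropped and counted.
#'
#' @param collection a `pathway_collection`.
#' @param analyte_meta analyte annotation table with `analyte_id` and
#'   optionally `gene_symbol`, `protein_id`.
#' @return Named list of analyte-id vectors; the total number of dropped
#'   members is in the `n_unmapped` attribute.
#' @export
resolve_pathways <- function(collection, analyte_meta) {
  stopifnot(inherits(collection, "pathway_collection"))
  by_id <- analyte_meta$analyte_id
  # first annotation wins for duplicated symbols/proteins
  gene_map <- if (!is.null(analyte_meta$gene_symbol)) {
    keep <- !duplicated(analyte_meta$gene_symbol)
    stats::setNames(analyte_meta$analyte_id[keep], analyte_meta$gene_symbol[keep])
  } else stats::setNames(character(0), character(0))
  prot_map <- if (!is.null(analyte_meta$protein_id)) {
    keep <- !duplicated(analyte_meta$protein_id)
    stats::setNames(analyte_meta$analyte_id[keep], analyte_meta$protein_id[keep])
  } else stats::setNames(character(0), character(0))
  n_unmapped <- 0L
  out <- lapply(collection, function(e) {
    m <- e$members
    resolved <- ifelse(m %in% by_id, m,
                ifelse(m %in% names(gene_map), unname(gene_map[m]),
                ifelse(m %in% names(prot_map), unname(prot_map[m]),
                       NA_character_)))
    n_unmapped <<- n_unmapped + sum(is.na(resolved))
    unique(resolved[!is.na(resolved)])
  })
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Screen pathway-restricted aging clocks
#'
#' Builds, for every pathway with at least `min_analytes` mapped analytes, a
#' ridge and a LASSO clock restricted to that pathway's analytes, reusing a
#' single shared train/test split for comparability, and reports train/test
#' Pearson r and median absolute error for both fits plus the LASSO active
#' set size. Pathways below the analyte threshold are excluded (and
#' counted); a pathway whose fit fails is marked failed rather than aborting
#' the screen.
#'
#' @param cohort a [proteomic_cohort()].
#' @param collection a `pathway_collection` (members may be analyte ids,
#'   gene symbols, or protein ids).
#' @param min_analytes minimum mapped analytes to retain a pathway
#'   (default 2).
#' @param split optional [split_train_test()] to reuse; built from `seed`
#'   when missing.
#' @param fraction,seed,n_lambda,n_folds passed to [train_clock()].
#' @return A `pathway_screen` data.frame with one row per retained pathway:
#'   `pathway_id`, `n_analytes`, `n_sparse` (LASSO active set),
#'   `ridge_train_r`, `ridge_train_mae`, `ridge_test_r`, `ridge_test_mae`,
#'   the four `lasso_*` counterparts, and `failed`. Excluded pathways are
#'   recorded in the `excluded` attribute.
#' @export
screen_pathways <- function(cohort, collection, min_analytes = 2,
                            split = NULL, fraction = 2/3, seed = 1,
                            n_lambda = 100, n_folds = 10) {
  stopifnot(inherits(cohort, "proteomic_cohort"),
            inherits(collection, "pathway_collection"))
  min_analytes <- check_count(min_analytes, "min_analytes", min = 1L)
  resolved <- resolve_pathways(collection, cohort$analytes)
  sizes <- lengths(resolved)
  keep <- sizes >= min_analytes
  excluded <- data.frame(pathway_id = names(resolved)[!keep],
                         n_mapped = unname(sizes[!keep]),
                         stringsAsFactors = FALSE)
  if (nrow(excluded))
    message(sprintf("excluding %d pathway(s) with fewer than %d mapped analytes",
                    nrow(excluded), min_analytes))
  if (is.null(split)) split <- split_train_test(cohort, fraction, seed)

  ids <- names(resolved)[keep]
  rows <- lapply(ids, function(pid) {
    feats <- resolved[[pid]]
    res <- tryCatch({
      ridge <- train_clock(cohort, features = feats, alpha = 0, split = split,
                           seed = seed, n_lambda = n_lambda, n_folds = n_folds)
      lasso <- train_clock(cohort, features = feats, alpha = 1, split = split,
                           seed = seed, n_lambda = n_lambda, n_folds = n_folds)
      data.frame(pathway_id = pid, n_analytes = length(feats),
                 n_sparse = sum(lasso$beta != 0),
                 ridge_train_r = ridge$evaluation$train$r,
                 ridge_train_mae = ridge$evaluation$train$mae,
                 ridge_test_r = ridge$evaluation$test$r,
                 ridge_test_mae = ridge$evaluation$test$mae,
                 lasso_train_r = lasso$evaluation$train$r,
                 lasso_train_mae = lasso$evaluation$train$mae,
                 lasso_test_r = lasso$evaluation$test$r,
                 lasso_test_mae = lasso$evaluation$test$mae,
                 failed = FALSE, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(pathway_id = pid, n_analytes = length(feats),
                 n_sparse = NA_integer_,
                 ridge_train_r = NA_real_, ridge_train_mae = NA_real_,
                 ridge_test_r = NA_real_, ridge_test_mae = NA_real_,
                 lasso_train_r = NA_real_, lasso_train_mae = NA_real_,
                 lasso_test_r = NA_real_, lasso_test_mae = NA_real_,
                 failed = TRUE, stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(pathway_id = character(), n_analytes = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "split") <- split
  class(out) <- c("pathway_screen", "data.frame")
  out
}

#' Rank screened pathway clocks
#'
#' Stable sort by held-out performance: descending Pearson r or ascending
#' median absolute error; ties are broken by fewer analytes, then pathway
#' id.
#'
#' @param results a `pathway_screen` from [screen_pathways()].
#' @param by `"test_r"` or `"test_mae"`.
#' @param model `"ridge"` or `"lasso"` evaluations to rank on.
#' @param top_k report at most this many pathways (default all).
#' @return The reordered (and possibly truncated) data.frame.
#' @export
rank_clocks <- function(results, by = c("test_r", "test_mae"),
                        model = c("ridge", "lasso"), top_k = Inf) {
  by <- match.arg(by)
  model <- match.arg(model)
  if (nrow(results) == 0L) stop("no results to rank", call. = FALSE)
  col <- paste0(model, "_", by)
  key <- results[[col]]
  ord <- if (by == "test_r")
    order(-key, results$n_analytes, results$pathway_id, na.last = TRUE)
  else
    order(key, results$n_analytes, results$pathway_id, na.last = TRUE)
  out <- results[ord, , drop = FALSE]
  rownames(out) <- NULL
  head(out, n = if (is.finite(top_k)) top_k else nrow(out))
}
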