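#' Write a cohort to CSV files
#'
#' Writes the intensity matrix (subjects in rows, first column `subject_id`),
#' the subject metadata, the analyte metadata, and optionally the ground
#' truth to four CSV files sharing a prefix.
#'
#' @param cohort a [proteomic_cohort()].
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @param truth optional `cohort_truth` to write alongside.
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort_table <- function(cohort, dir, prefix = "cohort", truth = NULL) {
  stopifnot(inherits(cohort, "proteomic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, paste0(prefix, "_matrix.csv")),
             subjects = file.path(dir, paste0(prefix, "_subjects.csv")),
             analytes = file.path(dir, paste0(prefix, "_analytes.csv")))
  m <- data.table::as.data.table(cohort$intensities, keep.rownames = "subject_id")
  data.table::fwrite(m, paths[["matrix"]])
  data.table::fwrite(cohort$subjects, paths[["subjects"]])
  data.table::fwrite(cohort$analytes, paths[["analytes"]])
  if (!is.null(truth)) {
    paths <- c(paths, truth = file.path(dir, paste0(prefix, "_truth.csv")))
    data.table::fwrite(as.data.frame(truth), paths[["truth"]])
  }
  invisible(paths)
}

#' Read a cohort from CSV/TSV files
#'
#' Rebuilds a validated [proteomic_cohort()] from the three tables written by
#' [write_cohort_table()]. Subjects and analytes are aligned by explicit IDs,
#' never by position; duplicated IDs, ID-set mismatches and non-positive
#' intensities are rejected with named errors. The delimiter is inferred from
#' the file contents (CSV and TSV both work).
#'
#' @param matrix_path path to the intensity table (first column subject ids).
#' @param subjects_path path to the subject metadata table.
#' @param analytes_path path to the analyte metadata table.
#' @return A [proteomic_cohort()].
#' @export
read_cohort_table <- function(matrix_path, subjects_path, analytes_path) {
  for (f in c(matrix_path, subjects_path, analytes_path))
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  m <- data.table::fread(matrix_path, header = TRUE, data.table = FALSE)
  subjects <- data.table::fread(subjects_path, header = TRUE, data.table = FALSE)
  analytes <- data.table::fread(analytes_path, header = TRUE, data.table = FALSE)

  sid <- as.character(m[[1]])
  if (anyDuplicated(sid))
    stop("duplicate subject id in intensity matrix", call. = FALSE)
  a_ids <- colnames(m)[-1]
  if (anyDuplicated(a_ids))
    stop("duplicate analyte id in intensity matrix", call. = FALSE)

  subjects$subject_id <- as.character(subjects$subject_id)
  analytes$analyte_id <- as.character(analytes$analyte_id)
  if (!setequal(sid, subjects$subject_id))
    stop("subject id mismatch between matrix and subject metadata",
         call. = FALSE)
  if (!setequal(a_ids, analytes$analyte_id))
    stop("analyte id mismatch between matrix and analyte metadata",
         call. = FALSE)

  intens <- as.matrix(m[, -1, drop = FALSE])
  rownames(intens) <- sid
  # align metadata to matrix order via IDs
  subjects <- subjects[match(sid, subjects$subject_id), , drop = FALSE]
  analytes <- analytes[match(a_ids, analytes$analyte_id), , drop = FALSE]
  rownames(subjects) <- rownames(analytes) <- NULL
  proteomic_cohort(intens, subjects, analytes)
}

# pathway collections --------------------------------------------------------

new_pathway_collection <- function(entries) {
  if (anyDuplicated(names(entries)))
    stop("duplicate pathway id", call. = FALSE)
  structure(entries, class = "pathway_collection")
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member ids. Blank lines are skipped, duplicate members within a line
#' are collapsed, and a line with fewer than three fields is a parse error
#' reporting the line number.
#'
#' @param path path to a GMT file.
#' @return A `pathway_collection`: a named list of
#'   `list(description, members)` entries.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  entries <- list()
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("GMT parse error at line %d: fewer than 3 tab-separated fields", i),
           call. = FALSE)
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L)
      stop(sprintf("GMT parse error at line %d: empty member list", i),
           call. = FALSE)
    entries[[f[1]]] <- list(description = f[2], members = members)
  }
  new_pathway_collection(entries)
}

#' Write a pathway collection to GMT
#'
#' @param collection a `pathway_collection`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "pathway_collection"))
  lines <- vapply(names(collection), function(nm) {
    e <- collection[[nm]]
    paste(c(nm, e$description, e$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.pathway_collection <- function(x, ...) {
  sz <- vapply(x, function(e) length(e$members), integer(1))
  cat(sprintf("<pathway_collection> %d sets, sizes %d-%d (median %g)\n",
              length(x), if (length(sz)) min(sz) else 0L,
              if (length(sz)) max(sz) else 0L, median(sz)))
  invisible(x)
}

# clock serialization ---------------------------------------------------------

CLOCK_SCHEMA_VERSION <- "1.0"

#' Serialize a fitted aging clock to JSON
#'
#' Stores everything needed to predict on new data: mixing parameter, the
#' selected penalty, intercept, per-analyte weights on the standardized
#' scale, and the per-analyte log10 means/SDs used for standardization.
#' Round-trips are lossless: predictions from a reloaded clock match the
#' original to better than 1e-12.
#'
#' @param model an `aging_clock` (see [train_clock()]).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_clock_model <- function(model, path) {
  stopifnot(inherits(model, "aging_clock"))
  obj <- list(
    schema_version = CLOCK_SCHEMA_VERSION,
    alpha = model$alpha,
    lambda = model$lambda,
    intercept = model$intercept,
    coefficients = as.list(model$beta),
    standardization = list(
      analyte_id = model$standardization$analyte_id,
      mean = model$standardization$mean,
      sd = model$standardization$sd),
    training = model$training %||% list())
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized aging clock
#'
#' Validates the schema version and the model invariants (coefficient and
#' standardization maps over the same analytes, strictly positive SDs)
#' before rebuilding a predict-ready `aging_clock`.
#'
#' @param path path to a JSON file written by [write_clock_model()].
#' @return An `aging_clock`.
#' @export
read_clock_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) ||
      !identical(as.character(obj$schema_version), CLOCK_SCHEMA_VERSION))
    stop(sprintf("clock schema_version mismatch: found '%s', expected '%s'",
                 obj$schema_version %||% "<missing>", CLOCK_SCHEMA_VERSION),
         call. = FALSE)
  beta <- unlist(obj$coefficients)
  std <- data.frame(analyte_id = as.character(obj$standardization$analyte_id),
                    mean = as.numeric(obj$standardization$mean),
                    sd = as.numeric(obj$standardization$sd),
                    stringsAsFactors = FALSE)
  if (!setequal(names(beta), std$analyte_id))
    stop("coefficient and standardization maps cover different analytes",
         call. = FALSE)
  if (any(!is.finite(std$sd)) || any(std$sd <= 0))
    stop("invalid standardization: sd values must be > 0", call. = FALSE)
  if (any(!is.finite(beta)))
    stop("invalid coefficients: weights must be finite", call. = FALSE)
  new_aging_clock(alpha = obj$alpha, lambda = obj$lambda,
                  intercept = obj$intercept,
                  beta = beta[std$analyte_id],
                  standardization = std,
                  training = obj$training)
}
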