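#' Hypergeometric overrepresentation analysis
#'
#' For each pathway, tests whether the query set overlaps the pathway more
#' than expected under random draws from the background universe:
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)` with background size
#' `N`, pathway size `K` (after intersection with the background), and query
#' size `n`. One-sided upper tail only (overrepresentation). FDR is
#' Benjamini-Hochberg across all tested pathways.
#'
#' The background defaults to the analysis universe actually measured (the
#' panel), not all protein-coding genes; pass a wider `background`
#' explicitly if appropriate.
#'
#' @param query character vector of ids (must be a subset of `background`).
#' @param background character vector: the universe of ids.
#' @param collection a `pathway_collection`; members are intersected with
#'   the background, and pathways with no background member are skipped.
#' @return An `enrichment_result` data.frame sorted by FDR then p-value then
#'   pathway id: `pathway_id`, `overlap` (k), `query_size` (n),
#'   `pathway_size` (K), `background_size` (N), `p_value`, `fdr`,
#'   `overlap_ids` (semicolon-separated).
#' @export
overrepresentation_test <- function(query, background, collection) {
  stopifnot(inherits(collection, "pathway_collection"))
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  offenders <- setdiff(query, background)
  if (length(offenders))
    stop("query ids missing from background: ",
         paste(head(offenders, 5), collapse = ", "),
         if (length(offenders) > 5) sprintf(" (and %d more)", length(offenders) - 5),
         call. = FALSE)
  N <- length(background)
  n <- length(query)

  rows <- lapply(names(collection), function(pid) {
    members <- intersect(collection[[pid]]$members, background)
    K <- length(members)
    if (K == 0L) return(NULL)
    hits <- intersect(query, members)
    k <- length(hits)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway_id = pid, overlap = k, query_size = n,
               pathway_size = K, background_size = N,
               p_value = p, fdr = NA_real_,
               overlap_ids = paste(sort(hits), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no pathway has members in the background", call. = FALSE)
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out <- out[order(out$fdr, out$p_value, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}
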