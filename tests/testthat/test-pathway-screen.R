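test_that("pathway members resolve by analyte id, gene symbol, or protein id", {
  meta <- data.frame(analyte_id = c("SOMA.1", "SOMA.2", "SOMA.3"),
                     protein_id = c("P1", "P2", "P2"),
                     gene_symbol = c("GA", "GB", "GB"),
                     stringsAsFactors = FALSE)
  coll <- structure(list(
    pw1 = list(description = "", members = c("SOMA.1", "GB", "unknown")),
    pw2 = list(description = "", members = c("P2", "GA"))),
    class = "pathway_collection")
  r <- resolve_pathways(coll, meta)
  # duplicated gene symbol resolves to the first annotation listed
  expect_identical(r$pw1, c("SOMA.1", "SOMA.2"))
  expect_identical(sort(r$pw2), c("SOMA.1", "SOMA.2"))
  expect_equal(attr(r, "n_unmapped"), 1L)
})

test_that("screen excludes sub-threshold pathways and finds the enriched set first", {
  g <- generate_cohort(cohort_spec(n_subjects = 300, n_analytes = 200,
                                   frac_informative = 0.25, seed = 41))
  ids <- analyte_ids(g$cohort)
  inf <- g$truth$analyte_id[g$truth$informative]
  nullish <- setdiff(ids, inf)
  set.seed(41)
  coll <- structure(list(
    tiny1 = list(description = "", members = ids[1]),
    tiny2 = list(description = "", members = nullish[2]),
    enriched = list(description = "", members = sample(inf, 15)),
    rand1 = list(description = "", members = sample(nullish, 12)),
    rand2 = list(description = "", members = sample(nullish, 10))),
    class = "pathway_collection")

  expect_message(
    res <- screen_pathways(g$cohort, coll, min_analytes = 2, seed = 41,
                           n_lambda = 40),
    "excluding 2")
  expect_equal(nrow(res), 3L)
  expect_identical(attr(res, "excluded")$pathway_id, c("tiny1", "tiny2"))
  expect_true(all(res$n_sparse <= res$n_analytes))

  ranked <- rank_clocks(res, by = "test_r", model = "ridge")
  expect_identical(ranked$pathway_id[1], "enriched")
  ranked_mae <- rank_clocks(res, by = "test_mae", model = "ridge")
  expect_identical(ranked_mae$pathway_id[1], "enriched")

  # determinism given (cohort, collection, seed)
  res2 <- suppressMessages(
    screen_pathways(g$cohort, coll, min_analytes = 2, seed = 41,
                    n_lambda = 40))
  expect_equal(res, res2, ignore_attr = TRUE)
})

test_that("ranking breaks ties by analyte count then pathway id, and honours top_k", {
  res <- data.frame(pathway_id = c("b", "a", "c"),
                    n_analytes = c(10, 5, 5),
                    n_sparse = c(3, 2, 2),
                    ridge_test_r = c(0.8, 0.8, 0.8),
                    ridge_test_mae = c(4, 5, 6),
                    stringsAsFactors = FALSE)
  class(res) <- c("pathway_screen", "data.frame")
  ranked <- rank_clocks(res, by = "test_r", model = "ridge")
  expect_identical(ranked$pathway_id, c("a", "c", "b"))
  expect_equal(nrow(rank_clocks(res, by = "test_r", top_k = 2)), 2L)
  expect_equal(nrow(rank_clocks(res, by = "test_r", top_k = 10)), 3L)
  expect_error(rank_clocks(res[0, ], by = "test_r"), "no results")
})

test_that("clocks on purely non-informative pathways have near-zero held-out r", {
  rs <- vapply(1:10, function(s) {
    g <- generate_cohort(cohort_spec(n_subjects = 250, n_analytes = 60,
                                     frac_informative = 0.2, seed = 200 + s))
    nullish <- g$truth$analyte_id[!g$truth$informative]
    set.seed(s)
    ck <- train_clock(g$cohort, features = sample(nullish, 10), alpha = 0,
                      seed = s, n_lambda = 30)
    ck$evaluation$test$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("the all-analyte clock is not much worse than the best pathway clock", {
  diffs <- vapply(1:3, function(s) {
    g <- generate_cohort(cohort_spec(n_subjects = 250, n_analytes = 120,
                                     frac_informative = 0.3, seed = 300 + s))
    coll <- generate_pathway_collection(g$cohort$analytes, g$truth,
                                        n_pathways = 4, size_range = c(10, 25),
                                        n_enriched = 2, seed = s)
    res <- suppressMessages(
      screen_pathways(g$cohort, coll, seed = s, n_lambda = 30))
    all_ck <- train_clock(g$cohort, alpha = 0, seed = s, n_lambda = 30)
    all_ck$evaluation$test$r - max(res$ridge_test_r)
  }, numeric(1))
  expect_gt(mean(diffs), -0.05)
})
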