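test_that("spec validation names the offending field", {
  expect_error(cohort_spec(n_subjects = -1), "n_subjects")
  expect_error(cohort_spec(age_range = c(76, 18)), "age_range")
  expect_error(cohort_spec(frac_informative = 1.2), "frac_informative")
  expect_error(cohort_spec(beta_range = c(-1, 2)), "beta_range")
  expect_error(cohort_spec(noise_sd = -0.1), "noise_sd")
})

test_that("noise-free informative analytes lie exactly on the age line", {
  g <- generate_cohort(cohort_spec(n_subjects = 50, n_analytes = 10,
                                   frac_informative = 0.1, noise_sd = 0,
                                   sex_effect_sd = 0, seed = 3))
  truth <- g$truth
  inf <- which(truth$informative)
  expect_length(inf, 1L)
  ages <- g$cohort$subjects$age
  lg <- log10(g$cohort$intensities[, inf])
  expected <- truth$mu[inf] + truth$true_beta[inf] * (ages - attr(truth, "age_center"))
  expect_equal(lg, expected, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("generation is bit-identical given the seed and respects the rounding rule", {
  sp <- tiny_spec(seed = 5)
  g1 <- generate_cohort(sp)
  g2 <- generate_cohort(sp)
  expect_identical(g1$cohort$intensities, g2$cohort$intensities)
  expect_identical(g1$truth$true_beta, g2$truth$true_beta)

  g3 <- generate_cohort(cohort_spec(n_subjects = 30, n_analytes = 3000,
                                    frac_informative = 0.15, seed = 2))
  expect_identical(sum(g3$truth$informative), 450L)
})

test_that("informative directions follow frac_increasing and betas stay in range", {
  g <- generate_cohort(cohort_spec(n_subjects = 10, n_analytes = 1000,
                                   frac_informative = 0.4,
                                   frac_increasing = 0.75, seed = 8))
  tr <- g$truth
  inf <- tr$informative
  expect_equal(sum(tr$true_beta[inf] > 0), round(0.75 * sum(inf)))
  mag <- abs(tr$true_beta[inf])
  expect_true(all(mag >= 3.24e-4 & mag <= 1.64e-2))
  expect_true(all(tr$true_beta[!inf] == 0))
  expect_identical(tr$direction, sign(tr$true_beta))
})

test_that("ages respect the declared range for both sampling modes", {
  for (dist in c("uniform", "triangular")) {
    g <- generate_cohort(cohort_spec(n_subjects = 500, n_analytes = 5,
                                     age_dist = dist, seed = 4))
    a <- g$cohort$subjects$age
    expect_true(all(a >= 18 & a <= 76))
  }
  # triangular option pulls the median towards the target
  g <- generate_cohort(cohort_spec(n_subjects = 4000, n_analytes = 2,
                                   age_dist = "triangular", seed = 4))
  expect_lt(abs(median(g$cohort$subjects$age) - 45), 1.5)
})

test_that("aging shift is the identity at 0 and matches a 10-year-older subject when noise-free", {
  g <- generate_cohort(cohort_spec(n_subjects = 40, n_analytes = 20,
                                   frac_informative = 0.5, noise_sd = 0,
                                   sex_effect_sd = 0, seed = 6))
  ids <- g$cohort$subjects$subject_id[1:5]
  same <- inject_aging_shift(g$cohort, g$truth, ids, 0)
  expect_equal(same$intensities, g$cohort$intensities)

  shifted <- inject_aging_shift(g$cohort, g$truth, ids[1], 10)
  age1 <- g$cohort$subjects$age[1]
  lg_shift <- log10(shifted$intensities[1, ])
  expected <- g$truth$mu + g$truth$true_beta *
    (age1 + 10 - attr(g$truth, "age_center"))
  expect_equal(unname(lg_shift), expected, tolerance = 1e-12)

  expect_error(inject_aging_shift(g$cohort, g$truth, "nope", 1),
               "unknown subject")
})

test_that("platform mask keeps requested columns in cohort order and is idempotent", {
  g <- tiny_cohort(p = 30)
  keep <- sample(analyte_ids(g$cohort), 12)
  m1 <- apply_platform_mask(g$cohort, keep)
  expect_equal(ncol(m1$intensities), 12L)
  expect_identical(colnames(m1$intensities),
                   intersect(analyte_ids(g$cohort), keep))
  m2 <- apply_platform_mask(m1, analyte_ids(g$cohort)[analyte_ids(g$cohort) %in% keep])
  expect_identical(m1, m2)
  expect_identical(apply_platform_mask(g$cohort, analyte_ids(g$cohort)), g$cohort)
  expect_error(apply_platform_mask(g$cohort, character(0)), "non-empty")
  expect_error(apply_platform_mask(g$cohort, "missing"), "unknown analyte")
})

test_that("shift-then-mask commutes with mask-then-shift", {
  g <- tiny_cohort(p = 25, seed = 9)
  keep <- analyte_ids(g$cohort)[c(2, 5, 8, 20)]
  ids <- g$cohort$subjects$subject_id[1:10]
  a <- apply_platform_mask(inject_aging_shift(g$cohort, g$truth, ids, 6), keep)
  b <- inject_aging_shift(apply_platform_mask(g$cohort, keep), g$truth, ids, 6)
  expect_equal(a$intensities, b$intensities)
})

test_that("reusing ground truth yields an independent cohort from the same process", {
  sp <- tiny_spec(seed = 21)
  g1 <- generate_cohort(sp)
  sp2 <- tiny_spec(seed = 22)
  g2 <- generate_cohort(sp2, truth = g1$truth)
  expect_identical(g2$truth, g1$truth)
  expect_identical(colnames(g2$cohort$intensities), colnames(g1$cohort$intensities))
  expect_false(isTRUE(all.equal(g1$cohort$intensities, g2$cohort$intensities)))
})

test_that("pathway collection sizes stay within bounds and enrichment biases membership", {
  g <- generate_cohort(cohort_spec(n_subjects = 10, n_analytes = 300,
                                   frac_informative = 0.2, seed = 13))
  pc <- generate_pathway_collection(g$cohort$analytes, g$truth,
                                    n_pathways = 20, size_range = c(4, 15),
                                    n_enriched = 0, seed = 1)
  sz <- vapply(pc, function(e) length(e$members), integer(1))
  expect_true(all(sz >= 4 & sz <= 15))
  expect_error(generate_pathway_collection(g$cohort$analytes, g$truth,
                                           size_range = c(1, 400)),
               "size_range")

  # enriched sets carry more informative analytes than the collection average
  inf_ids <- g$truth$analyte_id[g$truth$informative]
  frac_inf <- function(members) mean(members %in% inf_ids)
  diffs <- vapply(1:100, function(s) {
    pc <- generate_pathway_collection(g$cohort$analytes, g$truth,
                                      n_pathways = 10, size_range = c(8, 20),
                                      n_enriched = 1, seed = s)
    fr <- vapply(pc, function(e) frac_inf(e$members), numeric(1))
    fr[attr(pc, "enriched")] - mean(fr)
  }, numeric(1))
  expect_gt(mean(diffs), 0.3)
})
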