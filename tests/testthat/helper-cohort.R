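subject_ids_of <- function(cohort) cohort$subjects$subject_id

withr_like_tempdir <- function() {
  d <- tempfile("proteoclock-test-")
  dir.create(d)
  d
}

# small cohort factory used across tests
tiny_spec <- function(n = 120, p = 40, seed = 11, ...) {
  cohort_spec(n_subjects = n, n_analytes = p, seed = seed, ...)
}

tiny_cohort <- function(...) generate_cohort(tiny_spec(...))

# independent Benjamini-Hochberg oracle: brute-force step-up
# q_(i) = min_{j >= i} m * p_(j) / j, clipped at 1
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(m * ps[i:m] / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# elastic-net objective (1/2n)||y - b0 - Zb||^2 + lam[(1-a)/2 ||b||_2^2 + a||b||_1]
enet_objective <- function(z, y, beta, intercept, alpha, lambda) {
  r <- y - intercept - drop(z %*% beta)
  sum(r^2) / (2 * length(y)) +
    lambda * ((1 - alpha) / 2 * sum(beta^2) + alpha * sum(abs(beta)))
}

# KKT stationarity residual for an elastic-net solution (0 if exact)
enet_kkt_violation <- function(z, y, beta, intercept, alpha, lambda) {
  n <- length(y)
  r <- y - intercept - drop(z %*% beta)
  g <- drop(crossprod(z, r)) / n
  active <- beta != 0
  v_active <- if (any(active))
    max(abs(g[active] - (1 - alpha) * lambda * beta[active] -
              alpha * lambda * sign(beta[active]))) else 0
  v_inactive <- if (any(!active))
    max(0, max(abs(g[!active])) - alpha * lambda) else 0
  max(v_active, v_inactive)
}

# exhaustive enumeration oracle: over all C(N, n) query draws, the fraction
# with overlap >= k against a fixed pathway of size K
hyper_enum_oracle <- function(N, K, n, k) {
  bg <- seq_len(N)
  pw <- seq_len(K)
  draws <- combn(N, n)
  mean(apply(draws, 2, function(q) sum(q %in% pw) >= k))
}

# A noise-free two-feature toy: both analytes track age exactly on the z
# scale, the clock weights them equally, so restricting prediction to one
# feature halves all deviations from the mean prediction.
halved_toy <- function() {
  n <- 20
  ages <- seq(20, 70, length.out = n)
  zvals <- (ages - mean(ages)) / sd(ages)
  intens <- 10^cbind(A1 = 3 + 0.1 * zvals, A2 = 2 + 0.2 * zvals)
  rownames(intens) <- sprintf("S%02d", seq_len(n))
  cohort <- proteomic_cohort(
    intens,
    data.frame(subject_id = rownames(intens), age = ages),
    data.frame(analyte_id = c("A1", "A2")))
  std <- data.frame(analyte_id = c("A1", "A2"),
                    mean = c(3, 2), sd = c(0.1, 0.2),
                    stringsAsFactors = FALSE)
  w <- sd(ages) / 2
  clock <- proteoclock:::new_aging_clock(
    alpha = 0, lambda = 0, intercept = mean(ages),
    beta = c(A1 = w, A2 = w), standardization = std)
  list(cohort = cohort, clock = clock, ages = ages)
}

# shrinking-grid minimizer of the 3-predictor elastic-net objective;
# independent of the coordinate-descent path
lasso_grid_oracle <- function(z, y, alpha, lambda, n_iter = 60) {
  p <- ncol(z)
  stopifnot(p == 3)
  obj <- function(b) {
    b0 <- mean(y - drop(z %*% b))
    enet_objective(z, y, b, b0, alpha, lambda)
  }
  center <- rep(0, p)
  width <- max(abs(crossprod(z, y)) / nrow(z)) + 1
  offsets <- seq(-1, 1, length.out = 7)
  grid_idx <- as.matrix(expand.grid(offsets, offsets, offsets))
  for (it in seq_len(n_iter)) {
    cand <- sweep(grid_idx * width, 2, center, "+")
    vals <- apply(cand, 1, obj)
    center <- cand[which.min(vals), ]
    width <- width * 0.6
  }
  center
}
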