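make_problem <- function(n, p, seed = 1, rho = 0) {
  set.seed(seed)
  z <- matrix(rnorm(n * p), n, p)
  if (rho > 0) z <- z + rho * rnorm(n)  # shared factor -> correlated columns
  colnames(z) <- paste0("V", seq_len(p))
  beta <- rnorm(p)
  y <- drop(z %*% beta) + rnorm(n)
  list(z = z, y = y)
}

ridge_closed_form <- function(z, y, lambda) {
  n <- nrow(z)
  zc <- scale(z, scale = FALSE)
  yc <- y - mean(y)
  solve(crossprod(zc) / n + lambda * diag(ncol(z)), crossprod(zc, yc) / n)
}

test_that("ridge solutions match the closed form along the path", {
  pr <- make_problem(5, 3, seed = 2)
  lam <- c(2, 0.5, 0.1, 0.01)
  fit <- enet_path(pr$z, pr$y, alpha = 0, lambda = lam, tol = 1e-10)
  for (k in seq_along(lam)) {
    expect_equal(unname(fit$beta[, k]),
                 unname(drop(ridge_closed_form(pr$z, pr$y, lam[k]))),
                 tolerance = 1e-6)
  }
})

test_that("ridge at vanishing penalty reproduces OLS when p < n", {
  pr <- make_problem(40, 5, seed = 3)
  fit <- enet_path(pr$z, pr$y, alpha = 0, lambda = c(1, 1e-8), tol = 1e-10)
  ols <- coef(lm(pr$y ~ pr$z))
  expect_equal(unname(fit$beta[, 2]), unname(ols[-1]), tolerance = 1e-6)
  expect_equal(fit$intercept[2], unname(ols[1]), tolerance = 1e-6)
})

test_that("LASSO is exactly null at and above the critical penalty", {
  pr <- make_problem(30, 6, seed = 4)
  zc <- scale(pr$z, scale = FALSE)
  yc <- pr$y - mean(pr$y)
  lmax <- max(abs(crossprod(zc, yc))) / nrow(zc)
  fit <- enet_path(pr$z, pr$y, alpha = 1, lambda = c(2 * lmax, lmax * 1.0001))
  expect_true(all(fit$beta == 0))
  fit2 <- enet_path(pr$z, pr$y, alpha = 1, lambda = lmax * 0.95)
  expect_gt(sum(fit2$beta != 0), 0)
})

test_that("solutions satisfy KKT stationarity for both penalties", {
  for (alpha in c(0, 1, 0.5)) {
    pr <- make_problem(60, 12, seed = 5 + alpha * 10, rho = 0.5)
    fit <- enet_path(pr$z, pr$y, alpha = alpha, n_lambda = 30, tol = 1e-9)
    for (k in c(1, 10, 20, 30)) {
      v <- enet_kkt_violation(pr$z, pr$y, fit$beta[, k], fit$intercept[k],
                              alpha, fit$lambda[k])
      expect_lt(v, 1e-6)
    }
  }
})

# glmnet is the independent cross-check for the LASSO path only: for pure
# ridge with user-supplied lambdas, glmnet's internal response scaling means
# its solution is not the minimizer of the textbook objective, so the ridge
# route is checked against the closed form above instead.
test_that("LASSO coefficient path matches glmnet on shared lambdas", {
  skip_if_not_installed("glmnet")
  pr <- make_problem(80, 15, seed = 6, rho = 0.3)
  fit <- enet_path(pr$z, pr$y, alpha = 1, n_lambda = 40, tol = 1e-10)
  gn <- glmnet::glmnet(pr$z, pr$y, alpha = 1, lambda = fit$lambda,
                       standardize = FALSE, thresh = 1e-12)
  expect_equal(unname(as.matrix(gn$beta)), unname(fit$beta),
               tolerance = 1e-4)
  expect_equal(unname(gn$a0), fit$intercept, tolerance = 1e-4)
})

test_that("penalty monotonically shrinks the coefficient norms", {
  pr <- make_problem(50, 10, seed = 7, rho = 0.4)
  ridge <- enet_path(pr$z, pr$y, alpha = 0, n_lambda = 50)
  l2 <- sqrt(colSums(ridge$beta^2))
  expect_true(all(diff(l2) >= -1e-8))  # descending lambda -> growing norm
  lasso <- enet_path(pr$z, pr$y, alpha = 1, n_lambda = 50)
  l1 <- colSums(abs(lasso$beta))
  expect_true(all(diff(l1) >= -1e-8))
})

test_that("cross-validated fit is deterministic and centers its predictions", {
  pr <- make_problem(100, 20, seed = 8)
  f1 <- fit_penalized_clock(pr$z, pr$y, alpha = 1, n_lambda = 30, seed = 3)
  f2 <- fit_penalized_clock(pr$z, pr$y, alpha = 1, n_lambda = 30, seed = 3)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$lambda, f2$lambda)
  # training-set mean of predictions equals the mean response
  expect_equal(mean(predict(f1, pr$z)), mean(pr$y), tolerance = 1e-8)
})

test_that("non-finite inputs are rejected", {
  pr <- make_problem(20, 4)
  pr$z[3, 2] <- NA
  expect_error(enet_path(pr$z, pr$y, alpha = 0), "finite")
})
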