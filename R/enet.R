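# lambda path: 100 log-spaced values from lambda_max down to
# lambda_max * ratio. For pure ridge (alpha = 0) lambda_max is unbounded, so
# the mixing parameter is floored at 0.001 when computing it (the dominant
# penalized-regression convention). Default ratio 1e-4 when n > p, 1e-2
# otherwise.
enet_lambda_path <- function(Zc, yc, alpha, n_lambda, lambda_min_ratio = NULL) {
  n <- nrow(Zc)
  p <- ncol(Zc)
  if (is.null(lambda_min_ratio))
    # the floored-mixing lambda_max for pure ridge sits three orders of
    # magnitude above the l1 scale, so the ridge path needs the deeper floor
    # regardless of the n/p regime; for alpha > 0 the usual convention holds
    lambda_min_ratio <- if (alpha == 0 || n > p) 1e-4 else 1e-2
  lmax <- max(abs(crossprod(Zc, yc))) / (n * max(alpha, 0.001))
  if (lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

# Closed-form ridge solutions for every lambda from one symmetric
# eigendecomposition, working on whichever Gram side is smaller:
#   n <= p: beta = Zc' (Zc Zc' + n lam I)^-1 yc     (push-through identity)
#   n  > p: beta = (Zc'Zc + n lam I)^-1 Zc' yc
ridge_eigen_path <- function(Zc, yc, lambda) {
  n <- nrow(Zc)
  p <- ncol(Zc)
  if (n <= p) {
    K <- tcrossprod(Zc)
    E <- eigen(K, symmetric = TRUE)
    w <- drop(crossprod(E$vectors, yc))
    # columns: w_i / (d_i + n*lam_k)
    A <- w / outer(pmax(E$values, 0), n * lambda, "+")
    crossprod(Zc, E$vectors %*% A)
  } else {
    G <- crossprod(Zc)
    E <- eigen(G, symmetric = TRUE)
    w <- drop(crossprod(E$vectors, crossprod(Zc, yc)))
    A <- w / outer(pmax(E$values, 0), n * lambda, "+")
    E$vectors %*% A
  }
}

#' Elastic-net coefficient path by cyclic coordinate descent
#'
#' Minimizes `(1/2n) sum (y - b0 - Z b)^2 + lambda * [(1-alpha)/2 ||b||_2^2 +
#' alpha ||b||_1]` along a descending lambda sequence with warm starts. The
#' intercept is unpenalized (handled by centering). Convergence is declared
#' when the largest coefficient change in a sweep falls below `tol`.
#'
#' This is the package's own solver; it underlies [fit_penalized_clock()]
#' and [train_clock()].
#'
#' @param z numeric predictor matrix (typically z-scaled log10 intensities).
#' @param y numeric response (age in years).
#' @param alpha elastic-net mixing: 0 = ridge, 1 = LASSO.
#' @param lambda optional descending penalty sequence; computed from the data
#'   when missing.
#' @param n_lambda path length when `lambda` is missing (default 100).
#' @param lambda_min_ratio smallest/largest path value; default 1e-4 when
#'   n > p, 1e-2 otherwise.
#' @param tol convergence tolerance on the maximum coefficient change
#'   (default 1e-7).
#' @param max_iter maximum coordinate-descent sweeps per lambda.
#' @return A list with `lambda` (the path), `beta` (p x n_lambda matrix),
#'   `intercept` (per-lambda), and `iters` (sweeps per lambda).
#' @export
enet_path <- function(z, y, alpha, lambda = NULL, n_lambda = 100,
                      lambda_min_ratio = NULL, tol = 1e-7,
                      max_iter = 100000L) {
  z <- as.matrix(z)
  if (!is.numeric(z) || !all(is.finite(z)))
    stop("non-finite values in predictor matrix", call. = FALSE)
  if (!is.numeric(y) || !all(is.finite(y)))
    stop("non-finite values in response", call. = FALSE)
  if (length(y) != nrow(z))
    stop("length(y) must equal nrow(z)", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]", call. = FALSE)

  xm <- colMeans(z)
  ym <- mean(y)
  Zc <- sweep(z, 2, xm, "-")
  yc <- y - ym
  if (is.null(lambda)) {
    lambda <- enet_lambda_path(Zc, yc, alpha, n_lambda, lambda_min_ratio)
  } else {
    lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  }
  if (alpha == 0) {
    # pure ridge: seed coordinate descent at the closed-form minimizer
    # (one symmetric eigendecomposition serves the whole path), then let
    # sweeps certify the fixed point at the stated tolerance
    init <- ridge_eigen_path(Zc, yc, lambda)
    res <- cd_enet_polish(Zc, yc, alpha, lambda, init, tol,
                          as.integer(max_iter))
  } else {
    res <- cd_enet_path(Zc, yc, alpha, lambda, tol, as.integer(max_iter))
  }
  beta <- res$beta
  rownames(beta) <- colnames(z)
  intercept <- ym - as.numeric(crossprod(xm, beta))
  list(lambda = lambda, beta = beta, intercept = intercept,
       iters = res$iters)
}

#' Fit a penalized age regression with cross-validated penalty selection
#'
#' Fits the elastic-net path (see [enet_path()]) on the full data, selects
#' the penalty by tenfold cross-validation under the `lambda.min` rule (the
#' path value minimizing mean CV squared error; among ties the larger, more
#' regularized lambda wins), and returns the model at that penalty. Fold
#' membership is a seeded permutation, so the fit is deterministic given the
#' seed.
#'
#' @inheritParams enet_path
#' @param ages numeric response (chronological age in years).
#' @param n_folds number of CV folds (default 10).
#' @param seed integer seed for fold assignment.
#' @return An object of class `penalized_fit`: selected `lambda`,
#'   `lambda_path`, `beta` (named, at the selected lambda), `intercept`,
#'   `beta_path`, `cvm` (mean CV squared error per lambda), `nonzero`, `n`.
#' @export
fit_penalized_clock <- function(z, ages, alpha = 0, n_lambda = 100,
                                lambda_min_ratio = NULL, n_folds = 10,
                                seed = 1, tol = 1e-7, max_iter = 100000L) {
  z <- as.matrix(z)
  n <- nrow(z)
  n_folds <- check_count(n_folds, "n_folds", min = 2L)
  if (n < n_folds)
    stop(sprintf("need at least %d subjects for %d-fold CV", n_folds, n_folds),
         call. = FALSE)

  full <- enet_path(z, ages, alpha, n_lambda = n_lambda,
                    lambda_min_ratio = lambda_min_ratio, tol = tol,
                    max_iter = max_iter)
  lambda <- full$lambda

  fold <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  sse <- numeric(length(lambda))
  fold_mse <- matrix(NA_real_, n_folds, length(lambda))
  for (k in seq_len(n_folds)) {
    hold <- fold == k
    fit_k <- enet_path(z[!hold, , drop = FALSE], ages[!hold], alpha,
                       lambda = lambda, tol = tol, max_iter = max_iter)
    pred <- z[hold, , drop = FALSE] %*% fit_k$beta +
      matrix(fit_k$intercept, sum(hold), length(lambda), byrow = TRUE)
    err2 <- (pred - ages[hold])^2
    sse <- sse + colSums(err2)
    fold_mse[k, ] <- colMeans(err2)
  }
  cvm <- sse / n
  i_min <- which.min(cvm)  # path is descending: first minimum = largest lambda

  beta <- full$beta[, i_min]
  names(beta) <- colnames(z)
  structure(list(alpha = alpha,
                 lambda = lambda[i_min],
                 lambda_path = lambda,
                 beta = beta,
                 intercept = full$intercept[i_min],
                 beta_path = full$beta,
                 intercept_path = full$intercept,
                 cvm = cvm,
                 cvsd = apply(fold_mse, 2, sd) / sqrt(n_folds),
                 nonzero = sum(beta != 0),
                 n = n, n_folds = n_folds, seed = seed),
            class = "penalized_fit")
}

#' @export
print.penalized_fit <- function(x, ...) {
  kind <- if (x$alpha == 0) "ridge" else if (x$alpha == 1) "LASSO"
          else sprintf("elastic net (alpha = %g)", x$alpha)
  cat(sprintf("<penalized_fit> %s, n = %d, p = %d\n", kind, x$n,
              length(x$beta)))
  cat(sprintf("  lambda.min = %.4g (%d-fold CV over %d values), %d nonzero weights\n",
              x$lambda, x$n_folds, length(x$lambda_path), x$nonzero))
  invisible(x)
}

#' @export
coef.penalized_fit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$beta)
}

#' @export
predict.penalized_fit <- function(object, newz, ...) {
  newz <- as.matrix(newz)
  drop(newz[, names(object$beta), drop = FALSE] %*% object$beta) +
    object$intercept
}
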