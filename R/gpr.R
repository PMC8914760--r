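#' Exponential-kernel Gaussian process regression
#'
#' The regression engine behind the blood-pressure estimator: a zero-mean
#' Gaussian process over standardized feature vectors with the exponential
#' covariance
#' \deqn{k(x_i, x_j) = \sigma_f^2 \exp\{-\|x_i - x_j\|^2 / \sigma_l\}}
#' and i.i.d. Gaussian observation noise of variance \eqn{\sigma_n^2}.
#' Hyperparameters are the log length scale \eqn{\theta_1 = \log\sigma_l},
#' log signal standard deviation \eqn{\theta_2 = \log\sigma_f} and the log
#' noise variance, fitted by multi-start bounded quasi-Newton maximization
#' of the log marginal likelihood.
#'
#' The default covariance uses the squared Euclidean distance over
#' \eqn{\sigma_l}; `distance = "euclidean"` switches to the conventional
#' exponential kernel \eqn{\sigma_f^2 \exp\{-\|x_i-x_j\|/\sigma_l\}}.
#' An automatic-relevance-determination variant (one length scale per
#' feature) is available via `ard = TRUE`.
#'
#' @name gpr
NULL

#' Kernel parameter container
#'
#' @param sigma_f signal standard deviation (> 0)
#' @param sigma_l characteristic length scale (> 0); a vector of one length
#'   scale per feature when `ard = TRUE`
#' @param sigma_n2 observation-noise variance (>= 0), in squared target units
#' @param distance `"squared"` (default) or `"euclidean"` distance form
#' @return an object of class `kernel_params` with fields `sigma_f`,
#'   `sigma_l`, `sigma_n2`, `theta1 = log(sigma_l)`, `theta2 = log(sigma_f)`
#'   and `distance`
#' @export
kernel_params <- function(sigma_f, sigma_l, sigma_n2 = 0,
                          distance = c("squared", "euclidean")) {
  distance <- match.arg(distance)
  if (!all(is.finite(sigma_f)) || any(sigma_f <= 0))
    stop("sigma_f must be finite and > 0")
  if (!all(is.finite(sigma_l)) || any(sigma_l <= 0))
    stop("sigma_l must be finite and > 0")
  if (!is.finite(sigma_n2) || sigma_n2 < 0)
    stop("sigma_n2 must be finite and >= 0")
  structure(list(sigma_f = sigma_f, sigma_l = sigma_l,
                 theta1 = log(sigma_l), theta2 = log(sigma_f),
                 sigma_n2 = sigma_n2, distance = distance),
            class = "kernel_params")
}

#' Evaluate the exponential kernel between two feature vectors
#'
#' @param xi,xj numeric vectors of equal length
#' @param params a [kernel_params()] object
#' @return the scalar covariance; equals `sigma_f^2` when `xi == xj`
#' @export
kernel_eval <- function(xi, xj, params) {
  if (length(xi) != length(xj))
    stop("xi and xj must have the same length")
  if (!all(is.finite(xi)) || !all(is.finite(xj)))
    stop("non-finite kernel inputs")
  d <- xi - xj
  sl <- params$sigma_l
  if (length(sl) > 1L && length(sl) != length(d))
    stop("ARD length-scale vector must match feature dimension")
  r2 <- sum(d * d / sl)
  expo <- if (params$distance == "squared") r2 else sqrt(sum(d * d)) / sl[1L]
  params$sigma_f^2 * exp(-expo)
}

## Dense kernel matrix between rows of A and rows of B (both standardized).
kernel_matrix <- function(A, B, params) {
  sl <- params$sigma_l
  p <- ncol(A)
  if (length(sl) == 1L) sl <- rep(sl, p)
  if (params$distance == "squared") {
    As <- sweep(A, 2L, sqrt(sl), "/")
    Bs <- sweep(B, 2L, sqrt(sl), "/")
    d2 <- outer(rowSums(As^2), rowSums(Bs^2), "+") - 2 * tcrossprod(As, Bs)
    d2[d2 < 0] <- 0
    params$sigma_f^2 * exp(-d2)
  } else {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    d2[d2 < 0] <- 0
    params$sigma_f^2 * exp(-sqrt(d2) / sl[1L])
  }
}

## Cholesky of K + sigma_n2 I with escalating jitter.  Returns list(L, jitter).
chol_with_jitter <- function(K, sigma_n2, jitter_max = 1e-4) {
  n <- nrow(K)
  Ky <- K + diag(sigma_n2, n)
  jit <- 1e-10 * sum(diag(K)) / n
  L <- tryCatch(chol(Ky), error = function(e) NULL)
  while (is.null(L)) {
    if (jit > jitter_max)
      stop("singular kernel matrix: factorization failed at maximum jitter")
    L <- tryCatch(chol(Ky + diag(jit, n)), error = function(e) NULL)
    if (is.null(L)) jit <- jit * 10
  }
  list(L = L, jitter = if (is.null(attr(L, "jit"))) jit else jit)
}

#' Log marginal likelihood of a training set under fixed hyperparameters
#'
#' Computes \eqn{-\tfrac12 y^\top (K+\sigma_n^2 I)^{-1} y
#'   - \tfrac12 \log|K+\sigma_n^2 I| - \tfrac n2 \log 2\pi}
#' for the zero-mean GP observation model.
#'
#' @param X numeric matrix of inputs (rows = observations), already on the
#'   scale the kernel is meant to see
#' @param y numeric target vector, length `nrow(X)`
#' @param params a [kernel_params()] object
#' @return scalar log marginal likelihood
#' @export
log_marginal_likelihood <- function(X, y, params) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n, n >= 1)
  K <- kernel_matrix(X, X, params)
  cf <- chol_with_jitter(K, params$sigma_n2)
  L <- cf$L
  alpha <- backsolve(L, backsolve(L, y, transpose = TRUE))
  -0.5 * sum(y * alpha) - sum(log(diag(L))) - 0.5 * n * log(2 * pi)
}

## Per-feature squared-difference matrices (for ARD gradients) and their sum.
precompute_distances <- function(X, ard) {
  p <- ncol(X)
  per <- if (ard) lapply(seq_len(p), function(j) outer(X[, j], X[, j], "-")^2)
         else NULL
  d2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * tcrossprod(X)
  d2[d2 < 0] <- 0
  list(full = d2, per = per)
}

## Negative lml and gradient in theta = (theta1[, ...], theta2, log sigma_n2).
## For ARD, theta1 is a vector of per-feature log length scales.
## `dist` comes from precompute_distances() on the standardized X.
gpr_objective <- function(theta, dist, y, distance, ard) {
  n <- length(y)
  n_l <- if (ard) length(dist$per) else 1L
  sl <- exp(theta[seq_len(n_l)])
  sf <- exp(theta[n_l + 1L])
  sn2 <- exp(theta[n_l + 2L])
  if (distance == "squared") {
    r2 <- if (ard) Reduce(`+`, Map(`/`, dist$per, sl)) else dist$full / sl
    K <- sf^2 * exp(-r2)
  } else {
    K <- sf^2 * exp(-sqrt(dist$full) / sl[1L])
  }
  cf <- chol_with_jitter(K, sn2)
  L <- cf$L
  alpha <- backsolve(L, backsolve(L, y, transpose = TRUE))
  nll <- 0.5 * sum(y * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)

  Kinv <- chol2inv(L)
  W <- tcrossprod(alpha) - Kinv          # dL/dtheta = 0.5 tr(W dK/dtheta)
  grad <- numeric(length(theta))
  if (distance == "squared") {
    if (ard) {
      for (j in seq_len(n_l))
        grad[j] <- 0.5 * sum(W * (K * dist$per[[j]] / sl[j]))
    } else {
      grad[1L] <- 0.5 * sum(W * (K * dist$full / sl))
    }
  } else {
    grad[1L] <- 0.5 * sum(W * (K * sqrt(dist$full) / sl[1L]))
  }
  grad[n_l + 1L] <- 0.5 * sum(W * (2 * K))
  grad[n_l + 2L] <- 0.5 * sn2 * sum(diag(W))
  list(value = nll, gradient = -grad)
}

## Deterministic multi-start grid in (theta1, theta2, log sigma_n2).
gpr_starts <- function(n_l) {
  base <- rbind(
    c(0.0,  0.0, -2.0),
    c(2.5,  0.0, -2.0),
    c(-1.0, 0.5, -4.0),
    c(1.5, -0.5, -1.0),
    c(3.5,  0.5, -3.0))
  lapply(seq_len(nrow(base)), function(i)
    c(rep(base[i, 1L], n_l), base[i, 2L], base[i, 3L]))
}

#' Fit an exponential-kernel GPR model
#'
#' Standardizes the inputs and target (z-scores computed on the training
#' data only), then maximizes the log marginal likelihood over the log
#' hyperparameters with `optim(method = "L-BFGS-B")` from five fixed
#' starting points, analytic gradients, and box bounds `[-5, 5]` on the log
#' scales (`[-8, 3]` on the log noise variance).  The returned model caches
#' `alpha = (K + sigma_n2 I)^{-1} y` for prediction.
#'
#' @param X numeric matrix (n x p) of raw feature vectors
#' @param y numeric target vector (mmHg), length n >= 2
#' @param distance kernel distance form, `"squared"` (default) or
#'   `"euclidean"`
#' @param ard use one length scale per feature (default `FALSE`)
#' @return an object of class `gpr_model`
#' @export
fit_gpr <- function(X, y, distance = c("squared", "euclidean"), ard = FALSE) {
  distance <- match.arg(distance)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 training observations")
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("training data must be finite with no missing entries")

  x_mu <- colMeans(X)
  x_sd <- apply(X, 2L, stats::sd)
  x_sd[x_sd < 1e-12] <- 1          # constant columns pass through centered
  y_mu <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd < 1e-12) y_sd <- 1
  Xs <- sweep(sweep(X, 2L, x_mu), 2L, x_sd, "/")
  ys <- (y - y_mu) / y_sd

  n_l <- if (ard) ncol(X) else 1L
  lower <- c(rep(-5, n_l), -5, -8)
  upper <- c(rep(5, n_l), 5, 3)
  dist <- precompute_distances(Xs, ard)
  cache <- new.env(parent = emptyenv())     # fn and gr share one evaluation
  eval_obj <- function(th) {
    key <- paste(th, collapse = ",")
    if (!identical(cache$key, key)) {
      cache$val <- gpr_objective(th, dist, ys, distance, ard)
      cache$key <- key
    }
    cache$val
  }
  best <- NULL
  fails <- character(0)
  for (st in gpr_starts(n_l)) {
    fit <- tryCatch(
      stats::optim(st,
                   fn = function(th) eval_obj(th)$value,
                   gr = function(th) eval_obj(th)$gradient,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 200)),
      error = function(e) e)
    if (inherits(fit, "error")) { fails <- c(fails, conditionMessage(fit)); next }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("GPR fit failed from every start: ", paste(unique(fails), collapse = "; "))

  th <- best$par
  params <- kernel_params(exp(th[n_l + 1L]), exp(th[seq_len(n_l)]),
                          exp(th[n_l + 2L]), distance = distance)
  model <- structure(list(
    X = Xs, y = ys, params = params, ard = ard,
    standardizer = list(x_mean = x_mu, x_sd = x_sd, y_mean = y_mu, y_sd = y_sd),
    log_marginal = -best$value), class = "gpr_model")
  gpr_cache_alpha(model)
}

#' Build a GPR model with fixed hyperparameters (no fitting)
#'
#' @param X numeric matrix (n x p) of raw feature vectors
#' @param y numeric target vector, length n
#' @param params a [kernel_params()] object used as-is
#' @param standardize z-score inputs/target before conditioning (default
#'   `TRUE`); with `FALSE` the kernel sees the raw scales, which is what
#'   closed-form oracle comparisons want
#' @return an object of class `gpr_model`
#' @export
gpr_model <- function(X, y, params, standardize = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n, n >= 1)
  if (standardize) {
    x_mu <- colMeans(X); x_sd <- apply(X, 2L, stats::sd)
    x_sd[!is.finite(x_sd) | x_sd < 1e-12] <- 1
    y_mu <- mean(y); y_sd <- stats::sd(y)
    if (!is.finite(y_sd) || y_sd < 1e-12) y_sd <- 1
  } else {
    x_mu <- rep(0, ncol(X)); x_sd <- rep(1, ncol(X)); y_mu <- 0; y_sd <- 1
  }
  model <- structure(list(
    X = sweep(sweep(X, 2L, x_mu), 2L, x_sd, "/"),
    y = (y - y_mu) / y_sd, params = params,
    ard = length(params$sigma_l) > 1L,
    standardizer = list(x_mean = x_mu, x_sd = x_sd, y_mean = y_mu, y_sd = y_sd),
    log_marginal = NA_real_), class = "gpr_model")
  model <- gpr_cache_alpha(model)
  model$log_marginal <- log_marginal_likelihood(model$X, model$y, params)
  model
}

## Recompute and cache the Cholesky factor and alpha for a model's
## (standardized) training data.
gpr_cache_alpha <- function(model) {
  K <- kernel_matrix(model$X, model$X, model$params)
  cf <- chol_with_jitter(K, model$params$sigma_n2)
  model$L <- cf$L
  model$alpha <- backsolve(cf$L, backsolve(cf$L, model$y, transpose = TRUE))
  model
}

#' Posterior predictive mean and variance
#'
#' The predictive mean is \eqn{k_*^\top (K+\sigma_n^2 I)^{-1} y} and the
#' variance \eqn{k(x_*,x_*) - k_*^\top (K+\sigma_n^2 I)^{-1} k_*}
#' (latent-function variance, bounded by `sigma_f^2` in standardized
#' space), both de-standardized to mmHg / mmHg^2.
#'
#' @param object a fitted `gpr_model`
#' @param newdata numeric matrix (rows = query points) or single vector of
#'   raw (unstandardized) features
#' @param ... unused
#' @return a data.frame with columns `mean` (mmHg) and `variance` (mmHg^2)
#' @export
predict.gpr_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$X))
    stop("query has ", ncol(newdata), " features; model expects ",
         ncol(object$X))
  st <- object$standardizer
  Q <- sweep(sweep(newdata, 2L, st$x_mean), 2L, st$x_sd, "/")
  Kq <- kernel_matrix(Q, object$X, object$params)      # m x n
  mean_std <- as.numeric(Kq %*% object$alpha)
  v <- backsolve(object$L, t(Kq), transpose = TRUE)    # n x m
  var_std <- pmax(object$params$sigma_f^2 - colSums(v^2), 0)
  data.frame(mean = mean_std * st$y_sd + st$y_mean,
             variance = var_std * st$y_sd^2)
}

#' @export
print.gpr_model <- function(x, ...) {
  cat("Exponential-kernel GPR model\n")
  cat(sprintf("  n = %d, p = %d, distance = %s%s\n", nrow(x$X), ncol(x$X),
              x$params$distance, if (x$ard) " (ARD)" else ""))
  cat(sprintf("  sigma_f = %.4g, sigma_l = %s, sigma_n2 = %.4g\n",
              x$params$sigma_f,
              paste(signif(x$params$sigma_l, 4), collapse = ", "),
              x$params$sigma_n2))
  cat(sprintf("  log marginal likelihood = %.4f\n", x$log_marginal))
  invisible(x)
}

#' Append observations to a fitted model with hyperparameters frozen
#'
#' Used by the feedback-calibration step: the new (feature, reference BP)
#' pairs are standardized with the model's existing standardizer, appended
#' to the training set, and `alpha` is recomputed.  Kernel hyperparameters
#' are not re-fitted.
#'
#' @param model a fitted `gpr_model`
#' @param X_new numeric matrix (or single vector) of raw feature rows
#' @param y_new numeric vector of raw targets (mmHg)
#' @return the updated `gpr_model`
#' @export
gpr_augment <- function(model, X_new, y_new) {
  if (length(y_new) == 0L) return(model)
  if (is.null(dim(X_new))) X_new <- matrix(X_new, nrow = 1L)
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != ncol(model$X))
    stop("new rows have ", ncol(X_new), " features; model expects ",
         ncol(model$X))
  if (nrow(X_new) != length(y_new)) stop("X_new rows must match y_new length")
  st <- model$standardizer
  Xs <- sweep(sweep(X_new, 2L, st$x_mean), 2L, st$x_sd, "/")
  ys <- (y_new - st$y_mean) / st$y_sd
  model$X <- rbind(model$X, Xs)
  model$y <- c(model$y, ys)
  gpr_cache_alpha(model)
}
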