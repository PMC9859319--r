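## Least-squares support vector regression with RBF kernel.
##
## Training solves the dual KKT system
##
##   [ 0   1'          ] [ b     ]   [ 0 ]
##   [ 1   Omega + I/g ] [ alpha ] = [ y ],   Omega_ij = K(x_i, x_j),
##
## by block elimination on the symmetric positive definite A = Omega + I/gamma
## (Cholesky): solve A eta = 1 and A nu = y, then b = sum(nu) / sum(eta) and
## alpha = nu - b * eta, which satisfies sum(alpha) = 0 identically.
## Prediction is yhat(x) = sum_i alpha_i K(x, x_i) + b.

#' Kernel parameters
#'
#' @param sigma RBF width, `> 0`.
#' @param gamma Regularization, `> 0` (ridge term `I / gamma` in the dual).
#' @return An object of class `kernel_params`.
#' @export
kernel_params <- function(sigma, gamma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("`sigma` must be a single finite number > 0", call. = FALSE)
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma <= 0)
    stop("`gamma` must be a single finite number > 0", call. = FALSE)
  structure(list(sigma = sigma, gamma = gamma), class = "kernel_params")
}

#' Radial basis function kernel
#'
#' `K(x, x2) = exp(-||x - x2||^2 / (2 sigma^2))`; symmetric, in (0, 1],
#' equal to 1 iff `x == x2`.
#'
#' @param x,x2 Numeric vectors of equal length.
#' @param sigma Kernel width `> 0`.
#' @return Scalar similarity in (0, 1].
#' @export
#' @examples
#' rbf_kernel(c(0, 0), c(1, 1), sigma = 1)  # exp(-1)
rbf_kernel <- function(x, x2, sigma) {
  if (length(x) != length(x2))
    stop("`x` and `x2` must have the same dimension", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("`sigma` must be > 0", call. = FALSE)
  exp(-sum((x - x2)^2) / (2 * sigma^2))
}

## Gram matrix between row sets (n x d) and (n2 x d)
rbf_gram <- function(X, X2, sigma) {
  X <- as.matrix(X); X2 <- as.matrix(X2)
  d2 <- outer(rowSums(X^2), rowSums(X2^2), "+") - 2 * tcrossprod(X, X2)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

#' Fit a least-squares SVM regression
#'
#' @param x Numeric matrix of predictors, one row per training sample (a
#'   vector is taken as a single column).
#' @param y Numeric response, one value per row of `x`.
#' @param params A [kernel_params()] (or `sigma`/`gamma` given separately).
#' @param sigma,gamma Convenience scalars used when `params` is missing.
#' @return An object of class `lssvm`: `alphas`, `bias`, `train_inputs`,
#'   `params`, and `diagnostics` (relative KKT residual, `sum(alpha)`, and a
#'   Cholesky-based condition estimate).
#' @export
#' @examples
#' X <- matrix(seq(0, 1, length.out = 8))
#' m <- lssvm_fit(X, sin(2 * pi * X[, 1]), sigma = 0.3, gamma = 100)
#' max(abs(predict(m, X) - sin(2 * pi * X[, 1])))
lssvm_fit <- function(x, y, params = NULL, sigma = NULL, gamma = NULL) {
  if (is.null(params)) params <- kernel_params(sigma, gamma)
  stopifnot(inherits(params, "kernel_params"))
  X <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 training samples", call. = FALSE)
  if (length(y) != n)
    stop("`y` must have one value per row of `x`", call. = FALSE)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("training data must be finite", call. = FALSE)

  K <- rbf_gram(X, X, params$sigma)
  A <- K + diag(1 / params$gamma, n)
  R <- tryCatch(chol(A), error = function(e)
    stop("KKT system is numerically singular (Cholesky failed): ",
         conditionMessage(e), call. = FALSE))
  ## condition estimate from the Cholesky factor
  dr <- diag(R)
  cond <- (max(dr) / min(dr))^2
  if (cond > 1e12)
    warning(sprintf("ill-conditioned KKT system (condition estimate %.2e)",
                    cond), call. = FALSE)
  solve2 <- function(rhs) backsolve(R, forwardsolve(t(R), rhs))
  eta <- solve2(rep(1, n))
  nu <- solve2(y)
  b <- sum(nu) / sum(eta)
  alpha <- nu - b * eta

  kkt <- max(abs(A %*% alpha + b - y)) / max(1, max(abs(y)))
  structure(list(alphas = alpha, bias = b, train_inputs = X, params = params,
                 diagnostics = list(kkt_residual = kkt,
                                    sum_alpha = sum(alpha),
                                    condition = cond)),
            class = "lssvm")
}

#' Predict from a fitted LS-SVM
#'
#' @param object An `lssvm` model.
#' @param newdata Matrix (or vector) of predictor rows with the training
#'   dimension.
#' @param ... Unused.
#' @return Numeric vector of predictions `sum_i alpha_i K(x, x_i) + b`.
#' @export
predict.lssvm <- function(object, newdata, ...) {
  X2 <- as.matrix(newdata)
  if (ncol(X2) != ncol(object$train_inputs))
    stop(sprintf("newdata has %d columns; model was trained with %d",
                 ncol(X2), ncol(object$train_inputs)), call. = FALSE)
  as.vector(rbf_gram(X2, object$train_inputs, object$params$sigma) %*%
              object$alphas) + object$bias
}

#' @export
print.lssvm <- function(x, ...) {
  cat(sprintf(
    "LS-SVM: %d samples, %d predictors, sigma=%.4g gamma=%.4g (KKT %.1e)\n",
    nrow(x$train_inputs), ncol(x$train_inputs), x$params$sigma,
    x$params$gamma, x$diagnostics$kkt_residual))
  invisible(x)
}

#' Serialize / restore an LS-SVM model as plain text
#'
#' Key-value text format (full double precision via `format(..., digits =
#' 17)`) so fitted models can be archived with run outputs.
#'
#' @param model An `lssvm`.
#' @param file Path to write / read.
#' @return `write_lssvm` returns `file` invisibly; `read_lssvm` returns the
#'   restored `lssvm`.
#' @export
write_lssvm <- function(model, file) {
  stopifnot(inherits(model, "lssvm"))
  num <- function(v) paste(sprintf("%.17g", v), collapse = " ")
  lines <- c(
    paste("sigma:", num(model$params$sigma)),
    paste("gamma:", num(model$params$gamma)),
    paste("bias:", num(model$bias)),
    paste("alphas:", num(model$alphas)),
    paste("n:", nrow(model$train_inputs)),
    paste("d:", ncol(model$train_inputs)),
    paste("train_inputs:", num(as.vector(model$train_inputs)))
  )
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_lssvm
#' @export
read_lssvm <- function(file) {
  kv <- strsplit(readLines(file), ": ", fixed = TRUE)
  vals <- stats::setNames(
    lapply(kv, function(p) as.numeric(strsplit(p[2], " ")[[1]])),
    vapply(kv, `[[`, "", 1))
  X <- matrix(vals$train_inputs, nrow = vals$n, ncol = vals$d)
  m <- list(alphas = vals$alphas, bias = vals$bias, train_inputs = X,
            params = kernel_params(vals$sigma, vals$gamma),
            diagnostics = list(kkt_residual = NA_real_,
                               sum_alpha = sum(vals$alphas),
                               condition = NA_real_))
  class(m) <- "lssvm"
  m
}
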