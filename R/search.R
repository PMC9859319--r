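## Stochastic accept-if-no-worse search over the RBF width sigma and the
## regularization gamma, minimizing the squared-error objective G.

#' Search configuration
#'
#' @param init_sigma,init_gamma Positive starting point `(sigma0, gamma0)`.
#' @param epsilon Objective tolerance: the search stops as soon as
#'   `G <= epsilon` (default 0, i.e. run to the iteration cap).
#' @param max_iter Iteration cap (default 200).
#' @param seed RNG seed for the step draws.
#' @param step_mode `"symmetric"` (default): signed steps uniform on the
#'   *log* scale, i.e. proposals `sigma * exp(U(-step_sigma, step_sigma))`
#'   and `gamma * exp(U(-step_gamma, step_gamma))`, so the walk explores the
#'   orders of magnitude both parameters span and stays positive by
#'   construction.  `"upward"`: both steps additive, uniform on (0, 1), so
#'   sigma and gamma can only drift upward.
#' @param objective_mode How G is evaluated: `"loocv"` (default;
#'   leave-one-out, guards against the interpolation degeneracy of the
#'   training objective), `"train"` (mean squared residual of the fit on its
#'   own training points -- the literal objective formula) or `"holdout"`
#'   (same formula on a trailing block excluded from the fit).
#' @param step_sigma,step_gamma Half-widths of the symmetric log-scale
#'   steps.
#' @param sigma_range,gamma_range Box bounds; proposals outside are
#'   rejected without evaluation (the gamma ceiling keeps the dual system
#'   numerically positive definite).
#' @param holdout Number of trailing points held out in `"holdout"` mode.
#' @return An object of class `search_config`.
#' @export
search_config <- function(init_sigma = 1, init_gamma = 10, epsilon = 0,
                          max_iter = 200L, seed = 1L,
                          step_mode = c("symmetric", "upward"),
                          objective_mode = c("loocv", "train", "holdout"),
                          step_sigma = 0.4, step_gamma = 1.2,
                          sigma_range = c(1e-2, 1e3),
                          gamma_range = c(1e-2, 1e8),
                          holdout = NULL) {
  step_mode <- match.arg(step_mode)
  objective_mode <- match.arg(objective_mode)
  if (init_sigma <= 0 || init_gamma <= 0)
    stop("initial point must be strictly positive", call. = FALSE)
  if (epsilon < 0) stop("`epsilon` must be >= 0", call. = FALSE)
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L)
    stop("`max_iter` must be >= 1", call. = FALSE)
  structure(list(init_sigma = init_sigma, init_gamma = init_gamma,
                 epsilon = epsilon, max_iter = max_iter,
                 seed = as.integer(seed), step_mode = step_mode,
                 objective_mode = objective_mode, step_sigma = step_sigma,
                 step_gamma = step_gamma, sigma_range = sigma_range,
                 gamma_range = gamma_range, holdout = holdout),
            class = "search_config")
}

#' Squared-error objective G(sigma, gamma)
#'
#' `G = (1/m) sum_j (y_j - yhat(x_j))^2`.  In `"train"` mode the residuals
#' are those of the fit on its own training data; `"holdout"` fits on the
#' leading points and evaluates on the trailing `holdout` block; `"loocv"`
#' refits excluding each point in turn.
#'
#' @param x Predictor matrix (rows = samples).
#' @param y Numeric response.
#' @param params A [kernel_params()].
#' @param objective_mode `"train"`, `"holdout"` or `"loocv"`.
#' @param holdout Trailing block size for `"holdout"` mode (default: a
#'   quarter of the samples, at least 1).
#' @return Nonnegative mean squared error.
#' @export
objective_G <- function(x, y, params,
                        objective_mode = c("train", "holdout", "loocv"),
                        holdout = NULL) {
  objective_mode <- match.arg(objective_mode)
  X <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(X)
  if (objective_mode != "train" && n < 3L)
    stop("holdout/loocv objectives need at least 3 samples", call. = FALSE)
  switch(objective_mode,
    train = {
      fit <- lssvm_fit(X, y, params)
      mean((y - predict(fit, X))^2)
    },
    holdout = {
      k <- if (is.null(holdout)) max(1L, floor(n / 4)) else as.integer(holdout)
      if (k < 1L || k > n - 2L)
        stop("holdout block must leave at least 2 training samples",
             call. = FALSE)
      tr <- seq_len(n - k); te <- (n - k + 1L):n
      fit <- lssvm_fit(X[tr, , drop = FALSE], y[tr], params)
      mean((y[te] - predict(fit, X[te, , drop = FALSE]))^2)
    },
    loocv = {
      res <- vapply(seq_len(n), function(i) {
        fit <- lssvm_fit(X[-i, , drop = FALSE], y[-i], params)
        y[i] - predict(fit, X[i, , drop = FALSE])
      }, numeric(1))
      mean(res^2)
    })
}

#' Stochastic hyperparameter search
#'
#' Iterates: draw random steps, form a proposal from the current point
#' (additive in `"upward"` mode, multiplicative on the log scale in
#' `"symmetric"` mode), and accept it iff its objective does not exceed the
#' current one; stop when `G <= epsilon` or the iteration cap is reached.
#' Proposals outside the box bounds, and proposals whose fit fails
#' numerically, are rejected (trace rows with `G = NA`/`Inf`).  The
#' accepted-objective sequence is non-increasing by construction, and the
#' whole trajectory is reproducible from the seed.
#'
#' @param x Predictor matrix.
#' @param y Numeric response.
#' @param config A [search_config()].
#' @return An object of class `search_trace`: `trace` (data.frame with
#'   iteration, sigma, gamma, G of each proposal, accepted flag), `sigma`,
#'   `gamma`, `G` at the final accepted point, `G_init`, `stop_reason`
#'   (`"tolerance"` or `"iteration_cap"`), and `config`.
#' @export
hyper_search <- function(x, y, config) {
  stopifnot(inherits(config, "search_config"))
  X <- as.matrix(x); y <- as.numeric(y)
  gfun <- function(s, g)
    objective_G(X, y, kernel_params(s, g), config$objective_mode,
                config$holdout)

  s0 <- config$init_sigma; g0 <- config$init_gamma
  G0 <- gfun(s0, g0)
  G_init <- G0
  n_iter <- 0L
  rows <- vector("list", config$max_iter)
  stop_reason <- "iteration_cap"

  if (G0 <= config$epsilon) {
    stop_reason <- "tolerance"
  } else {
    with_seed(config$seed, {
      for (k in seq_len(config$max_iter)) {
        n_iter <- k
        if (config$step_mode == "upward") {
          s1 <- s0 + runif(1); g1 <- g0 + runif(1)
        } else {
          s1 <- s0 * exp(runif(1, -config$step_sigma, config$step_sigma))
          g1 <- g0 * exp(runif(1, -config$step_gamma, config$step_gamma))
        }
        if (s1 <= 0 || g1 <= 0 ||
            s1 < config$sigma_range[1] || s1 > config$sigma_range[2] ||
            g1 < config$gamma_range[1] || g1 > config$gamma_range[2]) {
          rows[[k]] <- data.frame(iteration = k, sigma = s1, gamma = g1,
                                  G = NA_real_, accepted = FALSE)
          next
        }
        G1 <- tryCatch(suppressWarnings(gfun(s1, g1)),
                       error = function(e) Inf)
        acc <- G1 <= G0
        rows[[k]] <- data.frame(iteration = k, sigma = s1, gamma = g1,
                                G = G1, accepted = acc)
        if (acc) { s0 <- s1; g0 <- g1; G0 <- G1 }
        if (G0 <= config$epsilon) { stop_reason <- "tolerance"; break }
      }
    })
  }
  trace <- if (n_iter > 0L) do.call(rbind, rows[seq_len(n_iter)])
           else data.frame(iteration = integer(), sigma = numeric(),
                           gamma = numeric(), G = numeric(),
                           accepted = logical())
  structure(list(trace = trace, sigma = s0, gamma = g0, G = G0,
                 G_init = G_init, iterations = n_iter,
                 stop_reason = stop_reason, config = config),
            class = "search_trace")
}

#' @export
print.search_trace <- function(x, ...) {
  cat(sprintf(
    "search: %d iterations (%d accepted), G %.4g -> %.4g, stop: %s\n",
    x$iterations, sum(x$trace$accepted), x$G_init, x$G, x$stop_reason))
  cat(sprintf("  final sigma=%.5g gamma=%.5g\n", x$sigma, x$gamma))
  invisible(x)
}

#' Export a search trace as CSV
#'
#' Columns: iteration, sigma, gamma, G, accepted.
#'
#' @param trace A `search_trace`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_search_trace <- function(trace, file) {
  stopifnot(inherits(trace, "search_trace"))
  utils::write.csv(trace$trace, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
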