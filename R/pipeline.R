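## Per-region, per-outcome out-of-sample forecasting experiment: chronological
## holdout split, per-region predictor standardization, hyperparameter search
## on the training years, final fit, and MPE/MSE/SDE on the held-out horizon.

#' Predictor sets of the three model variants
#'
#' Variant 1 uses eco-efficiency alone; variant 2 adds GDP per capita,
#' urbanization and population density; variant 3 further adds the three
#' medical supply and technical level factors (7 predictors in all).  The
#' sets are nested.
#'
#' @param id Variant id: 1, 2 or 3.
#' @return An object of class `model_variant` with `id` and `predictors`.
#' @export
#' @examples
#' model_variant(3)$predictors
model_variant <- function(id) {
  id <- as.integer(id)
  if (is.na(id) || !id %in% 1:3) stop("variant id must be 1, 2 or 3",
                                      call. = FALSE)
  ctl <- panel_columns()$controls
  predictors <- switch(id,
    "ree",
    c("ree", ctl[1:3]),
    c("ree", ctl))
  structure(list(id = id, predictors = predictors), class = "model_variant")
}

#' Forecast-error metrics over a horizon
#'
#' Signed mean percentage error, mean squared error and its square root:
#' `MPE = (1/T) sum (y_t - yhat_t) / y_t`, `MSE = (1/T) sum (y_t - yhat_t)^2`,
#' `SDE = sqrt(MSE)`.  No absolute value is taken in MPE, so it can be
#' negative.
#'
#' @param actuals Observed values `y_t`, all nonzero.
#' @param predictions Forecasts `yhat_t`, same length.
#' @param years Optional year labels for the per-year record.
#' @return An object of class `error_metrics`: `mpe`, `mse`, `sde`,
#'   `horizon_T`, and `per_year` (data.frame year, actual, predicted).
#' @export
#' @examples
#' m <- compute_metrics(c(1, 2, 4), c(1.1, 1.8, 4.4))
#' c(m$mpe, m$mse, m$sde)
compute_metrics <- function(actuals, predictions, years = NULL) {
  actuals <- as.numeric(actuals); predictions <- as.numeric(predictions)
  T <- length(actuals)
  if (T < 1L || length(predictions) != T)
    stop("`actuals` and `predictions` must have equal length >= 1",
         call. = FALSE)
  if (is.null(years)) years <- seq_len(T)
  if (any(actuals == 0))
    stop("zero actual value at year ", paste(years[actuals == 0],
                                             collapse = ", "),
         ": percentage error undefined", call. = FALSE)
  err <- actuals - predictions
  mse <- mean(err^2)
  structure(list(mpe = mean(err / actuals), mse = mse, sde = sqrt(mse),
                 horizon_T = T,
                 per_year = data.frame(year = years, actual = actuals,
                                       predicted = predictions)),
            class = "error_metrics")
}

#' @export
print.error_metrics <- function(x, ...) {
  cat(sprintf("T=%d  MPE=%.5f  MSE=%.5f  SDE=%.5f\n", x$horizon_T, x$mpe,
              x$mse, x$sde))
  invisible(x)
}

## standardize columns with training-set statistics; constant columns get
## sd 1 so they map to a constant 0
scale_train_test <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sd <- apply(Xtr, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(train = sweep(sweep(Xtr, 2, mu), 2, sd, "/"),
       test = sweep(sweep(Xte, 2, mu), 2, sd, "/"))
}

#' Fit, tune and evaluate one region-outcome-variant cell
#'
#' Chronological split (last `holdout` years held out), predictors
#' standardized with training-year statistics, hyperparameters chosen by
#' [hyper_search()] on the training years, final model fitted at the chosen
#' `(sigma, gamma)`, and errors computed on the held-out years.  The search
#' seed is derived deterministically from `search_cfg$seed` and the cell
#' identifiers, so results do not depend on row or loop order.
#'
#' @param panel A `panel_dataset` with `ree` filled.
#' @param region Region identifier.
#' @param outcome Outcome column name (one of `panel_columns()$outcomes`).
#' @param variant A [model_variant()] or its id.
#' @param holdout Number of trailing years held out (default 3).
#' @param search_cfg A [search_config()].
#' @param in_sample Also evaluate errors on the training years? (Adds an
#'   `in_sample` element mirroring `metrics`.)
#' @return List with `metrics` (holdout [compute_metrics()] result),
#'   `params` (chosen `kernel_params`), `trace` (the `search_trace`), and
#'   optionally `in_sample`.
#' @export
run_region <- function(panel, region, outcome, variant, holdout = 3L,
                       search_cfg = search_config(), in_sample = FALSE) {
  stopifnot(inherits(panel, "panel_dataset"))
  if (!inherits(variant, "model_variant")) variant <- model_variant(variant)
  d <- panel$data[panel$data$region == region, , drop = FALSE]
  if (nrow(d) == 0L) stop("unknown region: ", region, call. = FALSE)
  if (!outcome %in% names(d)) stop("unknown outcome: ", outcome,
                                   call. = FALSE)
  d <- d[order(d$year), , drop = FALSE]
  n <- nrow(d)
  holdout <- as.integer(holdout)
  if (holdout < 1L || n - holdout < 4L)
    stop(sprintf("region %s: need >= 4 training years after holding out %d",
                 region, holdout), call. = FALSE)
  if (anyNA(d[variant$predictors]))
    stop(sprintf("region %s: predictors contain NA (is `ree` filled?)",
                 region), call. = FALSE)

  tr <- seq_len(n - holdout); te <- (n - holdout + 1L):n
  Xall <- as.matrix(d[variant$predictors])
  sc <- scale_train_test(Xall[tr, , drop = FALSE], Xall[te, , drop = FALSE])
  y <- d[[outcome]]

  cfg <- search_cfg
  cfg$seed <- cell_seed(search_cfg$seed, region, outcome, variant$id)
  res <- tryCatch({
    tr_out <- hyper_search(sc$train, y[tr], cfg)
    params <- kernel_params(tr_out$sigma, tr_out$gamma)
    fit <- lssvm_fit(sc$train, y[tr], params)
    pred <- predict(fit, sc$test)
    out <- list(metrics = compute_metrics(y[te], pred, d$year[te]),
                params = params, trace = tr_out)
    if (in_sample)
      out$in_sample <- compute_metrics(y[tr], predict(fit, sc$train),
                                       d$year[tr])
    out
  }, error = function(e)
    stop(sprintf("region %s, outcome %s, variant %d: %s", region, outcome,
                 variant$id, conditionMessage(e)), call. = FALSE))
  res
}

#' Run the full forecasting experiment
#'
#' Cartesian product over regions x outcomes x variants.  Per-cell failures
#' are recorded (column `error`) rather than fatal.  The `averages` table
#' holds, per outcome and variant, the arithmetic mean over regions of each
#' metric; regions listed in `exclude_from_average` (e.g. a national
#' aggregate series) are forecast like any other but left out of the means.
#'
#' @param panel A `panel_dataset` with `ree` filled.
#' @param variants Vector of variant ids (default `1:3`).
#' @param outcomes Outcome columns (default all five).
#' @param holdout Trailing years held out per region (default 3).
#' @param search_cfg A [search_config()].
#' @param exclude_from_average Regions excluded from the average rows.
#' @return An object of class `experiment_result`: `cells` (one row per
#'   region-outcome-variant with mpe, mse, sde, sigma, gamma), `averages`,
#'   `per_year` (long data.frame of holdout actual/predicted pairs),
#'   `failures`, and the call settings.
#' @export
run_experiment <- function(panel, variants = 1:3,
                           outcomes = panel_columns()$outcomes,
                           holdout = 3L, search_cfg = search_config(),
                           exclude_from_average = character(0)) {
  stopifnot(inherits(panel, "panel_dataset"))
  regions <- sort(unique(panel$data$region))
  cells <- list(); per_year <- list(); failures <- list()
  for (v in variants) {
    var <- model_variant(v)
    for (o in outcomes) {
      for (r in regions) {
        res <- tryCatch(run_region(panel, r, o, var, holdout, search_cfg),
                        error = function(e) e)
        if (inherits(res, "error")) {
          failures[[length(failures) + 1L]] <-
            data.frame(region = r, outcome = o, variant = v,
                       message = conditionMessage(res))
          next
        }
        m <- res$metrics
        cells[[length(cells) + 1L]] <-
          data.frame(region = r, outcome = o, variant = v, mpe = m$mpe,
                     mse = m$mse, sde = m$sde, sigma = res$params$sigma,
                     gamma = res$params$gamma)
        per_year[[length(per_year) + 1L]] <-
          cbind(region = r, outcome = o, variant = v, m$per_year)
      }
    }
  }
  cells <- if (length(cells)) do.call(rbind, cells) else
    data.frame(region = character(), outcome = character(),
               variant = integer(), mpe = numeric(), mse = numeric(),
               sde = numeric(), sigma = numeric(), gamma = numeric())
  rownames(cells) <- NULL
  avg_src <- cells[!cells$region %in% exclude_from_average, , drop = FALSE]
  averages <- if (nrow(avg_src)) {
    ag <- stats::aggregate(avg_src[c("mpe", "mse", "sde")],
                           by = avg_src[c("outcome", "variant")], mean)
    ag[order(ag$variant, match(ag$outcome, outcomes)), , drop = FALSE]
  } else data.frame(outcome = character(), variant = integer(),
                    mpe = numeric(), mse = numeric(), sde = numeric())
  rownames(averages) <- NULL
  structure(list(cells = cells, averages = averages,
                 per_year = if (length(per_year)) do.call(rbind, per_year)
                            else NULL,
                 failures = if (length(failures)) do.call(rbind, failures)
                            else NULL,
                 outcomes = outcomes, variants = variants,
                 holdout = holdout, search_cfg = search_cfg,
                 exclude_from_average = exclude_from_average),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("experiment_result: %d cells (%d regions x %d outcomes x %d variants)\n",
              nrow(x$cells), length(unique(x$cells$region)),
              length(x$outcomes), length(x$variants)))
  if (!is.null(x$failures))
    cat(sprintf("  %d failed cells\n", nrow(x$failures)))
  print(x$averages, digits = 4)
  invisible(x)
}

#' Stability of forecast errors across the horizon
#'
#' For each region the per-year error series are the yearly percentage error
#' `(y_t - yhat_t) / y_t` (MPE series), squared error (MSE series) and
#' absolute error (SDE series).  For each (outcome, variant, metric), the
#' *average degree* is the mean over regions and years of the absolute
#' year-over-year change of the series, and the *variation degree* is the
#' standard deviation of those absolute changes; smaller values mean a more
#' stable forecast.
#'
#' @param result An `experiment_result` (its `per_year` slot must be
#'   present with horizon >= 2).
#' @return Data.frame: outcome, variant, metric, average_degree,
#'   variation_degree.
#' @export
stability_analysis <- function(result) {
  stopifnot(inherits(result, "experiment_result"))
  py <- result$per_year
  if (is.null(py)) stop("per-year errors not available", call. = FALSE)
  if (result$holdout < 2L)
    stop("stability analysis needs a horizon of at least 2 years",
         call. = FALSE)
  err <- py$actual - py$predicted
  series <- data.frame(py[c("region", "outcome", "variant", "year")],
                       mpe = err / py$actual, mse = err^2, sde = abs(err))
  out <- list()
  for (v in unique(series$variant)) {
    for (o in unique(series$outcome)) {
      sub <- series[series$variant == v & series$outcome == o, , drop = FALSE]
      ch <- lapply(split(sub, sub$region), function(s) {
        s <- s[order(s$year), , drop = FALSE]
        abs(apply(s[c("mpe", "mse", "sde")], 2, diff))
      })
      for (metric in c("mpe", "mse", "sde")) {
        d <- unlist(lapply(ch, function(m)
          if (is.matrix(m)) m[, metric] else m[metric]))
        out[[length(out) + 1L]] <- data.frame(
          outcome = o, variant = v, metric = metric,
          average_degree = mean(d),
          variation_degree = if (length(d) > 1L) stats::sd(d) else 0)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
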