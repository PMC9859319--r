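## Slacks-based measure (SBM) DEA with undesirable outputs.
##
## Each decision-making unit (DMU) o is scored by the non-oriented SBM
##
##   rho = min  (1 - (1/m) sum_i s_i^- / x_io) /
##              (1 + 1/(s1+s2) (sum_r s_r^g / y_ro^g + sum_r s_r^b / y_ro^b))
##
## over frontier weights lambda >= 0 and slacks s >= 0 subject to
##   x_o  = X  lambda + s^-,   y_o^g = Yg lambda - s^g,   y_o^b = Yb lambda + s^b.
##
## The fractional program is linearized by the Charnes-Cooper transform
## (multiply through by t > 0, fix the denominator at 1) and solved as one
## linear program per unit with the package's dense two-phase simplex
## (see R/lp.R), which tolerates the heavy degeneracy of efficient units.

#' Construct a DEA problem
#'
#' @param inputs Numeric matrix (DMUs x m), strictly positive.
#' @param good_outputs Numeric matrix (DMUs x s1), strictly positive
#'   desirable outputs.
#' @param bad_outputs Numeric matrix (DMUs x s2), strictly positive
#'   undesirable outputs, or `NULL` for none.
#' @param units Character identifiers, one per DMU; defaults to row names or
#'   `DMU1..DMUn`.
#' @return An object of class `dea_problem`.
#' @export
#' @examples
#' pr <- dea_problem(inputs = cbind(x = c(1, 2)),
#'                   good_outputs = cbind(y = c(1, 1)), units = c("A", "B"))
#' sbm_efficiency(pr, "B")$rho  # 0.5
dea_problem <- function(inputs, good_outputs, bad_outputs = NULL,
                        units = NULL) {
  inputs <- as.matrix(inputs)
  good_outputs <- as.matrix(good_outputs)
  n <- nrow(inputs)
  if (is.null(bad_outputs)) {
    bad_outputs <- matrix(numeric(0), nrow = n, ncol = 0)
  } else bad_outputs <- as.matrix(bad_outputs)
  if (nrow(good_outputs) != n || nrow(bad_outputs) != n)
    stop("inputs and outputs must have one row per DMU", call. = FALSE)
  if (is.null(units)) units <- rownames(inputs)
  if (is.null(units)) units <- paste0("DMU", seq_len(n))
  if (length(units) != n || anyDuplicated(units))
    stop("`units` must be unique, one per DMU", call. = FALSE)
  vals <- cbind(inputs, good_outputs, bad_outputs)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all DEA quantities must be strictly positive and finite",
         call. = FALSE)
  structure(list(units = as.character(units), inputs = inputs,
                 good_outputs = good_outputs, bad_outputs = bad_outputs),
            class = "dea_problem")
}

#' SBM efficiency of one unit
#'
#' Solves the non-oriented slacks-based measure with undesirable outputs for
#' one DMU as a single linear program (Charnes-Cooper linearization of the
#' fractional program).  Undominated units score exactly 1; scores are
#' invariant to rescaling any input/output column across all DMUs.
#'
#' @param problem A [dea_problem()].
#' @param unit Unit identifier (or index) to score.
#' @param returns_to_scale `"constant"` (default) or `"variable"` (adds the
#'   convexity constraint `sum(lambda) = 1`).
#' @param slack_tol Slacks below this (relative) threshold are treated as
#'   zero when deciding `rho = 1`.
#' @return An `sbm_score`: list with `rho` in (0, 1], `input_slacks`,
#'   `good_output_slacks`, `bad_output_slacks`, `lambdas` (frontier
#'   weights, named by DMU), and `efficient` flag.
#' @export
sbm_efficiency <- function(problem, unit,
                           returns_to_scale = c("constant", "variable"),
                           slack_tol = 1e-7) {
  stopifnot(inherits(problem, "dea_problem"))
  rts <- match.arg(returns_to_scale)
  if (is.character(unit)) {
    o <- match(unit, problem$units)
    if (is.na(o)) stop("unknown unit: ", unit, call. = FALSE)
  } else o <- as.integer(unit)
  X <- problem$inputs; G <- problem$good_outputs; B <- problem$bad_outputs
  n <- nrow(X); m <- ncol(X); s1 <- ncol(G); s2 <- ncol(B)
  so <- s1 + s2

  ## variables: t, Lambda (n), S^- (m), S^g (s1), S^b (s2)   [all >= 0]
  nv <- 1L + n + m + s1 + s2
  iL <- 1L + seq_len(n)
  iSm <- 1L + n + seq_len(m)
  iSg <- 1L + n + m + seq_len(s1)
  iSb <- 1L + n + m + s1 + seq_len(s2)

  obj <- numeric(nv)
  obj[1] <- 1
  obj[iSm] <- -1 / (m * X[o, ])

  ## denominator fixed at 1: t + (1/so)(sum Sg/g_o + sum Sb/b_o) = 1
  e1 <- numeric(nv); e1[1] <- 1
  if (so > 0) {
    if (s1 > 0) e1[iSg] <- 1 / (so * G[o, ])
    if (s2 > 0) e1[iSb] <- 1 / (so * B[o, ])
  }
  rows <- list(e1)
  for (i in seq_len(m)) {
    r <- numeric(nv); r[1] <- X[o, i]; r[iL] <- -X[, i]; r[iSm[i]] <- -1
    rows[[length(rows) + 1L]] <- r
  }
  for (r1 in seq_len(s1)) {
    r <- numeric(nv); r[1] <- G[o, r1]; r[iL] <- -G[, r1]; r[iSg[r1]] <- 1
    rows[[length(rows) + 1L]] <- r
  }
  for (r2 in seq_len(s2)) {
    r <- numeric(nv); r[1] <- B[o, r2]; r[iL] <- -B[, r2]; r[iSb[r2]] <- -1
    rows[[length(rows) + 1L]] <- r
  }
  if (rts == "variable") {
    r <- numeric(nv); r[1] <- -1; r[iL] <- 1
    rows[[length(rows) + 1L]] <- r
  }
  A3 <- do.call(rbind, rows)
  b3 <- c(1, rep(0, nrow(A3) - 1L))

  sol <- lp_solve_eq(obj, A3, b3)
  if (sol$status != "optimal")
    stop(sprintf("SBM linear program did not solve for unit '%s' (%s)",
                 problem$units[o], sol$status), call. = FALSE)
  x <- sol$x
  t <- x[1]
  if (t <= 0)
    stop("degenerate Charnes-Cooper scale (t <= 0); numerical failure",
         call. = FALSE)
  lam <- x[iL] / t
  s_in <- x[iSm] / t
  s_g <- if (s1 > 0) x[iSg] / t else numeric(0)
  s_b <- if (s2 > 0) x[iSb] / t else numeric(0)
  rho <- sol$value

  ## relative slack test for the efficiency call
  rel <- c(s_in / X[o, ],
           if (s1 > 0) s_g / G[o, ] else numeric(0),
           if (s2 > 0) s_b / B[o, ] else numeric(0))
  eff <- all(rel < slack_tol)
  if (eff) { rho <- 1; s_in[] <- 0; s_g[] <- 0; s_b[] <- 0 }
  rho <- min(max(rho, .Machine$double.eps), 1)
  names(lam) <- problem$units
  structure(list(rho = rho, input_slacks = stats::setNames(s_in, colnames(X)),
                 good_output_slacks = stats::setNames(s_g, colnames(G)),
                 bad_output_slacks = stats::setNames(s_b, colnames(B)),
                 lambdas = lam, efficient = eff,
                 unit = problem$units[o], returns_to_scale = rts),
            class = "sbm_score")
}

#' @export
print.sbm_score <- function(x, ...) {
  cat(sprintf("SBM efficiency of %s (%s returns): rho = %.6f%s\n", x$unit,
              x$returns_to_scale, x$rho, if (x$efficient) " (efficient)" else ""))
  invisible(x)
}

#' SBM efficiency of every unit
#'
#' @inheritParams sbm_efficiency
#' @return Named numeric vector of scores.
#' @export
sbm_efficiency_all <- function(problem,
                               returns_to_scale = c("constant", "variable"),
                               slack_tol = 1e-7) {
  rts <- match.arg(returns_to_scale)
  stats::setNames(
    vapply(seq_along(problem$units),
           function(o) sbm_efficiency(problem, o, rts, slack_tol)$rho,
           numeric(1)),
    problem$units)
}

#' Fill the eco-efficiency column of a panel with SBM scores
#'
#' Treats each region-year as a DMU with inputs (labor, capital, energy),
#' desirable output (GDP) and undesirable outputs (SO2, wastewater, solid
#' waste).  With `per_year = TRUE` (default) each calendar year forms its
#' own cross-sectional frontier; otherwise all region-years share one pooled
#' frontier.
#'
#' @param panel A `panel_dataset` with positive DEA columns.
#' @param per_year One frontier per year (default) or pooled.
#' @param returns_to_scale Passed to [sbm_efficiency()].
#' @return The panel with its `ree` column replaced by SBM scores.
#' @export
score_panel <- function(panel, per_year = TRUE,
                        returns_to_scale = c("constant", "variable")) {
  validate_panel(panel)
  rts <- match.arg(returns_to_scale)
  cols <- panel_columns()
  d <- panel$data
  groups <- if (per_year) split(seq_len(nrow(d)), d$year)
            else list(all = seq_len(nrow(d)))
  ree <- rep(NA_real_, nrow(d))
  for (g in names(groups)) {
    idx <- groups[[g]]
    pr <- tryCatch(
      dea_problem(inputs = as.matrix(d[idx, cols$dea_inputs]),
                  good_outputs = as.matrix(d[idx, cols$dea_good, drop = FALSE]),
                  bad_outputs = as.matrix(d[idx, cols$dea_bad]),
                  units = paste(d$region[idx], d$year[idx], sep = ":")),
      error = function(e) stop(sprintf("DEA frontier '%s': %s", g,
                                       conditionMessage(e)), call. = FALSE))
    ree[idx] <- tryCatch(sbm_efficiency_all(pr, rts),
                         error = function(e)
                           stop(sprintf("DEA frontier '%s': %s", g,
                                        conditionMessage(e)), call. = FALSE))
  }
  panel$data$ree <- ree
  panel
}
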