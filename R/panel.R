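## Synthetic panel generator: balanced region x year tables carrying the DEA
## input/output columns, the six control covariates, eco-efficiency (REE) and
## the five public-health demand outcomes.

#' Column groups of a panel dataset
#'
#' Canonical column names used throughout the package: the three DEA inputs
#' (labor, capital, energy), the desirable output (GDP), the three
#' undesirable outputs (SO2, wastewater, industrial solid waste), the six
#' control covariates, and the five hospital-activity outcomes.
#'
#' @return Named list of character vectors: `dea_inputs`, `dea_good`,
#'   `dea_bad`, `controls`, `outcomes`.
#' @export
#' @examples
#' panel_columns()$outcomes
panel_columns <- function() {
  list(
    dea_inputs = c("labor", "capital", "energy"),
    dea_good   = "gdp",
    dea_bad    = c("so2", "wastewater", "solid_waste"),
    controls   = c("gdp_pc", "urbanization", "pop_density",
                   "med_personnel", "licensed_doctors", "health_institutions"),
    outcomes   = c("vth", "owet", "ni", "nohe", "pd")
  )
}

#' Configuration for the synthetic panel generator
#'
#' @param n_regions Number of regions (default 30, one per province-level
#'   unit of the motivating application).
#' @param n_years Number of consecutive years (default 15).
#' @param start_year First calendar year (default 2002).
#' @param noise_sd Relative noise scale for the outcomes, `>= 0`.  Noise is
#'   multiplicative: `y = mu * exp(noise_sd * Z - noise_sd^2 / 2)` with
#'   standard normal `Z`, so outcomes stay strictly positive and the
#'   relative standard deviation is approximately `noise_sd`.
#' @param link Shape of the outcome dependence on eco-efficiency:
#'   `"nonlinear"` (monotone saturating, the default) or `"linear"`.
#' @param signal Which predictors carry signal: `"all"` (REE plus the six
#'   controls) or `"ree_only"` (controls have zero effect).
#' @param seed Integer RNG seed; regeneration with the same configuration is
#'   bit-identical.
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(n_regions = 30L, n_years = 15L, start_year = 2002L,
                         noise_sd = 0.05, link = c("nonlinear", "linear"),
                         signal = c("all", "ree_only"), seed = 1L) {
  link <- match.arg(link)
  signal <- match.arg(signal)
  n_regions <- as.integer(n_regions)
  n_years <- as.integer(n_years)
  if (is.na(n_regions) || n_regions < 2L)
    stop("`n_regions` must be an integer >= 2", call. = FALSE)
  if (is.na(n_years) || n_years < 4L)
    stop("`n_years` must be an integer >= 4", call. = FALSE)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || is.na(noise_sd) ||
      noise_sd < 0)
    stop("`noise_sd` must be a single number >= 0", call. = FALSE)
  structure(
    list(n_regions = n_regions, n_years = n_years,
         start_year = as.integer(start_year), noise_sd = noise_sd,
         link = link, signal = signal, seed = as.integer(seed)),
    class = "panel_config"
  )
}

## reference scales used to put the six controls on comparable footing inside
## the generating function (loosely: 1e4 yuan, fraction, persons/km^2,
## 1e4 persons x3)
.control_scales <- c(gdp_pc = 5, urbanization = 0.5, pop_density = 400,
                     med_personnel = 40, licensed_doctors = 20,
                     health_institutions = 1.5)

## typical magnitude of each outcome (units: 1e8 visits, 1e8 visits,
## 1e4 persons x3), matching the order of magnitude of published tables
.outcome_base_range <- list(
  vth  = c(0.5, 7),    owet = c(0.4, 6),   ni = c(50, 600),
  nohe = c(100, 2000), pd   = c(40, 500)
)

.saturating <- function(ree) ree / (0.5 + ree)

## evaluate the noiseless outcome surface for one region
.region_truth <- function(co, ree, Z, link, outcomes) {
  h <- if (link == "nonlinear") .saturating(ree) else ree
  sapply(outcomes, function(o) {
    cf <- co[[o]]
    if (link == "nonlinear") {
      cf$base * exp(cf$b_ree * h + as.vector(log(Z) %*% cf$b_ctl))
    } else {
      cf$base * (0.5 + cf$b_ree * h + as.vector(Z %*% cf$b_ctl))
    }
  })
}

#' Generate a seeded synthetic regional panel
#'
#' Draws, per region, smooth heterogeneous trajectories for the DEA columns
#' and the six controls, a saturating eco-efficiency path in (0, 1), and
#' outcomes that are a known (recorded) function of eco-efficiency and the
#' controls times multiplicative noise.  The noiseless surface and the
#' per-region coefficients are kept in the `truth` slot so recovery tests can
#' compare forecasts against the generating function.
#'
#' @param config A [panel_config()].
#' @return An object of class `panel_dataset`: a list with `data` (one row
#'   per region-year), `config`, and `truth` (noiseless outcomes plus
#'   generating coefficients).
#' @export
#' @examples
#' p <- generate_panel(panel_config(n_regions = 4, n_years = 6, seed = 1))
#' nrow(p$data)  # 24
generate_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  cols <- panel_columns()
  P <- config$n_regions; N <- config$n_years
  regions <- sprintf("R%02d", seq_len(P))
  years <- config$start_year + seq_len(N) - 1L
  tt <- seq_len(N)

  out <- with_seed(config$seed, {
    rows <- vector("list", P)
    truth_rows <- vector("list", P)
    coefs <- vector("list", P)
    names(coefs) <- regions
    for (p in seq_len(P)) {
      ## eco-efficiency: logistic rise between region-specific floors/ceilings
      lo <- runif(1, 0.15, 0.35); hi <- runif(1, 0.55, 0.95)
      kk <- runif(1, 0.3, 0.8);   mm <- runif(1, 0.3 * N, 0.7 * N)
      ree <- lo + (hi - lo) / (1 + exp(-kk * (tt - mm)))

      growth <- function(base, g) base * (1 + g)^(tt - 1)
      ## controls: decelerating (logistic) trends with region-specific
      ## amplitude, rate and midpoint -- development series plateau rather
      ## than compound forever -- times a smooth cyclical component whose
      ## period fits inside the sample, so held-out years stay within the
      ## observed range while the covariates carry variation that the
      ## monotone eco-efficiency path cannot proxy
      sat <- function(base, amp, k, m)
        base * (1 + amp / (1 + exp(-k * (tt - m))))
      rsat <- function(lo, hi, amp_max)
        sat(runif(1, lo, hi), runif(1, 0.4, amp_max),
            runif(1, 0.3, 0.7), runif(1, 0.25 * N, 0.6 * N))
      cyc <- function(v) {
        a <- runif(1, 0.1, 0.2); Tj <- runif(1, 4, 9); ph <- runif(1, 0, Tj)
        v * (1 + a * sin(2 * pi * (tt - ph) / Tj))
      }
      ctl <- cbind(
        gdp_pc = cyc(rsat(1, 8, 3)),
        urbanization = 0.2 + runif(1, 0.3, 0.7) /
          (1 + exp(-runif(1, 0.2, 0.6) * (tt - runif(1, 0.3 * N, 0.6 * N)))),
        pop_density = cyc(rsat(50, 800, 0.6)),
        med_personnel = cyc(rsat(10, 80, 2)),
        licensed_doctors = cyc(rsat(5, 40, 1.5)),
        health_institutions = cyc(rsat(0.5, 3, 1))
      )

      ## DEA columns: positive smooth trends (bads may decline)
      dea <- cbind(
        labor = growth(runif(1, 200, 3000), runif(1, 0, 0.02)),
        capital = growth(runif(1, 1000, 20000), runif(1, 0.08, 0.15)),
        energy = growth(runif(1, 500, 15000), runif(1, 0.03, 0.08)),
        gdp = growth(runif(1, 1000, 30000), runif(1, 0.07, 0.14)),
        so2 = growth(runif(1, 20, 150), runif(1, -0.03, 0.01)),
        wastewater = growth(runif(1, 5, 80), runif(1, -0.02, 0.02)),
        solid_waste = growth(runif(1, 10, 100), runif(1, -0.02, 0.02))
      )

      ## outcome coefficients for this region
      co <- lapply(cols$outcomes, function(o) {
        rng <- .outcome_base_range[[o]]
        b_ctl <- if (config$signal == "all") {
          if (config$link == "nonlinear") runif(6, 0.2, 0.5)
          else runif(6, 0.1, 0.4)
        } else rep(0, 6)
        list(base = runif(1, rng[1], rng[2]),
             b_ree = runif(1, 0.8, 1.6),
             b_ctl = b_ctl)
      })
      names(co) <- cols$outcomes
      coefs[[p]] <- co

      Z <- sweep(ctl, 2, .control_scales[colnames(ctl)], "/")
      mu <- .region_truth(co, ree, Z, config$link, cols$outcomes)
      noise <- matrix(stats::rnorm(N * length(cols$outcomes)), N)
      y <- mu * exp(config$noise_sd * noise - config$noise_sd^2 / 2)

      rows[[p]] <- data.frame(region = regions[p], year = years, dea, ctl,
                              ree = ree, y, check.names = FALSE)
      truth_rows[[p]] <- data.frame(region = regions[p], year = years, mu,
                                    check.names = FALSE)
    }
    list(data = do.call(rbind, rows),
         truth = list(noiseless = do.call(rbind, truth_rows), coefs = coefs))
  })

  dat <- out$data
  rownames(dat) <- NULL
  rownames(out$truth$noiseless) <- NULL
  res <- structure(list(data = dat, config = config, truth = out$truth),
                   class = "panel_dataset")
  validate_panel(res)
  res
}

#' Validate panel invariants
#'
#' Checks the balanced-panel property (every region-year exactly once) and
#' strict positivity / finiteness of all DEA quantities and outcomes.
#'
#' @param panel A `panel_dataset`.
#' @param require_ree Require the `ree` column to be filled and in (0, 1]?
#' @return The panel, invisibly; stops on violation.
#' @export
validate_panel <- function(panel, require_ree = FALSE) {
  stopifnot(inherits(panel, "panel_dataset"))
  d <- panel$data
  cols <- panel_columns()
  need <- c("region", "year", cols$dea_inputs, cols$dea_good, cols$dea_bad,
            cols$controls, cols$outcomes)
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("panel is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  key <- paste(d$region, d$year)
  if (anyDuplicated(key))
    stop("panel is not balanced: duplicated region-year cells", call. = FALSE)
  tab <- table(d$region)
  if (length(unique(tab)) != 1L)
    stop("panel is not balanced: regions differ in year coverage",
         call. = FALSE)
  num <- c(cols$dea_inputs, cols$dea_good, cols$dea_bad, cols$outcomes)
  v <- as.matrix(d[num])
  if (!all(is.finite(v)) || any(v <= 0))
    stop("DEA quantities and outcomes must be strictly positive and finite",
         call. = FALSE)
  if (require_ree) {
    r <- d$ree
    if (anyNA(r) || any(r <= 0 | r > 1))
      stop("`ree` must be filled and lie in (0, 1]", call. = FALSE)
  }
  invisible(panel)
}

#' Generate a panel with known DEA frontier membership
#'
#' Builds, for each year, `n_efficient` units on a common linear technology
#' (desirable output equal to the sum of inputs, undesirable outputs
#' proportional to it) -- mutually undominated by construction -- and fills
#' the remaining units with dominated copies of randomly chosen frontier
#' units whose inputs and undesirable outputs are inflated by known factors.
#' True efficiency status is recorded in `truth$efficient`.
#'
#' @param config A [panel_config()].
#' @param n_efficient Number of frontier units per year, in
#'   `[1, n_regions]`.
#' @return A `panel_dataset` whose `truth` additionally holds `efficient`
#'   (data.frame region, year, efficient flag, inflation factor).
#' @export
generate_dea_frontier_panel <- function(config, n_efficient) {
  stopifnot(inherits(config, "panel_config"))
  n_efficient <- as.integer(n_efficient)
  if (is.na(n_efficient) || n_efficient < 1L ||
      n_efficient > config$n_regions)
    stop("`n_efficient` must be in [1, n_regions]", call. = FALSE)
  panel <- generate_panel(config)
  cols <- panel_columns()
  d <- panel$data
  P <- config$n_regions
  beta <- c(0.02, 0.015, 0.01)  # bads per unit of good output

  eff <- with_seed(config$seed + 1L, {
    recs <- vector("list", 0L)
    for (yr in unique(d$year)) {
      idx <- which(d$year == yr)
      front <- idx[seq_len(n_efficient)]
      X <- matrix(runif(n_efficient * 3, 1, 10), n_efficient)
      g <- rowSums(X)
      d[front, cols$dea_inputs] <- X
      d[front, cols$dea_good] <- g
      d[front, cols$dea_bad] <- outer(g, beta)
      dom <- setdiff(idx, front)
      fac <- rep(NA_real_, length(idx))
      if (length(dom)) {
        src <- front[sample.int(n_efficient, length(dom), replace = TRUE)]
        f <- runif(length(dom), 1.3, 2.5)
        d[dom, cols$dea_inputs] <- d[src, cols$dea_inputs] * f
        d[dom, cols$dea_good] <- d[src, cols$dea_good]
        d[dom, cols$dea_bad] <- d[src, cols$dea_bad] *
          runif(length(dom), 1.2, 2)
        fac[match(dom, idx)] <- f
      }
      recs[[length(recs) + 1L]] <- data.frame(
        region = d$region[idx], year = yr,
        efficient = idx %in% front, inflation = fac)
    }
    do.call(rbind, recs)
  })
  panel$data <- d
  panel$truth$efficient <- eff
  validate_panel(panel)
  panel
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat(sprintf("panel_dataset: %d regions x %d years (%d rows)\n",
              length(unique(x$data$region)), length(unique(x$data$year)),
              nrow(x$data)))
  cat(sprintf("  link=%s signal=%s noise_sd=%g seed=%d\n",
              x$config$link, x$config$signal, x$config$noise_sd,
              x$config$seed))
  invisible(x)
}

#' Write / read a panel as long-format CSV
#'
#' Plain UTF-8 CSV with header `region, year`, then the named variable
#' columns; `.` decimal separator.  The `truth` slot is not serialized.
#'
#' @param panel A `panel_dataset`.
#' @param file Path to the CSV file.
#' @return `write_panel_csv` returns `file` invisibly; `read_panel_csv`
#'   returns a `panel_dataset` (with `config` and `truth` set to `NULL`).
#' @export
write_panel_csv <- function(panel, file) {
  stopifnot(inherits(panel, "panel_dataset"))
  utils::write.csv(panel$data, file, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(file)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE,
                       fileEncoding = "UTF-8")
  res <- structure(list(data = d, config = NULL, truth = NULL),
                   class = "panel_dataset")
  validate_panel(res)
  res
}
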