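test_that("panel_config validates its arguments", {
  expect_error(panel_config(n_regions = 1), "n_regions")
  expect_error(panel_config(n_years = 3), "n_years")
  expect_error(panel_config(noise_sd = -0.1), "noise_sd")
  cfg <- panel_config()
  expect_equal(cfg$n_regions, 30L)
  expect_equal(cfg$n_years, 15L)
  expect_equal(cfg$start_year, 2002L)
})

test_that("generation is seeded and bit-identical on regeneration", {
  a <- generate_panel(panel_config(n_regions = 5, n_years = 6, seed = 7))
  b <- generate_panel(panel_config(n_regions = 5, n_years = 6, seed = 7))
  expect_identical(a$data, b$data)
  expect_identical(a$truth$noiseless, b$truth$noiseless)
  c <- generate_panel(panel_config(n_regions = 5, n_years = 6, seed = 8))
  expect_false(identical(a$data, c$data))
})

test_that("the default panel is balanced with 30 x 15 region-years", {
  p <- generate_panel(panel_config(seed = 2))
  expect_equal(nrow(p$data), 30 * 15)
  expect_equal(length(unique(p$data$region)), 30)
  expect_equal(sort(unique(p$data$year)), 2002:2016)
  expect_equal(anyDuplicated(paste(p$data$region, p$data$year)), 0L)
})

test_that("all generated quantities are positive and finite, ree in (0,1)", {
  for (seed in 1:3) {
    p <- small_panel(seed = seed, noise_sd = 0.3)
    cols <- panel_columns()
    v <- as.matrix(p$data[c(cols$dea_inputs, cols$dea_good, cols$dea_bad,
                            cols$controls, cols$outcomes)])
    expect_true(all(is.finite(v)))
    expect_true(all(v > 0))
    expect_true(all(p$data$ree > 0 & p$data$ree < 1))
  }
})

test_that("zero noise makes outcomes equal the recorded truth exactly", {
  p <- small_panel(seed = 4, noise_sd = 0)
  oc <- panel_columns()$outcomes
  expect_equal(as.matrix(p$data[oc]), as.matrix(p$truth$noiseless[oc]),
               ignore_attr = TRUE)
})

test_that("noisy outcomes scatter multiplicatively around the truth", {
  p <- small_panel(seed = 5, noise_sd = 0.1, n_regions = 10, n_years = 15)
  oc <- panel_columns()$outcomes
  rel <- as.matrix(p$data[oc]) / as.matrix(p$truth$noiseless[oc])
  expect_true(all(rel > 0))
  expect_equal(sd(log(rel)), 0.1, tolerance = 0.15)
})

test_that("ree_only panels carry no control signal in the truth", {
  p <- small_panel(seed = 6, signal = "ree_only")
  for (co in p$truth$coefs) for (o in co)
    expect_equal(o$b_ctl, rep(0, 6))
})

test_that("frontier fixture records exactly n_efficient frontier units per year", {
  cfg <- panel_config(n_regions = 6, n_years = 4, seed = 2)
  fp <- generate_dea_frontier_panel(cfg, n_efficient = 3)
  eff <- fp$truth$efficient
  per_year <- tapply(eff$efficient, eff$year, sum)
  expect_true(all(per_year == 3))
  expect_true(all(eff$inflation[!eff$efficient] > 1))
  expect_error(generate_dea_frontier_panel(cfg, 0), "n_efficient")
  expect_error(generate_dea_frontier_panel(cfg, 7), "n_efficient")
})

test_that("frontier units are mutually undominated; inflated copies are dominated", {
  cfg <- panel_config(n_regions = 7, n_years = 4, seed = 9)
  fp <- generate_dea_frontier_panel(cfg, n_efficient = 4)
  cols <- panel_columns()
  d <- fp$data
  eff <- fp$truth$efficient
  for (yr in unique(d$year)) {
    idx <- which(d$year == yr)
    X <- as.matrix(d[idx, cols$dea_inputs])
    G <- as.matrix(d[idx, cols$dea_good, drop = FALSE])
    B <- as.matrix(d[idx, cols$dea_bad])
    flag <- eff$efficient[match(paste(d$region[idx], d$year[idx]),
                                paste(eff$region, eff$year))]
    dom <- vapply(seq_along(idx), function(o) is_dominated(X, G, B, o),
                  logical(1))
    expect_true(all(!dom[flag]))
    expect_true(all(dom[!flag]))
  }
})

test_that("all-efficient construction leaves every unit undominated", {
  cfg <- panel_config(n_regions = 5, n_years = 4, seed = 3)
  fp <- generate_dea_frontier_panel(cfg, n_efficient = 5)
  expect_true(all(fp$truth$efficient$efficient))
  f2 <- generate_dea_frontier_panel(cfg, n_efficient = 5)
  expect_identical(fp$data, f2$data)
  expect_identical(fp$truth$efficient, f2$truth$efficient)
})

test_that("panel CSV round-trips through write/read", {
  p <- small_panel(seed = 10)
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel_csv(p, f)
  q <- read_panel_csv(f)
  expect_equal(q$data$region, p$data$region)
  num <- vapply(p$data, is.numeric, logical(1))
  expect_equal(as.matrix(q$data[num]), as.matrix(p$data[num]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("validate_panel rejects broken panels", {
  p <- small_panel(seed = 1)
  p$data$gdp[3] <- -1
  expect_error(validate_panel(p), "positive")
  q <- small_panel(seed = 1)
  q$data <- q$data[-1, ]
  expect_error(validate_panel(q), "balanced")
})
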