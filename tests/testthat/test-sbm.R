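test_that("dea_problem validates data", {
  expect_error(dea_problem(cbind(c(1, -1)), cbind(c(1, 1))), "positive")
  expect_error(dea_problem(cbind(1:2), cbind(1:3)), "one row per DMU")
  expect_error(dea_problem(cbind(1:2), cbind(1:2), units = c("A", "A")),
               "unique")
})

test_that("a single DMU scores 1 with zero slacks", {
  pr <- dea_problem(cbind(x = 2), cbind(y = 3), cbind(b = 1))
  sc <- sbm_efficiency(pr, 1)
  expect_equal(sc$rho, 1)
  expect_true(sc$efficient)
  expect_equal(unname(sc$input_slacks), 0)
})

test_that("the hand-solved 2-DMU instance gives rho = 0.5 for the dominated unit", {
  pr <- dea_problem(inputs = cbind(x = c(1, 2)),
                    good_outputs = cbind(y = c(1, 1)), units = c("A", "B"))
  expect_equal(sbm_efficiency(pr, "B")$rho, 0.5, tolerance = 1e-9)
  expect_equal(sbm_efficiency(pr, "A")$rho, 1)
})

test_that("identical DMUs all score 1", {
  pr <- dea_problem(matrix(2, 4, 2), matrix(3, 4, 1), matrix(1, 4, 1))
  expect_equal(unname(sbm_efficiency_all(pr)), rep(1, 4))
})

test_that("scores are invariant to rescaling any single column by 1000", {
  set.seed(5)
  n <- 8
  X <- matrix(runif(n * 3, 1, 10), n)
  G <- matrix(runif(n, 1, 10), n)
  B <- matrix(runif(n * 2, 1, 10), n)
  base <- sbm_efficiency_all(dea_problem(X, G, B))
  for (col in 1:3) {
    X2 <- X; X2[, col] <- X2[, col] * 1000
    expect_lt(max(abs(sbm_efficiency_all(dea_problem(X2, G, B)) - base)),
              1e-9)
  }
  B2 <- B; B2[, 1] <- B2[, 1] * 1000
  expect_lt(max(abs(sbm_efficiency_all(dea_problem(X, G, B2)) - base)), 1e-9)
})

test_that("rho matches the dominance oracle on random instances", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 7
    X <- matrix(runif(n * 2, 1, 10), n)
    G <- matrix(runif(n, 1, 10), n)
    B <- matrix(runif(n, 1, 10), n)
    # plant one clearly dominated unit
    X[n, ] <- X[1, ] * 2; G[n, ] <- G[1, ]; B[n, ] <- B[1, ] * 1.5
    pr <- dea_problem(X, G, B)
    rho <- sbm_efficiency_all(pr)
    for (o in seq_len(n)) {
      if (is_dominated(X, G, B, o)) expect_lt(rho[o], 1)
      expect_gt(rho[o], 0)
      expect_lte(rho[o], 1)
    }
    expect_lt(rho[n], 1)
  }
})

test_that("rho agrees with an independent simplex solve on non-degenerate units", {
  skip_if_not_installed("boot")
  set.seed(11)
  n <- 6; m <- 2; s1 <- 1; s2 <- 1; so <- s1 + s2
  X <- matrix(runif(n * m, 1, 10), n)
  G <- matrix(runif(n * s1, 1, 10), n)
  B <- matrix(runif(n * s2, 1, 10), n)
  pr <- dea_problem(X, G, B)
  for (o in 1:n) {
    nv <- 1 + n + m + s1 + s2
    iL <- 1 + 1:n; iSm <- 1 + n + 1:m; iSg <- 1 + n + m + 1:s1
    iSb <- 1 + n + m + s1 + 1:s2
    obj <- numeric(nv); obj[1] <- 1; obj[iSm] <- -1 / (m * X[o, ])
    e1 <- numeric(nv); e1[1] <- 1
    e1[iSg] <- 1 / (so * G[o, ]); e1[iSb] <- 1 / (so * B[o, ])
    rows <- list(e1)
    for (i in 1:m) { r <- numeric(nv); r[1] <- X[o, i]; r[iL] <- -X[, i]
      r[iSm[i]] <- -1; rows[[length(rows) + 1]] <- r }
    for (k in 1:s1) { r <- numeric(nv); r[1] <- G[o, k]; r[iL] <- -G[, k]
      r[iSg[k]] <- 1; rows[[length(rows) + 1]] <- r }
    for (k in 1:s2) { r <- numeric(nv); r[1] <- B[o, k]; r[iL] <- -B[, k]
      r[iSb[k]] <- -1; rows[[length(rows) + 1]] <- r }
    # boot::simplex can fail on degenerate pivots; compare where it solves
    sol <- tryCatch(
      boot::simplex(a = obj, A3 = do.call(rbind, rows),
                    b3 = c(1, rep(0, m + s1 + s2)), maxi = FALSE,
                    n.iter = 1000),
      error = function(e) NULL)
    if (!is.null(sol) && sol$solved == 1)
      expect_equal(sbm_efficiency(pr, o)$rho, unname(sol$value),
                   tolerance = 1e-7)
  }
})

test_that("inflating a unit's input or bad output never raises its score", {
  set.seed(21)
  n <- 6
  X <- matrix(runif(n * 2, 1, 10), n)
  G <- matrix(runif(n, 1, 10), n)
  B <- matrix(runif(n, 1, 10), n)
  base <- sbm_efficiency_all(dea_problem(X, G, B))
  for (o in c(1, 4)) {
    X2 <- X; X2[o, 1] <- X2[o, 1] * 1.5
    expect_lte(sbm_efficiency(dea_problem(X2, G, B), o)$rho,
               base[o] + 1e-9)
    B2 <- B; B2[o, 1] <- B2[o, 1] * 1.5
    expect_lte(sbm_efficiency(dea_problem(X, G, B2), o)$rho,
               base[o] + 1e-9)
  }
})

test_that("variable returns to scale never scores below constant returns", {
  set.seed(31)
  n <- 8
  pr <- dea_problem(matrix(runif(n * 2, 1, 10), n),
                    matrix(runif(n, 1, 10), n), matrix(runif(n, 1, 10), n))
  crs <- sbm_efficiency_all(pr, "constant")
  vrs <- sbm_efficiency_all(pr, "variable")
  expect_true(all(vrs >= crs - 1e-8))
})

test_that("score_panel fills ree per-year and honours frontier truth", {
  cfg <- panel_config(n_regions = 6, n_years = 4, seed = 2)
  fp <- generate_dea_frontier_panel(cfg, n_efficient = 3)
  sp <- score_panel(fp)
  expect_true(all(sp$data$ree > 0 & sp$data$ree <= 1))
  key <- paste(sp$data$region, sp$data$year)
  eff <- fp$truth$efficient
  flag <- eff$efficient[match(key, paste(eff$region, eff$year))]
  expect_true(all(sp$data$ree[flag] == 1))
  expect_true(all(sp$data$ree[!flag] < 1))
})

test_that("pooled scoring gives one frontier across years", {
  p <- small_panel(seed = 3, n_regions = 4, n_years = 4)
  pooled <- score_panel(p, per_year = FALSE)
  per_year <- score_panel(p, per_year = TRUE)
  expect_true(all(pooled$data$ree <= per_year$data$ree + 1e-7))
})
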