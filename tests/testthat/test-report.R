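res_fixture <- function() {
  p <- small_panel(seed = 8, n_regions = 2, n_years = 8)
  run_experiment(p, variants = 1, outcomes = c("vth", "nohe"), holdout = 2,
                 search_cfg = search_config(seed = 1, max_iter = 5))
}

test_that("csv tables have one row per region plus an Average row", {
  res <- res_fixture()
  dir <- withr::local_tempdir()
  files <- render_tables(res, dir)
  expect_length(files, 2)  # one variant x two column groups
  tab <- utils::read.csv(files[1])
  expect_equal(nrow(tab), 3)  # 2 regions + Average
  expect_equal(tab$region[3], "Average")
  expect_equal(names(tab), c("region", "vth_mpe", "vth_mse", "vth_sde"))
  # formatted to 5 decimals
  raw <- readLines(files[1])[2]
  expect_match(raw, "^R01(,-?\\d+\\.\\d{5}){3}$")
})

test_that("the Average row equals the averages table after rounding", {
  res <- res_fixture()
  dir <- withr::local_tempdir()
  files <- render_tables(res, dir)
  tab <- utils::read.csv(files[1])
  avg <- res$averages[res$averages$outcome == "vth", ]
  expect_equal(tab$vth_mpe[3], round(avg$mpe, 5), tolerance = 1e-9)
})

test_that("markdown tables mark the Average row in bold", {
  res <- res_fixture()
  dir <- withr::local_tempdir()
  files <- render_tables(res, dir, style = "markdown")
  lines <- readLines(files[1])
  expect_match(lines[1], "^\\| region")
  expect_match(lines[length(lines)], "\\*\\*Average\\*\\*")
})

test_that("rendering is pure and re-rendering is byte-identical", {
  res <- res_fixture()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  before <- res
  f1 <- render_tables(res, d1)
  f2 <- render_tables(res, d2)
  expect_identical(res, before)
  for (i in seq_along(f1))
    expect_identical(readLines(f1[i]), readLines(f2[i]))
})

test_that("an empty region set renders a header-only table", {
  res <- res_fixture()
  res$cells <- res$cells[0, ]
  dir <- withr::local_tempdir()
  files <- render_tables(res, dir)
  tab <- utils::read.csv(files[1])
  expect_equal(nrow(tab), 1)  # only the (empty) Average row remains
})

test_that("the run manifest lists every output with its checksum", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.csv"); writeLines("x", f1)
  f2 <- file.path(dir, "b.csv"); writeLines("y", f2)
  mf <- file.path(dir, "manifest.txt")
  write_run_manifest(list(seed = 3), c(f1, f2),
                     c(simulate = 0.1, forecast = 1.2), mf)
  lines <- readLines(mf)
  expect_true(any(grepl("seed: 3", lines)))
  expect_true(any(grepl("a.csv", lines)))
  expect_true(any(grepl("b.csv", lines)))
  expect_true(any(grepl("config_md5: [0-9a-f]{32}", lines)))
})

test_that("the workflow reruns byte-identically from one configuration", {
  cfg <- workflow_config(seed = 5)
  cfg$panel$n_regions <- 3L; cfg$panel$n_years <- 8L
  cfg$forecast$variants <- 1L
  cfg$forecast$outcomes <- c("vth", "pd")
  cfg$forecast$holdout <- 2L
  cfg$forecast$search$max_iter <- 8L
  cfg$sbm$use_sbm_ree <- TRUE
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg$output_dir <- d1
  r1 <- run_workflow(cfg, quiet = TRUE)
  cfg$output_dir <- d2
  r2 <- run_workflow(cfg, quiet = TRUE)
  csv1 <- sort(basename(Sys.glob(file.path(d1, "*.csv"))))
  expect_true(length(csv1) >= 4)
  for (f in csv1)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("a YAML configuration file drives the same workflow", {
  cfg <- workflow_config(seed = 5)
  cfg$panel$n_regions <- 3L; cfg$panel$n_years <- 8L
  cfg$forecast$variants <- 1L
  cfg$forecast$outcomes <- "vth"
  cfg$forecast$holdout <- 2L
  cfg$forecast$search$max_iter <- 5L
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg$output_dir <- d1
  r1 <- run_workflow(cfg, quiet = TRUE)
  yml <- withr::local_tempfile(fileext = ".yaml")
  cfg$output_dir <- d2
  yaml::write_yaml(cfg, yml)
  r2 <- run_workflow(yml, quiet = TRUE)
  expect_identical(readLines(file.path(d1, "cells.csv")),
                   readLines(file.path(d2, "cells.csv")))
})
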