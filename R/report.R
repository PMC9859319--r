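## Table rendering and the reproducibility manifest.

## outcome display names used in table headers
.outcome_labels <- c(
  vth = "Visits (100 Million)",
  owet = "Outpatients with Emergency Treatment (100 Million)",
  ni = "Number of Inpatients (10,000 Persons)",
  nohe = "Number of Health Examinations (10,000 Persons)",
  pd = "Patients Discharged (10,000 Persons)")

## wide per-variant table: region rows, MPE/MSE/SDE per outcome, Average last
.variant_table <- function(result, variant, outcomes) {
  cells <- result$cells[result$cells$variant == variant, , drop = FALSE]
  regions <- unique(cells$region)
  avg_src <- cells[!cells$region %in% result$exclude_from_average, ,
                   drop = FALSE]
  rows <- lapply(c(regions, "Average"), function(r) {
    vals <- unlist(lapply(outcomes, function(o) {
      sub <- if (r == "Average") avg_src[avg_src$outcome == o, , drop = FALSE]
             else cells[cells$region == r & cells$outcome == o, , drop = FALSE]
      if (nrow(sub) == 0L) return(c(NA_real_, NA_real_, NA_real_))
      c(mean(sub$mpe), mean(sub$mse), mean(sub$sde))
    }))
    data.frame(region = r, t(vals))
  })
  tab <- do.call(rbind, rows)
  names(tab) <- c("region",
                  as.vector(t(outer(outcomes, c("mpe", "mse", "sde"),
                                    paste, sep = "_"))))
  tab
}

#' Render experiment results as per-variant tables
#'
#' Writes one file per (variant, column-group) pair: the five outcomes are
#' split into a first group (visits, emergency outpatients, inpatients) and
#' a second (health examinations, discharges), each with MPE/MSE/SDE
#' columns per outcome and an `Average` row last (rendered in bold in
#' markdown).  Numbers are printed with 5 decimal places.  Rendering is
#' pure: the result object is not modified, and re-rendering the same
#' result is byte-identical.
#'
#' @param result An `experiment_result`.
#' @param dir Output directory (created if needed).
#' @param style `"csv"` (default) or `"markdown"`.
#' @param prefix Filename prefix (default `"table"`).
#' @return Character vector of the files written, invisibly.
#' @export
render_tables <- function(result, dir, style = c("csv", "markdown"),
                          prefix = "table") {
  stopifnot(inherits(result, "experiment_result"))
  style <- match.arg(style)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  canonical <- panel_columns()$outcomes
  oc <- result$outcomes
  halves <- if (all(oc %in% canonical)) {
    h1 <- intersect(c("vth", "owet", "ni"), oc)
    h2 <- intersect(c("nohe", "pd"), oc)
    Filter(length, list(h1, h2))
  } else {
    k <- ceiling(length(oc) / 2)
    Filter(length, list(oc[seq_len(k)], oc[-seq_len(k)]))
  }
  ext <- if (style == "csv") "csv" else "md"
  files <- character(0)
  for (v in result$variants) {
    for (h in seq_along(halves)) {
      tab <- .variant_table(result, v, halves[[h]])
      num <- names(tab)[-1]
      tab[num] <- lapply(tab[num], fmt_num)
      file <- file.path(dir, sprintf("%s_variant%d_part%d.%s", prefix, v,
                                     h, ext))
      if (style == "csv") {
        utils::write.csv(tab, file, row.names = FALSE, quote = FALSE)
      } else {
        tab$region[tab$region == "Average"] <- "**Average**"
        lines <- c(paste0("| ", paste(names(tab), collapse = " | "), " |"),
                   paste0("|", paste(rep("---", ncol(tab)), collapse = "|"),
                          "|"),
                   apply(tab, 1, function(r)
                     paste0("| ", paste(r, collapse = " | "), " |")))
        writeLines(lines, file)
      }
      files <- c(files, file)
    }
  }
  invisible(files)
}

#' Write a stability table as CSV
#'
#' @param stability Output of [stability_analysis()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_stability_csv <- function(stability, file) {
  tab <- stability
  tab$average_degree <- fmt_num(tab$average_degree)
  tab$variation_degree <- fmt_num(tab$variation_degree)
  utils::write.csv(tab, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write a reproducibility manifest
#'
#' Plain-text record of the run: configuration hash (md5 of the canonical
#' deparse), seeds, package and R versions, per-stage timings, and the md5
#' of every output file.
#'
#' @param config The workflow configuration list.
#' @param files Character vector of output files.
#' @param timings Named numeric vector of per-stage elapsed seconds.
#' @param file Manifest path.
#' @return `file`, invisibly.
#' @export
write_run_manifest <- function(config, files, timings, file) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[order(names(config))]), tmp)
  chash <- unname(tools::md5sum(tmp))
  lines <- c(
    "# run manifest",
    paste("config_md5:", chash),
    paste("seed:", config$seed),
    paste("r_version:", R.version.string),
    paste("package_version:",
          as.character(utils::packageVersion("reeforecast"))),
    "timings_seconds:",
    sprintf("  %s: %.3f", names(timings), timings),
    "outputs:",
    sprintf("  %s: %s", basename(files), unname(tools::md5sum(files)))
  )
  writeLines(lines, file)
  invisible(file)
}
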