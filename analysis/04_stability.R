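#!/usr/bin/env Rscript
# Stage 4: stability of the forecast errors across the 3-year horizon.
# For each (outcome, variant, metric): average degree = mean absolute
# year-over-year change of the per-region error series; variation degree =
# the standard deviation of those changes.  Lower is more stable.

library(reeforecast)

per_year <- utils::read.csv("results/per_year.csv")
res <- structure(list(per_year = per_year, holdout = 3L),
                 class = "experiment_result")
stab <- stability_analysis(res)
write_stability_csv(stab, "results/stability.csv")

cat("stability (average degree of the MPE series, by variant):\n")
m <- stab[stab$metric == "mpe", ]
print(stats::aggregate(m["average_degree"], by = m["variant"], mean),
      row.names = FALSE)
wins <- sapply(split(stab, stab[c("outcome", "metric")]), function(s)
  s$variant[which.min(s$average_degree)])
cat("variant with the lowest average degree per (outcome, metric):\n")
print(table(wins))
cat("wrote results/stability.csv\n")
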