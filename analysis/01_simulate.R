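#!/usr/bin/env Rscript
# Simulate the 2012 study: three raw report streams at the published
# per-drug price levels and counts, with the crowdsourced contamination
# the credibility filters are designed to absorb. Writes the raw dialect
# CSVs (plus the daily BTC exchange-rate table) under results/data/.

suppressPackageStartupMessages(library(streetpricer))

seed <- 20120630
params <- default_generator_params(seed = seed)
reports <- generate_reports(params)
paths <- write_source_csvs(reports, "results/data")

cat("Simulated report streams (seed", seed, "):\n")
print(table(reports$source))
cat("\nInjected contamination (crowdsourced stream):\n")
cat("  endpoint-rated (1/5):", sum(reports$rating %in% c(1L, 5L)), "\n")
cat("  duplicate clones:   ", sum(grepl("^syn-dp", reports$report_id)), "\n")
cat("  missing strength:   ", sum(is.na(reports$strength_mg)), "\n")
cat("  bulk-flagged:       ", sum(reports$bulk_flag == "yes"), "\n")
cat("\nWrote:\n")
for (p in paths) cat("  ", p, "\n")
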