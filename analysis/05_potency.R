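#!/usr/bin/env Rscript
# Predicted relative potency: each drug's crowdsourced geometric-mean
# price per mg divided by morphine's, with a bootstrap log-ratio CI,
# compared against the VA/DoD 2012 clinical equianalgesic factors.

suppressPackageStartupMessages(library(streetpricer))

kept <- read_normalized_reports("results/reports_filtered.csv")
crowd <- kept[kept$source == "crowdsourced", ]
summaries <- summarize_prices(crowd)

pot <- predicted_relative_potency(summaries, reports = crowd,
                                  n_boot = 2000, seed = 20120630)
cat("Predicted relative potency (street price ratio vs morphine):\n")
print(as.data.frame(pot), digits = 3)
render_tables(summarize_prices(kept), pot, "results")
cat("\nWrote results/potency_table.csv (and .json).\n")
cat("Note: market valuation, not clinical guidance - never use these\n")
cat("ratios for dose conversion.\n")
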