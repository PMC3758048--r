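#!/usr/bin/env Rscript
# Cross-source validation: Spearman rank correlation of per-drug mean
# prices for each source pair (with exact permutation p-values), plus a
# per-drug Welch ANOVA on log prices for source-level price differences.

suppressPackageStartupMessages(library(streetpricer))

kept <- read_normalized_reports("results/reports_filtered.csv")
summaries <- summarize_prices(kept)

cm <- cross_source_matrix(summaries)
cat("Cross-source agreement on per-drug geometric means:\n")
print(as.data.frame(cm), digits = 3)
jsonlite::write_json(cm, "results/correlations.json", digits = NA,
                     pretty = TRUE)

tests <- compare_all_drugs(kept)
cat("\nPer-drug price differences across sources (Welch ANOVA on logs):\n")
print(as.data.frame(tests), digits = 3)
readr::write_csv(tests, "results/drug_tests.csv")
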