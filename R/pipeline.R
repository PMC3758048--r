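#' Pipeline configuration
#'
#' Paths and settings for a full run: ingest the three source dialects,
#' filter, estimate per-source geometric means, cross-validate sources,
#' and compute predicted relative potency. Any source path may be `NULL`
#' to run on a subset of streams.
#'
#' @param crowdsourced_path,law_enforcement_path,marketplace_path CSV
#'   paths in the dialects documented in [read_reports()].
#' @param rates_path exchange-rate CSV (required when the marketplace file
#'   prices in BTC).
#' @param out_dir output directory for the artifact bundle.
#' @param filter a [filter_config()].
#' @param alpha two-sided error rate for all CIs.
#' @param equianalgesic_path optional CSV overriding the packaged
#'   conversion table.
#' @param potency_source which source's summaries feed the potency table.
#' @param n_boot bootstrap resamples for the potency ratio CIs.
#' @param seed RNG seed for the bootstrap.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(crowdsourced_path = NULL,
                            law_enforcement_path = NULL,
                            marketplace_path = NULL,
                            rates_path = NULL,
                            out_dir,
                            filter = filter_config(),
                            alpha = 0.05,
                            equianalgesic_path = NULL,
                            potency_source = "crowdsourced",
                            n_boot = 2000,
                            seed = 20120101) {
  paths <- c(crowdsourced = crowdsourced_path,
             law_enforcement = law_enforcement_path,
             marketplace = marketplace_path)
  if (length(paths) == 0) stop("no input paths given", call. = FALSE)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(rates_path) && !file.exists(rates_path)) {
    stop("rates file not found: ", rates_path, call. = FALSE)
  }
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)
  structure(list(
    paths = paths, rates_path = rates_path, out_dir = out_dir,
    filter = filter, alpha = alpha, equianalgesic_path = equianalgesic_path,
    potency_source = potency_source, n_boot = n_boot,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

config_hash <- function(config) {
  # 31-bit rolling hash over the deparsed config; a stable run
  # fingerprint, not crypto
  h <- 17
  for (c in utf8ToInt(paste(deparse(unclass(config)), collapse = ""))) {
    h <- (h * 31 + c) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Run the full surveillance pipeline
#'
#' ingest -> filter -> estimate -> cross-validate -> potency, writing the
#' artifact bundle to `config$out_dir`: the per-source summary table
#' (`summary_table.csv/.json`), the cross-source correlation results
#' (`correlations.json`), the potency table (`potency_table.csv/.json`),
#' the per-drug cross-source tests (`drug_tests.csv`), the filter audit
#' (`filter_audit.json`), the ingestion rejects (`rejects.csv`), and run
#' metadata (`run_metadata.json`: config hash, seed, package and R
#' versions). Reruns with the same inputs, seed and config produce
#' byte-identical numeric outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `reports`, `filter_result`, `summaries`,
#'   `correlations`, `drug_tests`, `potency`, and `paths` of the files
#'   written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  rates <- if (!is.null(config$rates_path)) {
    read_exchange_rates(config$rates_path)
  }

  ingested <- purrr::imap(config$paths, function(path, dialect) {
    read_reports(path, dialect, rates = rates)
  })
  reports <- dplyr::bind_rows(purrr::map(ingested, "reports"))
  rejects <- dplyr::bind_rows(purrr::imap(
    ingested, function(x, d) dplyr::mutate(x$rejects, source = d)))

  fr <- apply_filters(reports, config$filter)
  summaries <- summarize_prices(fr$kept, alpha = config$alpha)
  correlations <- cross_source_matrix(summaries)
  drug_tests <- compare_all_drugs(fr$kept)

  eq_table <- equianalgesic_table(config$equianalgesic_path)
  pot_src <- config$potency_source
  potency <- predicted_relative_potency(
    summaries[summaries$source == pot_src, ],
    reports = fr$kept[fr$kept$source == pot_src, ],
    table = eq_table, n_boot = config$n_boot, alpha = config$alpha,
    seed = config$seed
  )

  paths <- render_tables(summaries, potency, config$out_dir)
  paths["correlations"] <- file.path(config$out_dir, "correlations.json")
  jsonlite::write_json(correlations, paths[["correlations"]],
                       digits = NA, pretty = TRUE)
  paths["drug_tests"] <- file.path(config$out_dir, "drug_tests.csv")
  readr::write_csv(drug_tests, paths[["drug_tests"]])
  paths["rejects"] <- file.path(config$out_dir, "rejects.csv")
  readr::write_csv(rejects, paths[["rejects"]], na = "")
  paths["audit"] <- file.path(config$out_dir, "filter_audit.json")
  write_filter_audit(fr, paths[["audit"]])
  paths["metadata"] <- file.path(config$out_dir, "run_metadata.json")
  jsonlite::write_json(list(
    config_hash = config_hash(config),
    seed = config$seed,
    alpha = config$alpha,
    package_version = as.character(utils::packageVersion("streetpricer")),
    r_version = R.version.string,
    caveat = paste("Predicted potency reflects market valuation;",
                   "it should not be used for clinical conversion.")
  ), paths[["metadata"]], auto_unbox = TRUE, pretty = TRUE)

  invisible(list(reports = reports, rejects = rejects, filter_result = fr,
                 summaries = summaries, correlations = correlations,
                 drug_tests = drug_tests, potency = potency, paths = paths))
}

#' Render the summary and potency tables
#'
#' Writes the per-source price table (one row per drug, per-source
#' `n` / mean / 95% CI column groups, drugs ordered by descending
#' crowdsourced mean) and the potency table (predicted relative potency
#' with CI, clinical factor, comparison label; drugs without a clinical
#' factor keep their ratio but no comparison). Monetary cells print with
#' 2 decimals; ratios follow [format_potency()].
#'
#' @param summaries tibble from [summarize_prices()].
#' @param potency tibble from [predicted_relative_potency()].
#' @param dir output directory.
#' @param formats subset of `c("csv", "json")`.
#' @return named vector of written paths, invisibly.
#' @export
render_tables <- function(summaries, potency, dir,
                          formats = c("csv", "json")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  fmt_money <- function(x) sprintf("%.2f", round(x, 2))

  wide <- summaries |>
    dplyr::mutate(
      cell = ifelse(is.na(.data$ci_low),
                    fmt_money(.data$gm_price_per_mg),
                    sprintf("%s (%s-%s)", fmt_money(.data$gm_price_per_mg),
                            fmt_money(.data$ci_low),
                            fmt_money(.data$ci_high)))) |>
    dplyr::select("drug", "source", "n", "cell") |>
    tidyr::pivot_wider(names_from = "source",
                       values_from = c("n", "cell"), names_vary = "slowest")
  ord <- summaries |>
    dplyr::group_by(.data$drug) |>
    dplyr::summarise(key = max(.data$gm_price_per_mg), .groups = "drop")
  wide <- wide[order(-ord$key[match(wide$drug, ord$drug)]), ]

  pot_out <- potency |>
    dplyr::mutate(
      predicted = format_potency(.data$predicted_potency),
      ci = ifelse(is.na(.data$ci_low), NA_character_,
                  sprintf("(%s-%s)", format_potency(.data$ci_low),
                          format_potency(.data$ci_high)))) |>
    dplyr::select("drug", "n", "gm_price_per_mg", "predicted", "ci",
                  "clinical_factor", "comparison")

  if ("csv" %in% formats) {
    paths["summary_csv"] <- file.path(dir, "summary_table.csv")
    readr::write_csv(wide, paths[["summary_csv"]], na = "")
    paths["potency_csv"] <- file.path(dir, "potency_table.csv")
    readr::write_csv(pot_out, paths[["potency_csv"]], na = "")
  }
  if ("json" %in% formats) {
    paths["summary_json"] <- file.path(dir, "summary_table.json")
    jsonlite::write_json(summaries, paths[["summary_json"]],
                         digits = NA, pretty = TRUE)
    paths["potency_json"] <- file.path(dir, "potency_table.json")
    jsonlite::write_json(potency, paths[["potency_json"]],
                         digits = NA, pretty = TRUE)
  }
  invisible(paths)
}
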