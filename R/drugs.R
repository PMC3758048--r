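#' Opioid drug registry
#'
#' Canonical active-ingredient names for the oral/sublingual opioid
#' analgesics covered by the surveillance pipeline, with common brand-name
#' synonyms. Drug-name normalization in [read_reports()] is a
#' case-insensitive lookup against this registry; names that do not resolve
#' are routed to the rejects stream rather than silently coerced.
#'
#' @param extra_synonyms optional named character vector mapping additional
#'   synonyms (names) to canonical drug names (values); use this to extend
#'   the registry without editing the package.
#' @return A named character vector mapping lower-case synonyms to canonical
#'   drug names. Canonical names map to themselves.
#' @export
#' @examples
#' drug_registry()[["oxycontin"]]
drug_registry <- function(extra_synonyms = NULL) {
  canonical <- c(
    "hydromorphone", "buprenorphine", "oxymorphone", "methadone",
    "oxycodone", "hydrocodone", "morphine", "tramadol"
  )
  synonyms <- c(
    dilaudid = "hydromorphone", exalgo = "hydromorphone",
    suboxone = "buprenorphine", subutex = "buprenorphine",
    opana = "oxymorphone", numorphan = "oxymorphone",
    dolophine = "methadone", methadose = "methadone",
    oxycontin = "oxycodone", percocet = "oxycodone",
    roxicodone = "oxycodone", oxy = "oxycodone",
    vicodin = "hydrocodone", norco = "hydrocodone", lortab = "hydrocodone",
    "ms contin" = "morphine", mscontin = "morphine", kadian = "morphine",
    ultram = "tramadol"
  )
  registry <- c(stats::setNames(canonical, canonical), synonyms)
  if (!is.null(extra_synonyms)) {
    stopifnot(is.character(extra_synonyms), !is.null(names(extra_synonyms)))
    registry <- c(registry, stats::setNames(tolower(extra_synonyms),
                                            tolower(names(extra_synonyms))))
  }
  stats::setNames(registry, tolower(names(registry)))
}

#' Normalize free-text drug names against the registry
#'
#' @param x character vector of drug names as they appear in a source file.
#' @param registry registry as returned by [drug_registry()].
#' @return Character vector of canonical names, `NA` where the name is not
#'   in the registry.
#' @export
normalize_drug_name <- function(x, registry = drug_registry()) {
  out <- unname(registry[tolower(trimws(as.character(x)))])
  out
}

#' Recognized report sources
#' @return character vector of the three source identifiers.
#' @export
report_sources <- function() {
  c("crowdsourced", "law_enforcement", "marketplace")
}

#' Clinical equianalgesic conversion table
#'
#' Milligrams of morphine equianalgesic to 1 mg of each drug (morphine = 1),
#' from the 2012 US VA/DoD Clinical Practice Guideline for Management of
#' Opioid Therapy for Chronic Pain. The table ships as an editable CSV so
#' other published conversion guides can be swapped in; factors differ
#' between guides and none should be used for clinical dosing decisions.
#' Buprenorphine has no single accepted oral conversion factor and is
#' absent, which excludes it from potency comparison by default.
#'
#' @param path optional path to a CSV with columns `drug`, `factor`
#'   (and optionally `citation`); defaults to the packaged VA/DoD 2012 table.
#' @return A tibble with columns `drug` and `factor`. Morphine is always
#'   present with factor exactly 1.
#' @export
#' @examples
#' equianalgesic_table()
equianalgesic_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "equianalgesic_va_dod_2012.csv",
                        package = "streetpricer", mustWork = TRUE)
  }
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("drug", "factor") %in% names(tab))) {
    stop("equianalgesic table must have columns 'drug' and 'factor'", call. = FALSE)
  }
  tab <- dplyr::mutate(tab, drug = tolower(.data$drug),
                       factor = as.numeric(.data$factor))
  if (any(!is.finite(tab$factor) | tab$factor <= 0)) {
    stop("all equianalgesic factors must be positive", call. = FALSE)
  }
  if (!"morphine" %in% tab$drug || tab$factor[tab$drug == "morphine"] != 1) {
    stop("equianalgesic table must contain morphine with factor exactly 1",
         call. = FALSE)
  }
  tibble::as_tibble(tab[, c("drug", "factor")])
}

#' Published 2012 US street-price summary
#'
#' Per-drug, per-source counts and geometric-mean prices per milligram
#' (US$/mg, with 95% CIs) for diverted prescription opioids in the United
#' States in 2012, as published from the three surveillance streams:
#' crowdsourced web submissions, a quarterly law-enforcement drug-diversion
#' survey, and listings scraped from an anonymous online marketplace.
#' These printed summary values are the reference conditions for the
#' synthetic-data generator ([default_generator_params()]) and the input to
#' the in-package reproduction of the cross-source rank correlations and
#' the predicted-relative-potency column.
#'
#' @return A tibble with columns `drug`, `source`, `n`, `gm_price_per_mg`,
#'   `ci_low`, `ci_high` (24 rows: 8 drugs x 3 sources).
#' @export
#' @examples
#' published_price_summary()
published_price_summary <- function() {
  tab <- tibble::tribble(
    ~drug,            ~source,           ~n,  ~gm_price_per_mg, ~ci_low, ~ci_high,
    "hydromorphone",  "crowdsourced",    75L,  3.29, 2.74, 3.96,
    "buprenorphine",  "crowdsourced",    34L,  2.13, 1.69, 2.69,
    "oxymorphone",    "crowdsourced",    38L,  1.57, 1.27, 1.95,
    "methadone",      "crowdsourced",    21L,  0.96, 0.71, 1.29,
    "oxycodone",      "crowdsourced",   454L,  0.97, 0.90, 1.04,
    "hydrocodone",    "crowdsourced",   228L,  0.81, 0.74, 0.89,
    "morphine",       "crowdsourced",    83L,  0.52, 0.40, 0.68,
    "tramadol",       "crowdsourced",    21L,  0.05, 0.03, 0.07,
    "hydromorphone",  "law_enforcement", 54L,  4.47, 3.57, 5.59,
    "buprenorphine",  "law_enforcement", 81L,  2.35, 1.97, 2.80,
    "oxymorphone",    "law_enforcement", 43L,  1.64, 1.29, 2.10,
    "methadone",      "law_enforcement", 81L,  1.16, 1.01, 1.37,
    "oxycodone",      "law_enforcement", 181L, 0.86, 0.78, 0.93,
    "hydrocodone",    "law_enforcement", 179L, 0.90, 0.84, 0.97,
    "morphine",       "law_enforcement", 81L,  0.67, 0.59, 0.75,
    "tramadol",       "law_enforcement", 37L,  0.09, 0.07, 0.12,
    "hydromorphone",  "marketplace",     14L,  3.55, 3.09, 4.08,
    "buprenorphine",  "marketplace",     12L,  2.58, 2.13, 3.13,
    "oxymorphone",    "marketplace",      6L,  1.58, 0.73, 3.43,
    "methadone",      "marketplace",      3L,  0.93, 0.65, 1.34,
    "oxycodone",      "marketplace",     43L,  0.99, 0.83, 1.18,
    "hydrocodone",    "marketplace",     46L,  0.97, 0.90, 1.05,
    "morphine",       "marketplace",     16L,  0.42, 0.37, 0.48,
    "tramadol",       "marketplace",      7L,  0.02, 0.01, 0.03
  )
  tab$alpha <- 0.05
  tab
}
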