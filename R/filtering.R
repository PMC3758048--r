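#' Credibility-filter configuration
#'
#' Settings for the report-stream filters applied before estimation.
#' Defaults reproduce the study conditions of the 2012 US analysis window:
#' reports from the United States, user-flagged outlier ratings (1 =
#' "cheap", 5 = "overpriced") excluded, same-IP same-drug submissions less
#' than 10 seconds apart collapsed to the earliest, bulk purchases flagged
#' but retained, marketplace listings restricted to US shipping origin.
#'
#' @param window_start,window_end eligibility window (Dates, inclusive).
#' @param country ISO country code reports must match.
#' @param exclude_ratings integer ratings treated as user-flagged price
#'   outliers; `integer(0)` disables the rule. Unrated reports always pass:
#'   only reports positively identified as cheap/overpriced are excluded.
#' @param duplicate_window_seconds two same-IP, same-drug submissions
#'   closer than this are treated as one accidental double entry.
#' @param require_strength require non-missing `strength_mg` (and
#'   formulation where recorded) for a report to be analyzable.
#' @param exclude_bulk drop reports flagged as bulk purchases (more than 10
#'   units). Off by default: bulk status is noted, not an exclusion.
#' @param marketplace_ship_origin country code marketplace listings must
#'   ship from, or `NULL` to accept any origin.
#' @param date_basis which date the eligibility window applies to:
#'   `"submission"` uses the submission timestamp where one exists
#'   (falling back to the transaction date), `"transaction"` always uses
#'   the transaction date.
#' @return a `filter_config` list.
#' @export
filter_config <- function(window_start = as.Date("2012-01-01"),
                          window_end = as.Date("2012-12-31"),
                          country = "US",
                          exclude_ratings = c(1L, 5L),
                          duplicate_window_seconds = 10,
                          require_strength = TRUE,
                          exclude_bulk = FALSE,
                          marketplace_ship_origin = "US",
                          date_basis = c("submission", "transaction")) {
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  if (is.na(window_start) || is.na(window_end) || window_start > window_end) {
    stop("window_start must be <= window_end", call. = FALSE)
  }
  if (!is.numeric(duplicate_window_seconds) || duplicate_window_seconds <= 0) {
    stop("duplicate_window_seconds must be positive", call. = FALSE)
  }
  exclude_ratings <- as.integer(exclude_ratings)
  if (length(exclude_ratings) && !all(exclude_ratings %in% 1:5)) {
    stop("exclude_ratings must be a subset of 1:5", call. = FALSE)
  }
  structure(list(
    window_start = window_start, window_end = window_end,
    country = country, exclude_ratings = exclude_ratings,
    duplicate_window_seconds = duplicate_window_seconds,
    require_strength = isTRUE(require_strength),
    exclude_bulk = isTRUE(exclude_bulk),
    marketplace_ship_origin = marketplace_ship_origin,
    date_basis = match.arg(date_basis)
  ), class = "filter_config")
}

partition <- function(reports, keep) {
  list(kept = reports[keep, , drop = FALSE],
       removed = reports[!keep, , drop = FALSE])
}

filter_eligibility <- function(reports, config) {
  basis_date <- if (config$date_basis == "submission") {
    dplyr::coalesce(as.Date(reports$submitted_at, tz = "UTC"),
                    reports$transaction_date)
  } else {
    reports$transaction_date
  }
  keep <- !is.na(basis_date) &
    basis_date >= config$window_start & basis_date <= config$window_end &
    !is.na(reports$country) & reports$country == config$country
  if (!is.null(config$marketplace_ship_origin)) {
    mp <- reports$source == "marketplace"
    keep <- keep & (!mp | (!is.na(reports$ship_origin) &
                             reports$ship_origin ==
                               config$marketplace_ship_origin))
  }
  partition(reports, keep)
}

#' Completeness filter
#'
#' Reports must carry a dose strength (and a formulation, where the source
#' records one) to be converted to a per-milligram price; incomplete
#' reports are removed.
#'
#' @param reports normalized report tibble.
#' @param config a [filter_config()].
#' @return list with `kept` and `removed` tibbles.
#' @export
filter_completeness <- function(reports, config = filter_config()) {
  if (!config$require_strength) {
    return(partition(reports, rep(TRUE, nrow(reports))))
  }
  keep <- !is.na(reports$strength_mg) & !is.na(reports$price_per_mg)
  # the crowdsourced form records a formulation; a blank one is incomplete
  keep <- keep & (reports$source != "crowdsourced" |
                    !is.na(reports$formulation))
  partition(reports, keep)
}

#' Outlier-rating filter
#'
#' Crowdsourced submissions rated at the endpoints of the 5-point
#' visual-analog price scale ("cheap" or "overpriced") are treated as
#' user-identified price outliers and excluded. The rule applies only to
#' crowdsourced reports; other sources, and unrated submissions, pass
#' through.
#'
#' @inheritParams filter_completeness
#' @return list with `kept` and `removed` tibbles.
#' @export
filter_outlier_ratings <- function(reports, config = filter_config()) {
  keep <- !(reports$source == "crowdsourced" &
              !is.na(reports$rating) &
              reports$rating %in% config$exclude_ratings)
  partition(reports, keep)
}

#' Near-simultaneous duplicate removal
#'
#' Two submissions of the same drug from the same (hashed) IP address less
#' than `duplicate_window_seconds` apart almost certainly record one
#' transaction twice; only the earliest of such a dyad is retained. Chains
#' are resolved with a sliding anchor: within each (ip, drug) group sorted
#' by submission time, a report is removed when it falls strictly less
#' than the window after the most recently *retained* report, so of
#' submissions at 0, 6 and 12 seconds (10 s window) the first and third
#' survive. Reports without an IP token or timestamp do not participate.
#'
#' @inheritParams filter_completeness
#' @return list with `kept` and `removed` tibbles.
#' @export
deduplicate <- function(reports, config = filter_config()) {
  n <- nrow(reports)
  keep <- rep(TRUE, n)
  eligible <- which(!is.na(reports$ip_token) & !is.na(reports$submitted_at))
  if (length(eligible) > 1) {
    grp <- split(eligible,
                 paste(reports$ip_token[eligible], reports$drug[eligible],
                       sep = "\r"))
    for (idx in grp) {
      if (length(idx) < 2) next
      idx <- idx[order(reports$submitted_at[idx])]
      anchor <- as.numeric(reports$submitted_at[idx[1]])
      for (i in idx[-1]) {
        t <- as.numeric(reports$submitted_at[i])
        if (t - anchor < config$duplicate_window_seconds) {
          keep[i] <- FALSE
        } else {
          anchor <- t
        }
      }
    }
  }
  partition(reports, keep)
}

filter_bulk <- function(reports, config) {
  if (!config$exclude_bulk) {
    return(partition(reports, rep(TRUE, nrow(reports))))
  }
  partition(reports, reports$bulk_flag != "yes")
}

#' Apply all credibility filters with an audit trail
#'
#' Runs the filter rules in a fixed order — eligibility (window, country,
#' marketplace shipping origin), completeness, outlier ratings,
#' near-duplicate removal, then optional bulk exclusion — and records how
#' many reports each rule removed. The count identity
#' `nrow(kept) + sum(removed_by_rule)` equals the input size for every
#' input, and filtering is idempotent: re-filtering the kept set removes
#' nothing.
#'
#' @inheritParams filter_completeness
#' @return object of class `filter_result`: list with `kept` (tibble),
#'   `removed_by_rule` (named integer vector), `rule_order`, and `removed`
#'   (tibble of removed reports with a `removed_by` column).
#' @export
apply_filters <- function(reports, config = filter_config()) {
  if (!inherits(config, "filter_config")) {
    stop("config must be created by filter_config()", call. = FALSE)
  }
  rules <- list(
    eligibility = filter_eligibility,
    completeness = filter_completeness,
    outlier_rating = filter_outlier_ratings,
    duplicate = deduplicate,
    bulk = filter_bulk
  )
  kept <- reports
  removed_by_rule <- stats::setNames(integer(length(rules)), names(rules))
  removed_all <- list()
  for (rule in names(rules)) {
    part <- rules[[rule]](kept, config)
    removed_by_rule[[rule]] <- nrow(part$removed)
    if (nrow(part$removed)) {
      removed_all[[rule]] <- dplyr::mutate(part$removed, removed_by = rule)
    }
    kept <- part$kept
  }
  structure(list(
    kept = kept,
    removed_by_rule = removed_by_rule,
    rule_order = names(rules),
    removed = dplyr::bind_rows(removed_all)
  ), class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("<filter_result>\n")
  cat("  kept:", nrow(x$kept), "reports\n")
  for (rule in x$rule_order) {
    cat(sprintf("  removed by %-14s %d\n", paste0(rule, ":"),
                x$removed_by_rule[[rule]]))
  }
  invisible(x)
}

#' Serialize a filter audit trail to JSON
#'
#' @param result a `filter_result` from [apply_filters()].
#' @param path output path for the JSON audit file.
#' @return `path`, invisibly.
#' @export
write_filter_audit <- function(result, path) {
  jsonlite::write_json(list(
    kept = nrow(result$kept),
    removed_by_rule = as.list(result$removed_by_rule),
    rule_order = result$rule_order
  ), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
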