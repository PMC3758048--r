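#' @importFrom rlang .data
NULL

# Normalized report column order; the single schema every dialect maps into.
REPORT_COLUMNS <- c(
  "report_id", "source", "drug", "formulation", "strength_mg",
  "quantity_units", "total_price_usd", "price_per_mg", "transaction_date",
  "country", "region", "rating", "attribution", "ip_token", "submitted_at",
  "bulk_flag", "ship_origin"
)

#' Price per milligram of active ingredient
#'
#' The pipeline's standard unit: US$ paid per milligram of active
#' ingredient, `total_price_usd / (quantity_units * strength_mg)`,
#' rounded half-to-even at 4 decimal places.
#'
#' @param total_price_usd nonnegative total transaction price in US$.
#' @param quantity_units positive integer number of dosage units bought.
#' @param strength_mg positive milligrams of active ingredient per unit.
#' @return price in US$/mg; vectorized over its arguments.
#' @export
#' @examples
#' price_per_mg(80, 10, 8)    # 1.00
#' price_per_mg(60, 10, 15)   # 0.40
price_per_mg <- function(total_price_usd, quantity_units, strength_mg) {
  if (any(!is.finite(total_price_usd) | total_price_usd < 0)) {
    stop("total_price_usd must be nonnegative", call. = FALSE)
  }
  if (any(!is.finite(quantity_units) | quantity_units < 1 |
          quantity_units != round(quantity_units))) {
    stop("quantity_units must be a positive integer", call. = FALSE)
  }
  if (any(!is.finite(strength_mg) | strength_mg <= 0)) {
    stop("strength_mg must be positive", call. = FALSE)
  }
  round(total_price_usd / (quantity_units * strength_mg), 4)
}

#' Read a dated BTC to USD exchange-rate table
#'
#' Two-column CSV: ISO-8601 `date`, `usd_per_btc` (the daily
#' weighted-average exchange price in US$ per bitcoin). Dates must be
#' unique and all rates strictly positive. No interpolation is done
#' anywhere in the package: conversion uses the rate of the posting day
#' or fails for that row.
#'
#' @param path path to the CSV.
#' @return tibble with columns `date` (Date) and `usd_per_btc` (double).
#' @export
read_exchange_rates <- function(path) {
  rates <- readr::read_csv(path, col_types = readr::cols(
    date = readr::col_date(), usd_per_btc = readr::col_double()
  ))
  if (anyDuplicated(rates$date)) {
    stop("exchange-rate table has duplicate dates", call. = FALSE)
  }
  if (any(!is.finite(rates$usd_per_btc) | rates$usd_per_btc <= 0)) {
    stop("exchange rates must be positive", call. = FALSE)
  }
  dplyr::arrange(rates, .data$date)
}

#' Convert a bitcoin amount to US dollars at the daily rate
#'
#' Multiplies by the US$/BTC weighted-average rate recorded for `date`.
#' A date absent from the table is an error, never interpolated, because
#' the conversion convention is the rate of the day the sale was posted.
#' Result is rounded half-to-even at 4 decimals (cent-level arithmetic is
#' applied once at record normalization).
#'
#' @param amount_btc nonnegative BTC amount (vectorized).
#' @param date Date of the posting (vectorized, recycled against amount).
#' @param rates exchange-rate table from [read_exchange_rates()].
#' @return US$ amount(s).
#' @export
convert_currency <- function(amount_btc, date, rates) {
  if (any(!is.finite(amount_btc) | amount_btc < 0)) {
    stop("amount_btc must be nonnegative", call. = FALSE)
  }
  date <- as.Date(date)
  idx <- match(date, rates$date)
  if (anyNA(idx)) {
    missing_dates <- unique(date[is.na(idx)])
    stop("no exchange rate for date(s): ",
         paste(format(missing_dates), collapse = ", "), call. = FALSE)
  }
  round(amount_btc * rates$usd_per_btc[idx], 4)
}

quarter_start <- function(quarter) {
  # "2012Q1" -> 2012-01-01; malformed strings return NA
  m <- regmatches(quarter, regexec("^([0-9]{4})[Qq]([1-4])$", trimws(quarter)))
  vapply(m, function(g) {
    if (length(g) != 3) return(NA_character_)
    sprintf("%s-%02d-01", g[2], (as.integer(g[3]) - 1L) * 3L + 1L)
  }, character(1))
}

new_reject <- function(row_number, reason, raw) {
  tibble::tibble(row_number = row_number, reason = reason, raw = raw)
}

empty_reports <- function() {
  tibble::tibble(
    report_id = character(), source = character(), drug = character(),
    formulation = character(), strength_mg = double(),
    quantity_units = integer(), total_price_usd = double(),
    price_per_mg = double(), transaction_date = as.Date(character()),
    country = character(), region = character(), rating = integer(),
    attribution = character(), ip_token = character(),
    submitted_at = as.POSIXct(character(), tz = "UTC"),
    bulk_flag = character(), ship_origin = character()
  )
}

#' Read price reports from one source dialect
#'
#' Parses one of the three source file dialects into the normalized report
#' schema, resolving drug names against the registry, converting BTC to
#' USD where needed, and computing price per milligram. Rows whose
#' mandatory fields cannot be parsed are emitted to a rejects table with a
#' reason, never silently dropped; `nrow(reports) + nrow(rejects)` always
#' equals the number of input rows.
#'
#' Dialect column schemas (CSV, header row required):
#' \describe{
#'   \item{crowdsourced}{`drug, formulation, strength_mg, quantity_units,
#'     price_usd, rating, attribution, ip_hash, submitted_at, country,
#'     region, bulk_purchase`. `submitted_at` is an ISO-8601 timestamp;
#'     the transaction date is taken as its calendar date. `rating` is the
#'     1-5 visual-analog price rating (1 = "cheap", 5 = "overpriced") or
#'     empty. `bulk_purchase` is yes/no/empty (more than 10 units).}
#'   \item{law_enforcement}{`drug, strength_mg, price_usd, quarter`
#'     (e.g. `2012Q1`). Officers report the price paid for one unit of the
#'     most commonly encountered strength, so `quantity_units` is 1 and the
#'     transaction date is taken as the quarter start.}
#'   \item{marketplace}{`drug, strength_mg, quantity_units, price_btc,
#'     posting_date, ship_origin`. An optional `price_usd` column is used
#'     for rows whose `price_btc` is empty. BTC prices are converted at the
#'     daily US$/BTC rate of the posting date; a missing rate rejects the
#'     row.}
#' }
#'
#' Monetary normalization: USD totals are rounded half-to-even to cents;
#' price per mg is carried at 4 decimals.
#'
#' @param path CSV file path.
#' @param dialect one of `"crowdsourced"`, `"law_enforcement"`,
#'   `"marketplace"`.
#' @param rates exchange-rate table from [read_exchange_rates()]; required
#'   for the marketplace dialect when any row is priced in BTC.
#' @param registry drug-name registry, see [drug_registry()].
#' @return list with elements `reports` (normalized tibble) and `rejects`
#'   (tibble with `row_number`, `reason`, `raw`).
#' @export
read_reports <- function(path, dialect, rates = NULL,
                         registry = drug_registry()) {
  dialect <- match.arg(dialect, report_sources())
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"))
  parse_raw_reports(raw, dialect, rates = rates, registry = registry)
}

#' @rdname read_reports
#' @param raw a character-typed tibble of raw rows (as read from the CSV).
#' @export
parse_raw_reports <- function(raw, dialect, rates = NULL,
                              registry = drug_registry()) {
  dialect <- match.arg(dialect, report_sources())
  required <- switch(dialect,
    crowdsourced = c("drug", "strength_mg", "quantity_units", "price_usd",
                     "submitted_at"),
    law_enforcement = c("drug", "strength_mg", "price_usd", "quarter"),
    marketplace = c("drug", "strength_mg", "quantity_units", "posting_date")
  )
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("dialect '%s' requires column(s): %s", dialect,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    return(list(reports = empty_reports(), rejects = new_reject(
      integer(), character(), character())))
  }

  n <- nrow(raw)
  reason <- rep(NA_character_, n)
  note <- function(bad, why) {
    reason <<- ifelse(is.na(reason) & bad, why, reason)
  }
  col <- function(name, default = NA_character_) {
    if (name %in% names(raw)) raw[[name]] else rep(default, n)
  }

  drug <- normalize_drug_name(col("drug"), registry)
  note(is.na(drug), "unknown drug")

  strength <- suppressWarnings(as.numeric(col("strength_mg")))
  # missing strength is allowed (completeness filter handles it); a value
  # that is present but non-numeric or nonpositive is unparseable
  has_strength_text <- !is.na(col("strength_mg"))
  note(has_strength_text & (is.na(strength) | strength <= 0),
       "invalid strength")
  strength[!has_strength_text] <- NA_real_

  qty_raw <- col("quantity_units")
  qty <- suppressWarnings(as.numeric(qty_raw))
  qty[is.na(qty_raw)] <- 1  # absent quantity means a single unit
  note(is.na(qty) | qty < 1 | qty != round(qty), "invalid quantity")

  rating <- suppressWarnings(as.integer(col("rating")))
  note(!is.na(col("rating")) & (is.na(rating) | !rating %in% 1:5),
       "invalid rating")

  if (dialect == "marketplace") {
    btc <- suppressWarnings(as.numeric(col("price_btc")))
    usd_direct <- suppressWarnings(as.numeric(col("price_usd")))
    date <- as.Date(suppressWarnings(readr::parse_date(col("posting_date"))))
    note(is.na(date), "invalid date")
    usd <- usd_direct
    if (any(!is.na(btc))) {
      if (is.null(rates)) {
        stop("marketplace rows priced in BTC require an exchange-rate table",
             call. = FALSE)
      }
      have_rate <- date %in% rates$date
      note(!is.na(btc) & !is.na(date) & !have_rate, "no exchange rate")
      ok <- !is.na(btc) & !is.na(date) & have_rate
      usd[ok] <- convert_currency(btc[ok], date[ok], rates)
    }
    note(is.na(usd) & is.na(btc), "missing price")
    note(!is.na(usd) & usd < 0, "invalid price")
    submitted <- as.POSIXct(rep(NA_real_, n), tz = "UTC",
                            origin = "1970-01-01")
    country <- rep("US", n)
    region <- rep(NA_character_, n)
    attribution <- rep(NA_character_, n)
    ip <- rep(NA_character_, n)
    bulk <- ifelse(!is.na(qty) & qty > 10, "yes", "unanswered")
    ship <- toupper(col("ship_origin"))
  } else if (dialect == "law_enforcement") {
    usd <- suppressWarnings(as.numeric(col("price_usd")))
    note(is.na(usd), "missing price")
    note(!is.na(usd) & usd < 0, "invalid price")
    qstart <- quarter_start(col("quarter"))
    date <- as.Date(qstart)
    note(is.na(date), "invalid quarter")
    submitted <- as.POSIXct(rep(NA_real_, n), tz = "UTC",
                            origin = "1970-01-01")
    country <- toupper(col("country", "US"))
    country[is.na(country)] <- "US"
    region <- col("region")
    attribution <- rep(NA_character_, n)
    ip <- rep(NA_character_, n)
    bulk <- rep("unanswered", n)
    ship <- rep(NA_character_, n)
  } else { # crowdsourced
    usd <- suppressWarnings(as.numeric(col("price_usd")))
    note(is.na(usd), "missing price")
    note(!is.na(usd) & usd < 0, "invalid price")
    submitted <- suppressWarnings(
      as.POSIXct(col("submitted_at"), tz = "UTC",
                 tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                "%Y-%m-%d")))
    note(is.na(submitted), "invalid timestamp")
    date <- as.Date(submitted, tz = "UTC")
    country <- toupper(col("country", "US"))
    country[is.na(country)] <- "US"
    region <- col("region")
    attribution <- tolower(col("attribution"))
    note(!is.na(attribution) &
           !attribution %in% c("personal", "swim", "internet"),
         "invalid attribution")
    ip <- col("ip_hash")
    bulk_raw <- tolower(col("bulk_purchase"))
    bulk <- dplyr::case_when(
      bulk_raw %in% "yes" ~ "yes",
      bulk_raw %in% "no" ~ "no",
      TRUE ~ "unanswered"
    )
    ship <- rep(NA_character_, n)
  }

  usd <- round(usd, 2)
  ppm <- rep(NA_real_, n)
  calc <- is.na(reason) & !is.na(strength) & !is.na(usd)
  if (any(calc)) {
    ppm[calc] <- price_per_mg(usd[calc], qty[calc], strength[calc])
  }

  reports <- tibble::tibble(
    report_id = sprintf("%s-%05d", substr(dialect, 1, 2), seq_len(n)),
    source = dialect,
    drug = drug,
    formulation = if ("formulation" %in% names(raw)) raw$formulation
                  else NA_character_,
    strength_mg = strength,
    quantity_units = as.integer(qty),
    total_price_usd = usd,
    price_per_mg = ppm,
    transaction_date = date,
    country = country,
    region = region,
    rating = rating,
    attribution = attribution,
    ip_token = ip,
    submitted_at = submitted,
    bulk_flag = bulk,
    ship_origin = ship
  )

  keep <- is.na(reason)
  rejects <- new_reject(
    which(!keep), reason[!keep],
    vapply(which(!keep), function(i)
      paste(unlist(raw[i, ]), collapse = "|"), character(1))
  )
  list(reports = reports[keep, REPORT_COLUMNS], rejects = rejects)
}

#' Write and re-read normalized reports
#'
#' The normalized CSV is the package's interchange format; writing a parsed
#' report stream and re-reading it yields identical records (timestamps are
#' serialized as ISO-8601 UTC).
#'
#' @param reports normalized report tibble.
#' @param path output CSV path.
#' @return `write_reports` returns `path` invisibly;
#'   `read_normalized_reports` returns the report tibble.
#' @export
write_reports <- function(reports, path) {
  out <- reports
  out$submitted_at <- format(out$submitted_at, "%Y-%m-%dT%H:%M:%OS3Z",
                             tz = "UTC")
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_reports
#' @export
read_normalized_reports <- function(path) {
  out <- readr::read_csv(path, na = "", col_types = readr::cols(
    report_id = "c", source = "c", drug = "c", formulation = "c",
    strength_mg = "d", quantity_units = "i", total_price_usd = "d",
    price_per_mg = "d", transaction_date = readr::col_date(),
    country = "c", region = "c", rating = "i", attribution = "c",
    ip_token = "c",
    submitted_at = readr::col_datetime(format = "%Y-%m-%dT%H:%M:%OSZ"),
    bulk_flag = "c", ship_origin = "c"
  ))
  out$submitted_at <- as.POSIXct(out$submitted_at, tz = "UTC")
  out[, REPORT_COLUMNS]
}
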