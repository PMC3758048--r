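# Typical US unit strengths (mg) used when synthesizing listings.
TYPICAL_STRENGTH_MG <- c(
  hydromorphone = 8, buprenorphine = 8, oxymorphone = 10, methadone = 10,
  oxycodone = 30, hydrocodone = 10, morphine = 30, tramadol = 50
)

# Deterministic 31-bit hash of a cell key, mixed with the master seed, so
# each (drug, source) cell has its own RNG stream and adding a drug never
# perturbs another cell's draws. All intermediates stay < 2^53.
cell_seed <- function(seed, key) {
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483647
  (h + (seed %% 2147483647) * 7919) %% 2147483647
}

#' Synthetic-report generator parameters
#'
#' Level parameters (`cells`: one row per drug/source with the true
#' geometric-mean price per mg, log-scale SD and report count) plus the
#' contamination rates the credibility filters are meant to absorb:
#' user-flagged price outliers (extreme prices coupled to endpoint
#' ratings), near-simultaneous same-IP duplicate submissions, missing
#' dose strengths, and bulk-purchase flags. Contamination applies to the
#' crowdsourced stream only, mirroring how the three streams are
#' collected.
#'
#' @param cells tibble with columns `drug`, `source`, `true_gm`, `log_sd`,
#'   `n`.
#' @param outlier_fraction fraction of crowdsourced reports given outlier
#'   prices and endpoint ratings (1 "cheap" / 5 "overpriced"); the study
#'   condition is that about one quarter of submissions are rated in these
#'   two categories.
#' @param outlier_multiplier_range outlier prices are the clean draw
#'   multiplied or divided (equal probability) by a factor uniform in this
#'   range.
#' @param duplicate_fraction fraction of crowdsourced reports cloned with
#'   the same IP token and drug, offset by `duplicate_gap_seconds`.
#' @param duplicate_gap_seconds clone timestamp offset; must sit inside
#'   the 10-second dedup window.
#' @param missing_strength_fraction fraction of crowdsourced reports with
#'   the dose strength left blank.
#' @param bulk_fraction fraction of crowdsourced reports flagged as bulk
#'   purchases (more than 10 units); the study condition is 10%.
#' @param seed master RNG seed.
#' @return a `generator_params` list.
#' @export
generator_params <- function(cells,
                             outlier_fraction = 0.25,
                             outlier_multiplier_range = c(4, 10),
                             duplicate_fraction = 0.05,
                             duplicate_gap_seconds = 5,
                             missing_strength_fraction = 0.05,
                             bulk_fraction = 0.10,
                             seed = 1L) {
  stopifnot(all(c("drug", "source", "true_gm", "log_sd", "n") %in%
                  names(cells)))
  if (any(cells$true_gm <= 0) || any(cells$log_sd <= 0) || any(cells$n < 1)) {
    stop("cells must have positive true_gm, log_sd and n", call. = FALSE)
  }
  fracs <- c(outlier_fraction, duplicate_fraction,
             missing_strength_fraction, bulk_fraction)
  if (any(fracs < 0 | fracs >= 1)) {
    stop("all fractions must be in [0, 1)", call. = FALSE)
  }
  if (!(duplicate_gap_seconds > 0 && duplicate_gap_seconds < 10)) {
    stop("duplicate_gap_seconds must be in (0, 10)", call. = FALSE)
  }
  if (any(outlier_multiplier_range <= 1) ||
      outlier_multiplier_range[1] > outlier_multiplier_range[2]) {
    stop("outlier_multiplier_range must be an increasing pair > 1",
         call. = FALSE)
  }
  structure(list(
    cells = tibble::as_tibble(cells),
    outlier_fraction = outlier_fraction,
    outlier_multiplier_range = outlier_multiplier_range,
    duplicate_fraction = duplicate_fraction,
    duplicate_gap_seconds = duplicate_gap_seconds,
    missing_strength_fraction = missing_strength_fraction,
    bulk_fraction = bulk_fraction,
    seed = as.integer(seed)
  ), class = "generator_params")
}

#' Default generator parameters: the published 2012 study conditions
#'
#' Level parameters are taken from [published_price_summary()]: per
#' (drug, source) cell, the true geometric mean is the printed mean and
#' `n` the printed report count; the log-scale SD is back-solved from the
#' printed 95% CI half-width via the log-t interval,
#' `log_sd = (log(ci_high) - log(ci_low)) / 2 * sqrt(n) / qt(0.975, n-1)`,
#' rather than invented. Contamination defaults are the study's own
#' dataset properties: a quarter of crowdsourced submissions rated at the
#' scale endpoints, 10% bulk flags.
#'
#' @param seed master RNG seed.
#' @param ... overrides passed to [generator_params()].
#' @return a `generator_params` object.
#' @export
default_generator_params <- function(seed = 1L, ...) {
  tab <- published_price_summary()
  tab$log_sd <- (log(tab$ci_high) - log(tab$ci_low)) / 2 *
    sqrt(tab$n) / stats::qt(0.975, df = tab$n - 1)
  cells <- tibble::tibble(drug = tab$drug, source = tab$source,
                          true_gm = tab$gm_price_per_mg,
                          log_sd = tab$log_sd, n = tab$n)
  generator_params(cells, seed = seed, ...)
}

random_hex <- function(n, bytes = 6) {
  vapply(seq_len(n), function(i) {
    paste(sprintf("%02x", sample.int(256L, bytes, replace = TRUE) - 1L),
          collapse = "")
  }, character(1))
}

generate_cell <- function(drug, source, true_gm, log_sd, n, params) {
  strength <- unname(TYPICAL_STRENGTH_MG[drug])
  if (is.na(strength)) strength <- 10
  ppm <- stats::rlnorm(n, meanlog = log(true_gm), sdlog = log_sd)

  if (source == "crowdsourced") {
    start <- as.POSIXct("2012-01-01 00:00:00", tz = "UTC")
    submitted <- start + stats::runif(n, 0, 181 * 86400 - 1)
    qty <- rep(1L, n)
    bulk <- rep("no", n)
    is_bulk <- stats::runif(n) < params$bulk_fraction
    qty[is_bulk] <- sample(11:30, sum(is_bulk), replace = TRUE)
    bulk[is_bulk] <- "yes"

    rating <- sample(c(2L, 3L, 4L, NA_integer_), n, replace = TRUE,
                     prob = c(0.25, 0.3, 0.25, 0.2))
    is_out <- stats::runif(n) < params$outlier_fraction
    mult <- stats::runif(n, params$outlier_multiplier_range[1],
                         params$outlier_multiplier_range[2])
    up <- stats::runif(n) < 0.5
    ppm[is_out & up] <- ppm[is_out & up] * mult[is_out & up]
    ppm[is_out & !up] <- ppm[is_out & !up] / mult[is_out & !up]
    rating[is_out & up] <- 5L     # overpriced
    rating[is_out & !up] <- 1L    # cheap

    reports <- tibble::tibble(
      report_id = sprintf("syn-cr-%s-%04d", drug, seq_len(n)),
      source = source, drug = drug,
      formulation = sprintf("%g mg tablet", strength),
      strength_mg = strength, quantity_units = qty,
      total_price_usd = round(ppm * strength * qty, 2),
      transaction_date = as.Date(submitted, tz = "UTC"),
      country = "US",
      region = sample(c("NC", "CO", "MA", "FL", "CA"), n, replace = TRUE),
      rating = rating,
      attribution = sample(c("personal", "swim", "internet"), n,
                           replace = TRUE, prob = c(0.6, 0.3, 0.1)),
      ip_token = random_hex(n),
      submitted_at = submitted,
      bulk_flag = bulk, ship_origin = NA_character_
    )

    miss <- stats::runif(n) < params$missing_strength_fraction
    reports$strength_mg[miss] <- NA_real_

    dup <- stats::runif(n) < params$duplicate_fraction & !miss
    if (any(dup)) {
      clones <- reports[dup, ]
      clones$report_id <- sub("syn-cr", "syn-dp", clones$report_id)
      clones$submitted_at <- clones$submitted_at + params$duplicate_gap_seconds
      clones$transaction_date <- as.Date(clones$submitted_at, tz = "UTC")
      reports <- dplyr::bind_rows(reports, clones)
    }
  } else if (source == "law_enforcement") {
    quarter <- sample(c("2012-01-01", "2012-04-01"), n, replace = TRUE)
    reports <- tibble::tibble(
      report_id = sprintf("syn-le-%s-%04d", drug, seq_len(n)),
      source = source, drug = drug, formulation = NA_character_,
      strength_mg = strength, quantity_units = 1L,
      total_price_usd = round(ppm * strength, 2),
      transaction_date = as.Date(quarter),
      country = "US", region = NA_character_, rating = NA_integer_,
      attribution = NA_character_, ip_token = NA_character_,
      submitted_at = as.POSIXct(NA_real_, tz = "UTC",
                                origin = "1970-01-01"),
      bulk_flag = "unanswered", ship_origin = NA_character_
    )
  } else {
    qty <- sample(c(1L, 2L, 5L, 10L), n, replace = TRUE,
                  prob = c(0.5, 0.2, 0.2, 0.1))
    posting <- as.Date("2012-10-01") + sample(0:30, n, replace = TRUE)
    reports <- tibble::tibble(
      report_id = sprintf("syn-mk-%s-%04d", drug, seq_len(n)),
      source = source, drug = drug, formulation = NA_character_,
      strength_mg = strength, quantity_units = qty,
      total_price_usd = round(ppm * strength * qty, 2),
      transaction_date = posting,
      country = "US", region = NA_character_, rating = NA_integer_,
      attribution = NA_character_, ip_token = NA_character_,
      submitted_at = as.POSIXct(NA_real_, tz = "UTC",
                                origin = "1970-01-01"),
      bulk_flag = "unanswered", ship_origin = "US"
    )
  }
  reports$price_per_mg <- ifelse(
    is.na(reports$strength_mg), NA_real_,
    round(reports$total_price_usd /
            (reports$quantity_units * reports$strength_mg), 4))
  reports[, REPORT_COLUMNS]
}

#' Generate a synthetic price-report stream
#'
#' Draws, per (drug, source) cell, `n` reports whose price per milligram
#' is log-normal around the cell's true geometric mean, then injects the
#' crowdsourced contamination the credibility filters target: a fraction
#' of reports get prices multiplied or divided by a large factor and the
#' corresponding endpoint rating (extreme prices are what users flag);
#' a fraction are cloned a few seconds apart from the same IP token; a
#' fraction lose their dose strength; a fraction carry bulk flags. Output
#' is deterministic for a fixed seed, with one RNG stream per cell.
#'
#' @param params a [generator_params()] object.
#' @return normalized report tibble (clean rows plus contamination).
#' @export
generate_reports <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  cells <- params$cells
  out <- purrr::map(seq_len(nrow(cells)), function(i) {
    key <- paste(cells$drug[i], cells$source[i], sep = "|")
    withr::with_seed(cell_seed(params$seed, key), {
      generate_cell(cells$drug[i], cells$source[i], cells$true_gm[i],
                    cells$log_sd[i], cells$n[i], params)
    })
  })
  dplyr::bind_rows(out)
}

#' Write a synthetic stream as the three raw source CSV dialects
#'
#' Serializes a generated report stream into the dialect files the
#' ingestion module reads (crowdsourced, law-enforcement and marketplace
#' CSVs), plus a daily US$/BTC exchange-rate table covering the
#' marketplace posting dates; marketplace prices are expressed in BTC at
#' that day's rate so ingestion exercises the currency conversion.
#'
#' @param reports report tibble from [generate_reports()].
#' @param dir output directory (created if needed).
#' @return named character vector of the four file paths, invisibly.
#' @export
write_source_csvs <- function(reports, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    crowdsourced = file.path(dir, "crowdsourced.csv"),
    law_enforcement = file.path(dir, "law_enforcement.csv"),
    marketplace = file.path(dir, "marketplace.csv"),
    rates = file.path(dir, "exchange_rates.csv")
  )

  cr <- reports[reports$source == "crowdsourced", ]
  readr::write_csv(tibble::tibble(
    drug = cr$drug, formulation = cr$formulation,
    strength_mg = cr$strength_mg, quantity_units = cr$quantity_units,
    price_usd = sprintf("%.2f", cr$total_price_usd), rating = cr$rating,
    attribution = cr$attribution, ip_hash = cr$ip_token,
    submitted_at = format(cr$submitted_at, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC"),
    country = cr$country, region = cr$region,
    bulk_purchase = ifelse(cr$bulk_flag == "unanswered", NA, cr$bulk_flag)
  ), paths["crowdsourced"], na = "")

  le <- reports[reports$source == "law_enforcement", ]
  readr::write_csv(tibble::tibble(
    drug = le$drug, strength_mg = le$strength_mg,
    price_usd = sprintf("%.2f", le$total_price_usd),
    quarter = sprintf("%dQ%d", as.integer(format(le$transaction_date, "%Y")),
                      (as.integer(format(le$transaction_date, "%m")) - 1L)
                      %/% 3L + 1L)
  ), paths["law_enforcement"], na = "")

  mk <- reports[reports$source == "marketplace", ]
  dates <- seq(as.Date("2012-10-01"), as.Date("2012-10-31"), by = "day")
  # daily weighted-average rate, around the ~11 USD/BTC level of late 2012
  rates <- tibble::tibble(date = dates,
                          usd_per_btc = 11 + 0.05 * seq_along(dates))
  rate_of <- rates$usd_per_btc[match(mk$transaction_date, rates$date)]
  readr::write_csv(tibble::tibble(
    drug = mk$drug, strength_mg = mk$strength_mg,
    quantity_units = mk$quantity_units,
    price_btc = sprintf("%.8f", mk$total_price_usd / rate_of),
    posting_date = format(mk$transaction_date),
    ship_origin = mk$ship_origin
  ), paths["marketplace"], na = "")

  readr::write_csv(rates, paths["rates"], na = "")
  invisible(paths)
}

#' Parameter-recovery study
#'
#' Runs generate -> filter -> summarize for `n_replicates` independent
#' seeds and reports, per (drug, source) cell, the mean recovered
#' geometric mean, its relative bias against the generating truth, and
#' the empirical coverage of the 95% CI. Because outlier selection is
#' independent of the clean price draw and the rating filter removes
#' exactly the injected contamination, the retained prices stay iid
#' log-normal and the estimator should be unbiased with nominal coverage.
#'
#' @param params a [generator_params()] object; its seed is combined with
#'   the replicate index.
#' @param n_replicates number of replicates (>= 1; coverage is only
#'   meaningful for 100 or more).
#' @param config filter configuration applied to each replicate.
#' @param alpha CI error rate.
#' @return tibble with `drug`, `source`, `n_cell`, `true_gm`, `mean_gm`,
#'   `rel_bias`, `coverage`, `n_replicates`.
#' @export
recovery_study <- function(params, n_replicates = 200,
                           config = filter_config(), alpha = 0.05) {
  stopifnot(n_replicates >= 1)
  truth <- params$cells[, c("drug", "source", "true_gm", "n")]
  reps <- purrr::map(seq_len(n_replicates), function(r) {
    p <- params
    p$seed <- (params$seed + 7907L * r) %% 2147483647L
    kept <- apply_filters(generate_reports(p), config)$kept
    sm <- summarize_prices(kept, alpha = alpha)
    sm$replicate <- r
    sm
  })
  dplyr::bind_rows(reps) |>
    dplyr::inner_join(truth, by = c("drug", "source")) |>
    dplyr::group_by(.data$drug, .data$source) |>
    dplyr::summarise(
      n_cell = .data$n.y[1],
      true_gm = .data$true_gm[1],
      mean_gm = mean(.data$gm_price_per_mg),
      rel_bias = mean(.data$gm_price_per_mg) / .data$true_gm[1] - 1,
      coverage = if (dplyr::n() >= 2)
        mean(.data$ci_low <= .data$true_gm & .data$true_gm <= .data$ci_high,
             na.rm = TRUE) else NA_real_,
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
}
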