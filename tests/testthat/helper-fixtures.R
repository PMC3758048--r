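# Fixture builders and independent oracles shared across test files.

# One normalized report row with overridable fields (crowdsourced defaults).
make_report <- function(...) {
  base <- tibble::tibble(
    report_id = "r-1", source = "crowdsourced", drug = "oxycodone",
    formulation = "30 mg tablet", strength_mg = 30, quantity_units = 1L,
    total_price_usd = 30, price_per_mg = 1,
    transaction_date = as.Date("2012-03-01"), country = "US",
    region = "NC", rating = 3L, attribution = "personal",
    ip_token = "aabbcc", submitted_at = as.POSIXct("2012-03-01 12:00:00",
                                                   tz = "UTC"),
    bulk_flag = "no", ship_origin = NA_character_
  )
  dots <- list(...)
  for (nm in names(dots)) base[[nm]] <- dots[[nm]]
  base
}

make_reports <- function(...) {
  rows <- list(...)
  out <- dplyr::bind_rows(rows)
  out$report_id <- sprintf("r-%03d", seq_len(nrow(out)))
  out
}

# Independent sliding-anchor oracle: greedy scan over times sorted
# ascending; keep a time iff no kept time lies strictly within `window`
# seconds before it.
dedup_oracle_keep <- function(times, window = 10) {
  ord <- order(times)
  kept <- logical(length(times))
  last_kept <- -Inf
  for (i in ord) {
    if (times[i] - last_kept < window && is.finite(last_kept)) {
      kept[i] <- FALSE
    } else {
      kept[i] <- TRUE
      last_kept <- times[i]
    }
  }
  kept
}

# Independent permutation enumerator: all n-tuples via expand.grid,
# filtered to permutations (deliberately not the package's algorithm).
perms_oracle <- function(n) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  grid[apply(grid, 1, function(r) length(unique(r)) == n), , drop = FALSE]
}

# Exhaustive two-tailed Spearman permutation p-value via perms_oracle.
spearman_p_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  obs <- abs(stats::cor(rx, ry))
  perms <- perms_oracle(length(x))
  vals <- apply(perms, 1, function(p) abs(stats::cor(rx, ry[p])))
  mean(vals >= obs - 1e-12)
}

# Small constant-price stream: per (drug, source), `n` identical reports
# at the published geometric-mean price (one synthetic strength unit).
published_means_reports <- function(n_per_cell = 3) {
  tab <- published_price_summary()
  rows <- purrr::pmap(tab[, c("drug", "source", "gm_price_per_mg")],
    function(drug, source, gm_price_per_mg) {
      strength <- 10
      make_report(
        source = source, drug = drug, strength_mg = strength,
        formulation = if (source == "crowdsourced") "10 mg tablet"
                      else NA_character_,
        total_price_usd = gm_price_per_mg * strength,
        price_per_mg = gm_price_per_mg,
        rating = NA_integer_, ip_token = NA_character_,
        ship_origin = if (source == "marketplace") "US" else NA_character_
      )[rep(1, n_per_cell), ]
    })
  out <- dplyr::bind_rows(rows)
  out$report_id <- sprintf("pm-%03d", seq_len(nrow(out)))
  out
}

write_fixture_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}
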