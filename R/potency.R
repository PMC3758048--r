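#' Price per morphine-milligram-equivalent
#'
#' Re-expresses a per-milligram price on the morphine scale by dividing by
#' the drug's clinical equianalgesic factor (mg of morphine equianalgesic
#' to 1 mg of the drug), so prices of different molecules are compared per
#' unit of analgesic effect.
#'
#' @param price_per_mg price in US$/mg (vectorized).
#' @param drug drug name(s), must be present in `table`.
#' @param table conversion table from [equianalgesic_table()].
#' @return price in US$ per morphine-mg-equivalent.
#' @export
#' @examples
#' morphine_equivalent_price(3.29, "hydromorphone")  # 0.8225
morphine_equivalent_price <- function(price_per_mg, drug,
                                      table = equianalgesic_table()) {
  idx <- match(tolower(drug), table$drug)
  if (anyNA(idx)) {
    stop("no equianalgesic factor for: ",
         paste(unique(drug[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  price_per_mg / table$factor[idx]
}

#' Predicted relative potency from street prices
#'
#' The market's implicit potency estimate: each drug's geometric-mean
#' price per milligram divided by morphine's. If the black market prices
#' drugs in proportion to their pharmacologic effect, this ratio should
#' track the clinical equianalgesic factor. When raw reports are supplied
#' a nonparametric bootstrap percentile CI of the ratio is computed by
#' resampling each drug's reports and morphine's independently on the log
#' scale; without raw reports the point estimate is returned alone,
#' because the published per-drug CIs do not combine into a ratio CI by
#' interval arithmetic.
#'
#' @param summaries summary tibble (one source) from [summarize_prices()],
#'   or any tibble with `drug` and `gm_price_per_mg`.
#' @param reports optional raw report tibble for the same source, used for
#'   the bootstrap CI.
#' @param reference reference drug (potency 1 by construction).
#' @param table clinical conversion table for the comparison column; drugs
#'   absent from it (e.g. buprenorphine, which lacks an accepted oral
#'   factor) get `NA` clinical factors and no comparison label.
#' @param n_boot bootstrap resamples.
#' @param alpha two-sided error rate for the bootstrap CI.
#' @param seed RNG seed for the bootstrap (fixed for reproducibility).
#' @return tibble with `drug`, `n`, `gm_price_per_mg`, `predicted_potency`,
#'   `ci_low`, `ci_high`, `clinical_factor`, `comparison`. The reference
#'   drug's potency is exactly 1.
#' @export
predicted_relative_potency <- function(summaries, reports = NULL,
                                       reference = "morphine",
                                       table = equianalgesic_table(),
                                       n_boot = 2000, alpha = 0.05,
                                       seed = 20120101) {
  if (length(unique(summaries$source)) > 1) {
    stop("summaries must be restricted to a single source", call. = FALSE)
  }
  if (!reference %in% summaries$drug) {
    stop(sprintf("reference drug '%s' absent from summaries", reference),
         call. = FALSE)
  }
  ref_gm <- summaries$gm_price_per_mg[summaries$drug == reference]
  out <- tibble::tibble(
    drug = summaries$drug,
    n = if ("n" %in% names(summaries)) summaries$n else NA_integer_,
    gm_price_per_mg = summaries$gm_price_per_mg,
    predicted_potency = summaries$gm_price_per_mg / ref_gm,
    ci_low = NA_real_, ci_high = NA_real_
  )
  out$predicted_potency[out$drug == reference] <- 1  # exact by construction

  if (!is.null(reports)) {
    dat <- reports[!is.na(reports$price_per_mg) & reports$price_per_mg > 0, ]
    logs <- split(log(dat$price_per_mg), dat$drug)
    ref_logs <- logs[[reference]]
    if (is.null(ref_logs)) {
      stop("raw reports contain no reference-drug prices", call. = FALSE)
    }
    withr::with_seed(seed, {
      ref_boot <- vapply(seq_len(n_boot), function(i) {
        mean(ref_logs[sample.int(length(ref_logs), replace = TRUE)])
      }, numeric(1))
      for (i in seq_len(nrow(out))) {
        d <- out$drug[i]
        if (d == reference || is.null(logs[[d]]) || length(logs[[d]]) < 2) next
        lv <- logs[[d]]
        drug_boot <- vapply(seq_len(n_boot), function(j) {
          mean(lv[sample.int(length(lv), replace = TRUE)])
        }, numeric(1))
        ci <- stats::quantile(exp(drug_boot - ref_boot),
                              c(alpha / 2, 1 - alpha / 2), names = FALSE)
        out$ci_low[i] <- ci[1]
        out$ci_high[i] <- ci[2]
      }
    })
  }

  out$clinical_factor <- table$factor[match(out$drug, table$drug)]
  out$comparison <- compare_potency_to_clinical(out$ci_low, out$ci_high,
                                                out$clinical_factor)
  dplyr::arrange(out, dplyr::desc(.data$predicted_potency))
}

#' Label a potency estimate against its clinical factor
#'
#' `indistinguishable` when the CI contains the clinical factor,
#' `valued_higher` when the whole CI lies above it (the street values the
#' drug more per mg than the clinic), `valued_lower` when below. `NA`
#' where the CI or the clinical factor is unavailable.
#'
#' @param ci_low,ci_high CI bounds of the predicted potency (vectorized).
#' @param clinical_factor clinical equianalgesic factor(s).
#' @return character vector of labels.
#' @export
#' @examples
#' compare_potency_to_clinical(5.8, 6.8, 4)  # valued_higher
compare_potency_to_clinical <- function(ci_low, ci_high, clinical_factor) {
  if (any(!is.na(ci_low) & !is.na(ci_high) & ci_low > ci_high)) {
    stop("ci_low must be <= ci_high", call. = FALSE)
  }
  dplyr::case_when(
    is.na(ci_low) | is.na(ci_high) | is.na(clinical_factor) ~ NA_character_,
    ci_low > clinical_factor ~ "valued_higher",
    ci_high < clinical_factor ~ "valued_lower",
    TRUE ~ "indistinguishable"
  )
}

#' Display rounding for potency ratios
#'
#' Ratios print with 1 decimal, except values below 0.5 which keep 2
#' decimals so small ratios (e.g. tramadol) are not flattened to one
#' significant figure.
#'
#' @param x numeric ratios.
#' @return character vector.
#' @export
format_potency <- function(x) {
  ifelse(is.na(x), NA_character_,
         ifelse(x < 0.5, sprintf("%.2f", round(x, 2)),
                sprintf("%.1f", round(x, 1))))
}
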