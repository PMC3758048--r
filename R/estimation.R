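#' Geometric mean with a 95% confidence interval
#'
#' Summary statistic for skewed positive prices: `exp(mean(log(x)))`. The
#' default interval is the log-scale Student-t interval,
#' `exp(mean(log x) +/- t(1 - alpha/2, n - 1) * sd(log x) / sqrt(n))`,
#' the standard choice for log-normally distributed prices; a
#' nonparametric bootstrap percentile interval is available as an
#' alternative. With a single observation the geometric mean is the value
#' itself and the interval is undefined (`ci_defined = FALSE`).
#'
#' @param values positive prices (US$/mg or any positive quantity).
#' @param alpha two-sided error rate; 0.05 gives a 95% CI.
#' @param method `"t"` (log-scale t interval) or `"bootstrap"`
#'   (percentile, `n_boot` resamples of the log mean).
#' @param n_boot bootstrap resamples (bootstrap method only).
#' @return list with `gm`, `ci_low`, `ci_high`, `n`, `ci_defined`.
#' @export
#' @examples
#' geometric_mean_ci(c(1, 10, 100))
geometric_mean_ci <- function(values, alpha = 0.05,
                              method = c("t", "bootstrap"), n_boot = 2000) {
  method <- match.arg(method)
  if (length(values) == 0) stop("empty input", call. = FALSE)
  if (any(!is.finite(values) | values <= 0)) {
    stop("all values must be positive", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  lv <- log(values)
  n <- length(lv)
  gm <- exp(mean(lv))
  if (n == 1) {
    return(list(gm = gm, ci_low = NA_real_, ci_high = NA_real_, n = 1L,
                ci_defined = FALSE))
  }
  if (method == "t") {
    half <- stats::qt(1 - alpha / 2, df = n - 1) * stats::sd(lv) / sqrt(n)
    ci <- exp(mean(lv) + c(-1, 1) * half)
  } else {
    boot_means <- vapply(seq_len(n_boot), function(i) {
      mean(lv[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
    ci <- exp(stats::quantile(boot_means, c(alpha / 2, 1 - alpha / 2),
                              names = FALSE, type = 7))
  }
  list(gm = gm, ci_low = ci[1], ci_high = ci[2], n = n, ci_defined = TRUE)
}

#' Per-drug, per-source price summaries
#'
#' Computes the geometric mean price per milligram with its confidence
#' interval for every (drug, source) pair present in the report stream.
#' Zero-price reports (free sharing) carry no information about prices
#' paid and have no logarithm; they are excluded from the computation and
#' counted in the `n_zero_excluded` attribute. Rows are ordered by source,
#' then by descending geometric mean.
#'
#' @param reports filtered report tibble with `price_per_mg` populated.
#' @param alpha two-sided error rate for the CIs.
#' @param method CI method, see [geometric_mean_ci()].
#' @return tibble with columns `drug`, `source`, `n`, `gm_price_per_mg`,
#'   `ci_low`, `ci_high`, `alpha`; attribute `n_zero_excluded`.
#' @export
summarize_prices <- function(reports, alpha = 0.05, method = "t") {
  if (any(is.na(reports$price_per_mg))) {
    stop("all reports must have price_per_mg populated; run the ",
         "completeness filter first", call. = FALSE)
  }
  zero <- reports$price_per_mg <= 0
  priced <- reports[!zero, , drop = FALSE]
  out <- priced |>
    dplyr::group_by(.data$drug, .data$source) |>
    dplyr::group_modify(function(df, key) {
      ci <- geometric_mean_ci(df$price_per_mg, alpha = alpha, method = method)
      tibble::tibble(n = ci$n, gm_price_per_mg = ci$gm,
                     ci_low = ci$ci_low, ci_high = ci$ci_high)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(alpha = alpha) |>
    dplyr::arrange(.data$source, dplyr::desc(.data$gm_price_per_mg))
  attr(out, "n_zero_excluded") <- sum(zero)
  out
}
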