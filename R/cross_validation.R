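#' All permutations of 1..n
#'
#' Exhaustive n! x n matrix of orderings, used by the exact permutation
#' branch of [spearman_pvalue()]. Intended for small n (the exact branch
#' caps at n = 10).
#' @param n number of elements.
#' @return integer matrix with n! rows.
#' @keywords internal
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 10)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

rank_avg <- function(x) rank(x, ties.method = "average")

#' Spearman rank correlation coefficient
#'
#' `1 - 6 * sum(d^2) / (n (n^2 - 1))` on untied ranks; with ties, the
#' Pearson product-moment correlation of average ranks (the tie-corrected
#' definition). Invariant under strictly monotone transforms of either
#' vector.
#'
#' @param x,y paired numeric vectors (paired by drug in the cross-source
#'   use), length >= 3.
#' @return rho in `[-1, 1]`.
#' @export
#' @examples
#' spearman_rho(1:5, c(2, 4, 6, 8, 10))  # 1
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  rx <- rank_avg(x)
  ry <- rank_avg(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    stop("rho undefined for constant input", call. = FALSE)
  }
  tied <- anyDuplicated(rx) || anyDuplicated(ry)
  if (!tied) {
    1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
  } else {
    # Pearson on ranks, written out so the tie correction is explicit
    (sum(rx * ry) - n * mean(rx) * mean(ry)) /
      ((n - 1) * stats::sd(rx) * stats::sd(ry))
  }
}

#' P-value for the Spearman correlation
#'
#' Tests independence of the two rankings. For n <= `exact_n_max` (default
#' 10) the null distribution is enumerated exactly over all n!
#' arrangements of one rank vector and the p-value is the proportion of
#' arrangements at least as extreme as the observed rho; printed p-values
#' at n = 8 drugs cannot be trusted to an asymptotic formula, and 8! =
#' 40320 arrangements are trivial to enumerate. Larger n falls back to the
#' Student-t approximation `t = rho sqrt((n-2)/(1-rho^2))`.
#'
#' @inheritParams spearman_rho
#' @param two_tailed compare `|rho|` (default) or the upper tail only.
#' @param exact_n_max largest n for which the exact branch is used.
#' @return list with `rho`, `p_value`, `method` (`"exact_permutation"` or
#'   `"t_approximation"`), and `n`.
#' @export
spearman_pvalue <- function(x, y, two_tailed = TRUE, exact_n_max = 10) {
  rho <- spearman_rho(x, y)  # validates input
  n <- length(x)
  eps <- 1e-12
  if (n <= exact_n_max) {
    rx <- rank_avg(x)
    ry <- rank_avg(y)
    perms <- all_permutations(n)
    s <- as.vector(matrix(ry[perms], nrow(perms), n) %*% rx)
    rho_perm <- (s - n * mean(rx) * mean(ry)) /
      ((n - 1) * stats::sd(rx) * stats::sd(ry))
    p <- if (two_tailed) {
      mean(abs(rho_perm) >= abs(rho) - eps)
    } else {
      mean(rho_perm >= rho - eps)
    }
    list(rho = rho, p_value = p, method = "exact_permutation", n = n)
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- stats::pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
    if (two_tailed) p <- 2 * p
    list(rho = rho, p_value = min(p, 1), method = "t_approximation", n = n)
  }
}

#' Pairwise cross-source agreement
#'
#' For every unordered pair of sources, correlates the per-drug geometric
#' mean prices on the drugs the two sources share (Spearman rho with its
#' p-value). Agreement of independently collected price streams is the
#' study's validation argument: monotone agreement of per-drug means
#' across sources indicates each stream measures the same underlying
#' market. Pairs sharing fewer than 3 drugs are skipped with a warning.
#'
#' @param summaries summary tibble from [summarize_prices()] (or any tibble
#'   with `drug`, `source`, `gm_price_per_mg`).
#' @param two_tailed passed to [spearman_pvalue()].
#' @return tibble with `source_a`, `source_b`, `n_drugs`, `rho`, `p_value`,
#'   `method`.
#' @export
cross_source_matrix <- function(summaries, two_tailed = TRUE) {
  sources <- sort(unique(summaries$source))
  if (length(sources) < 2) {
    stop("need at least 2 sources", call. = FALSE)
  }
  pairs <- utils::combn(sources, 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(pr) {
    a <- summaries[summaries$source == pr[1], ]
    b <- summaries[summaries$source == pr[2], ]
    shared <- intersect(a$drug, b$drug)
    if (length(shared) < 3) {
      warning(sprintf("sources %s and %s share %d drug(s); need 3 - skipped",
                      pr[1], pr[2], length(shared)), call. = FALSE)
      return(NULL)
    }
    res <- spearman_pvalue(a$gm_price_per_mg[match(shared, a$drug)],
                           b$gm_price_per_mg[match(shared, b$drug)],
                           two_tailed = two_tailed)
    tibble::tibble(source_a = pr[1], source_b = pr[2],
                   n_drugs = length(shared), rho = res$rho,
                   p_value = res$p_value, method = res$method)
  })
  dplyr::bind_rows(rows)
}

#' Test a drug's price difference across sources
#'
#' One-way heteroscedastic (Welch) ANOVA on log prices per milligram
#' across sources, chosen for robustness to the unequal group sizes and
#' variances typical of the three streams. With exactly two sources this
#' reduces to the two-sample Welch t-test (the F statistic is the squared
#' t). No multiple-testing correction is applied by default (per-drug
#' testing); `p_adjust_method` applies one when several drugs are tested
#' together via [compare_all_drugs()].
#'
#' @param reports filtered report tibble (positive `price_per_mg`).
#' @param drug drug to test.
#' @return list with `statistic` (F), `df` (numerator, denominator),
#'   `p_value`, `method`, and `summaries` (per-source geometric means the
#'   test compared).
#' @export
compare_drug_across_sources <- function(reports, drug) {
  dat <- reports[reports$drug == drug & !is.na(reports$price_per_mg) &
                   reports$price_per_mg > 0, , drop = FALSE]
  counts <- table(dat$source)
  if (length(counts) < 2) {
    stop(sprintf("drug '%s' present in fewer than 2 sources", drug),
         call. = FALSE)
  }
  small <- names(counts)[counts < 2]
  if (length(small)) {
    stop(sprintf("drug '%s': source(s) %s have fewer than 2 reports", drug,
                 paste(small, collapse = ", ")), call. = FALSE)
  }
  lp <- log(dat$price_per_mg)
  if (all(tapply(lp, dat$source, stats::var) == 0)) {
    stop("degenerate input: zero variance in every source", call. = FALSE)
  }
  fit <- stats::oneway.test(lp ~ source, data = data.frame(
    lp = lp, source = dat$source), var.equal = FALSE)
  list(
    statistic = unname(fit$statistic),
    df = unname(fit$parameter),
    p_value = unname(fit$p.value),
    method = "welch_anova_log_price",
    summaries = summarize_prices(dat)
  )
}

#' Welch test for every drug with enough data
#'
#' Runs [compare_drug_across_sources()] for each drug observed in at least
#' 2 sources with at least 2 positive-price reports each; other drugs are
#' omitted.
#'
#' @param reports filtered report tibble.
#' @param p_adjust_method multiplicity correction passed to
#'   [stats::p.adjust()]; `"none"` (default) matches per-drug testing.
#' @return tibble with `drug`, `statistic`, `df1`, `df2`, `p_value`,
#'   `p_adjusted`.
#' @export
compare_all_drugs <- function(reports, p_adjust_method = "none") {
  dat <- reports[!is.na(reports$price_per_mg) & reports$price_per_mg > 0, ]
  eligible <- dat |>
    dplyr::count(.data$drug, .data$source) |>
    dplyr::filter(.data$n >= 2) |>
    dplyr::count(.data$drug) |>
    dplyr::filter(.data$n >= 2) |>
    dplyr::pull(.data$drug)
  rows <- purrr::map(sort(eligible), function(d) {
    sub <- dat[dat$drug == d, ]
    sub <- sub[sub$source %in% names(which(table(sub$source) >= 2)), ]
    if (all(tapply(log(sub$price_per_mg), sub$source, stats::var) == 0)) {
      warning(sprintf("drug '%s': zero variance in every source - skipped",
                      d), call. = FALSE)
      return(NULL)
    }
    res <- compare_drug_across_sources(sub, d)
    tibble::tibble(drug = d, statistic = res$statistic,
                   df1 = res$df[1], df2 = res$df[2], p_value = res$p_value)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(drug = character(), statistic = double(),
                          df1 = double(), df2 = double(),
                          p_value = double(), p_adjusted = double()))
  }
  out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust_method)
  out
}
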