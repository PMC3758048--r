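crowd <- c(3.29, 2.13, 1.57, 0.96, 0.97, 0.81, 0.52, 0.05)
law <- c(4.47, 2.35, 1.64, 1.16, 0.86, 0.90, 0.67, 0.09)
market <- c(3.55, 2.58, 1.58, 0.93, 0.99, 0.97, 0.42, 0.02)

test_that("rho reproduces the published cross-source correlations", {
  expect_equal(spearman_rho(crowd, law), 1 - 36 / 504)
  expect_equal(round(spearman_rho(crowd, law), 2), 0.93)
  expect_equal(spearman_rho(crowd, market), 1 - 12 / 504)
  expect_equal(round(spearman_rho(crowd, market), 2), 0.98)
  expect_equal(spearman_rho(law, market), 1 - 48 / 504)
  expect_equal(round(spearman_rho(law, market), 2), 0.90)
})

test_that("rho honors rank identities and its contracts", {
  x <- c(2, 7, 1, 9, 4)
  expect_equal(spearman_rho(x, x), 1)
  expect_equal(spearman_rho(x, -x), -1)
  expect_equal(spearman_rho(sort(x), rev(sort(x))), -1)
  expect_error(spearman_rho(1:4, 1:5), "length")
  expect_error(spearman_rho(1:2, 2:1), "3")
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})

test_that("rho is invariant under strictly monotone transforms and
           matches the reference implementation", {
  set.seed(12)
  for (i in 1:30) {
    n <- sample(4:20, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    expect_equal(spearman_rho(x, y),
                 unname(cor(x, y, method = "spearman")))
    expect_equal(spearman_rho(exp(x), y), spearman_rho(x, y))
    expect_equal(spearman_rho(x, y^3), spearman_rho(x, y))
    # tied case also matches Pearson-on-ranks
    xt <- round(x, 0)
    if (var(rank(xt)) > 0) {
      expect_equal(spearman_rho(xt, y),
                   unname(cor(xt, y, method = "spearman")))
    }
  }
})

test_that("exact permutation p-values match exhaustive enumeration", {
  # perfectly concordant n = 4: only identity and reversal are as extreme
  res <- spearman_pvalue(1:4, c(10, 20, 30, 40))
  expect_equal(res$p_value, 2 / 24)
  expect_equal(res$method, "exact_permutation")

  set.seed(77)
  for (i in 1:12) {
    n <- sample(4:6, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    res <- spearman_pvalue(x, y)
    expect_equal(res$p_value, spearman_p_oracle(x, y))
    # and the independent AS-89 exact distribution in cor.test
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
    expect_equal(res$p_value, ct$p.value, tolerance = 1e-10)
  }
  # ties: enumeration oracle only (cor.test refuses exact ties)
  xt <- c(1, 1, 2, 3, 4)
  yt <- c(2, 1, 4, 4, 5)
  expect_equal(spearman_pvalue(xt, yt)$p_value, spearman_p_oracle(xt, yt))
  expect_error(spearman_pvalue(rep(2, 4), 1:4), "constant")
})

test_that("published-scale p-values: exact branch at n = 8, and the
           t-approximation that the printed values reflect", {
  exact <- spearman_pvalue(crowd, law)
  expect_equal(exact$method, "exact_permutation")
  expect_equal(exact$p_value, 90 / 40320) # independent enumeration oracle
  expect_lt(exact$p_value, 0.05)
  approx <- spearman_pvalue(crowd, law, exact_n_max = 0)
  expect_equal(approx$method, "t_approximation")
  expect_lt(approx$p_value, 0.001)
  approx_lm <- spearman_pvalue(law, market, exact_n_max = 0)
  expect_equal(round(approx_lm$p_value, 3), 0.002)
})

test_that("cross_source_matrix intersects drugs and skips thin pairs", {
  sm <- published_price_summary()
  cm <- cross_source_matrix(sm)
  expect_equal(nrow(cm), 3)
  expect_equal(cm$n_drugs, rep(8L, 3))
  rho_of <- function(a, b) cm$rho[cm$source_a == a & cm$source_b == b]
  expect_equal(round(rho_of("crowdsourced", "law_enforcement"), 2), 0.93)
  expect_equal(round(rho_of("crowdsourced", "marketplace"), 2), 0.98)
  expect_equal(round(rho_of("law_enforcement", "marketplace"), 2), 0.90)
  expect_true(all(cm$p_value < 0.05))

  dup <- sm[sm$source == "crowdsourced", ]
  dup2 <- dplyr::mutate(dup, source = "law_enforcement")
  cm_id <- cross_source_matrix(dplyr::bind_rows(dup, dup2))
  expect_equal(cm_id$rho, 1)

  disjoint <- dplyr::bind_rows(
    dup[1:3, ],
    dplyr::mutate(dup[4:6, ], source = "marketplace"))
  expect_warning(res <- cross_source_matrix(disjoint), "skipped")
  expect_equal(nrow(res), 0)
  expect_error(cross_source_matrix(dup), "2 sources")
})

test_that("the Welch test on logs reduces to the squared Welch t with two
           sources and detects separated medians", {
  set.seed(5)
  a <- rlnorm(30, log(0.5), 0.6)
  b <- rlnorm(50, log(0.8), 0.3)
  reports <- dplyr::bind_rows(
    make_report(price_per_mg = 1)[rep(1, 30), ] |>
      dplyr::mutate(price_per_mg = a),
    make_report(source = "law_enforcement", price_per_mg = 1)[rep(1, 50), ] |>
      dplyr::mutate(price_per_mg = b))
  res <- compare_drug_across_sources(reports, "oxycodone")
  tt <- t.test(log(a), log(b), var.equal = FALSE)
  expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(res$method, "welch_anova_log_price")

  # 10-fold separated medians, n = 50 each: decisive rejection
  set.seed(6)
  big <- dplyr::bind_rows(
    make_report(price_per_mg = 1)[rep(1, 50), ] |>
      dplyr::mutate(price_per_mg = rlnorm(50, log(0.1), 0.5)),
    make_report(source = "marketplace", price_per_mg = 1)[rep(1, 50), ] |>
      dplyr::mutate(price_per_mg = rlnorm(50, log(1.0), 0.5)))
  expect_lt(compare_drug_across_sources(big, "oxycodone")$p_value, 0.001)

  # error contracts
  expect_error(compare_drug_across_sources(make_report(), "oxycodone"),
               "fewer than 2 sources")
  thin <- dplyr::bind_rows(
    make_report(), make_report(),
    make_report(source = "marketplace"))
  expect_error(compare_drug_across_sources(thin, "oxycodone"), "marketplace")
  flat <- dplyr::bind_rows(
    make_report()[rep(1, 3), ],
    make_report(source = "marketplace")[rep(1, 3), ])
  expect_error(compare_drug_across_sources(flat, "oxycodone"), "degenerate")
})

test_that("type-I error of the Welch branch is nominal under the null", {
  template <- make_report()[rep(1, 60), ]
  template$source <- rep(report_sources(), each = 20)
  set.seed(2026)
  pvals <- replicate(2000, {
    template$price_per_mg <- rlnorm(60, log(0.8), 0.5)
    compare_drug_across_sources(template, "oxycodone")$p_value
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.015)
  # p roughly uniform under the null
  expect_lt(abs(mean(pvals) - 0.5), 0.04)
})
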