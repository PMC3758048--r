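config <- filter_config()

test_that("completeness keeps only reports with strength and formulation", {
  reports <- make_reports(
    make_report(),
    make_report(strength_mg = NA_real_, price_per_mg = NA_real_),
    make_report()
  )
  part <- filter_completeness(reports, config)
  expect_equal(nrow(part$kept), 2)
  expect_equal(nrow(part$removed), 1)
  all_complete <- make_reports(make_report(), make_report())
  expect_equal(nrow(filter_completeness(all_complete, config)$kept), 2)
  empty <- make_report()[0, ]
  expect_equal(nrow(filter_completeness(empty, config)$kept), 0)
})

test_that("endpoint ratings are excluded for crowdsourced reports only", {
  reports <- make_reports(
    make_report(rating = 1L), make_report(rating = 2L),
    make_report(rating = 3L), make_report(rating = 4L),
    make_report(rating = 5L), make_report(rating = NA_integer_)
  )
  part <- filter_outlier_ratings(reports, config)
  expect_equal(sort(part$kept$rating, na.last = TRUE), c(2L, 3L, 4L, NA))
  expect_setequal(part$removed$rating, c(1L, 5L))

  le <- make_report(source = "law_enforcement", rating = NA_integer_,
                    ip_token = NA_character_)
  expect_equal(nrow(filter_outlier_ratings(le, config)$kept), 1)
  mid <- make_reports(make_report(rating = 3L), make_report(rating = 3L))
  expect_equal(nrow(filter_outlier_ratings(mid, config)$kept), 2)
})

test_that("near-simultaneous same-IP duplicates collapse to the earliest", {
  t0 <- as.POSIXct("2012-03-01 12:00:00", tz = "UTC")
  pair <- make_reports(
    make_report(submitted_at = t0),
    make_report(submitted_at = t0 + 5)
  )
  part <- deduplicate(pair, config)
  expect_equal(part$kept$submitted_at, t0)

  diff_drug <- make_reports(
    make_report(submitted_at = t0),
    make_report(submitted_at = t0 + 5, drug = "morphine")
  )
  expect_equal(nrow(deduplicate(diff_drug, config)$kept), 2)

  # sliding anchor: 0, 6, 12 s keeps 0 and 12
  chain <- make_reports(
    make_report(submitted_at = t0),
    make_report(submitted_at = t0 + 6),
    make_report(submitted_at = t0 + 12)
  )
  part <- deduplicate(chain, config)
  expect_equal(as.numeric(part$kept$submitted_at) - as.numeric(t0), c(0, 12))
})

test_that("dedup agrees with a brute-force oracle on small groups", {
  t0 <- as.POSIXct("2012-03-01 12:00:00", tz = "UTC")
  set.seed(99)
  for (rep in 1:40) {
    k <- sample(2:5, 1)
    offsets <- sort(round(runif(k, 0, 40), 1))
    reports <- dplyr::bind_rows(purrr::map(
      offsets, function(o) make_report(submitted_at = t0 + o)))
    reports$report_id <- sprintf("r-%02d", seq_len(k))
    kept <- deduplicate(reports, config)$kept
    oracle <- dedup_oracle_keep(offsets, 10)
    expect_equal(kept$submitted_at, (t0 + offsets)[oracle])
  }
})

test_that("apply_filters audits each rule and conserves counts", {
  t0 <- as.POSIXct("2012-03-01 12:00:00", tz = "UTC")
  reports <- make_reports(
    make_report(),                                        # clean
    make_report(transaction_date = as.Date("2011-06-01"), # outside window
                submitted_at = as.POSIXct("2011-06-01 10:00:00", tz = "UTC")),
    make_report(strength_mg = NA_real_, price_per_mg = NA_real_),
    make_report(rating = 5L),
    make_report(ip_token = "dupip", submitted_at = t0),
    make_report(ip_token = "dupip", submitted_at = t0 + 4),  # dup of above
    make_report(drug = "morphine"),
    make_report(drug = "tramadol", ip_token = "x1"),
    make_report(source = "law_enforcement", rating = NA_integer_,
                ip_token = NA_character_,
                submitted_at = as.POSIXct(NA, tz = "UTC")),
    make_report(source = "marketplace", ship_origin = "US",
                rating = NA_integer_, ip_token = NA_character_,
                submitted_at = as.POSIXct(NA, tz = "UTC"),
                transaction_date = as.Date("2012-10-05"))
  )
  res <- apply_filters(reports, config)
  expect_s3_class(res, "filter_result")
  expect_equal(nrow(res$kept), 6)
  expect_equal(unname(res$removed_by_rule[c("eligibility", "completeness",
                                            "outlier_rating", "duplicate")]),
               c(1L, 1L, 1L, 1L))
  expect_equal(nrow(res$kept) + sum(res$removed_by_rule), nrow(reports))

  # disabled rules: only completeness and dedup act
  loose <- filter_config(window_start = "2000-01-01",
                         window_end = "2030-01-01",
                         exclude_ratings = integer(0))
  res2 <- apply_filters(reports, loose)
  expect_equal(unname(res2$removed_by_rule[["outlier_rating"]]), 0L)
  expect_equal(unname(res2$removed_by_rule[["eligibility"]]), 0L)

  # idempotence: filtering the kept set removes nothing
  res3 <- apply_filters(res$kept, config)
  expect_equal(res3$kept, res$kept)
  expect_equal(sum(res3$removed_by_rule), 0L)
})

test_that("conservation and idempotence hold on generated streams", {
  params <- default_generator_params(seed = 5)
  reports <- generate_reports(params)
  res <- apply_filters(reports, config)
  expect_equal(nrow(res$kept) + sum(res$removed_by_rule), nrow(reports))
  res2 <- apply_filters(res$kept, config)
  expect_equal(sum(res2$removed_by_rule), 0L)
})

test_that("kept set is invariant to rule order when dedup runs last", {
  params <- default_generator_params(seed = 23)
  params$cells <- params$cells[params$cells$source == "crowdsourced" &
                                 params$cells$drug %in%
                                   c("oxycodone", "morphine"), ]
  reports <- generate_reports(params)
  rules <- list(
    eligibility = streetpricer:::filter_eligibility,
    completeness = filter_completeness,
    outlier_rating = filter_outlier_ratings
  )
  run_order <- function(ord) {
    kept <- reports
    for (rule in rules[ord]) kept <- rule(kept, config)$kept
    deduplicate(kept, config)$kept$report_id
  }
  baseline <- run_order(1:3)
  for (ord in list(c(2, 1, 3), c(3, 2, 1), c(1, 3, 2))) {
    expect_equal(sort(run_order(ord)), sort(baseline))
  }
})

test_that("invalid configurations are refused", {
  expect_error(filter_config(window_start = "2012-06-01",
                             window_end = "2012-01-01"), "window")
  expect_error(filter_config(duplicate_window_seconds = 0), "positive")
  expect_error(filter_config(exclude_ratings = c(0, 9)), "subset")
  expect_error(apply_filters(make_report(), list()), "filter_config")
})

test_that("bulk exclusion is a switch, off by default", {
  reports <- make_reports(make_report(bulk_flag = "yes", ip_token = "i1"),
                          make_report(bulk_flag = "no", ip_token = "i2"),
                          make_report(bulk_flag = "unanswered",
                                      ip_token = "i3"))
  expect_equal(nrow(apply_filters(reports, config)$kept), 3)
  strict <- filter_config(exclude_bulk = TRUE)
  res <- apply_filters(reports, strict)
  expect_equal(nrow(res$kept), 2)
  expect_equal(unname(res$removed_by_rule[["bulk"]]), 1L)
})
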