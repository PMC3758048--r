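test_that("crowdsourced rows normalize with price per mg", {
  path <- write_fixture_csv(c(
    "drug,formulation,strength_mg,quantity_units,price_usd,rating,attribution,ip_hash,submitted_at,country,region,bulk_purchase",
    "oxycodone,30 mg tablet,30,1,30,3,personal,abc123,2012-03-01T12:00:00,US,NC,no"
  ))
  res <- read_reports(path, "crowdsourced")
  expect_equal(nrow(res$reports), 1)
  expect_equal(nrow(res$rejects), 0)
  r <- res$reports
  expect_equal(r$price_per_mg, 1.00)
  expect_equal(r$drug, "oxycodone")
  expect_equal(r$transaction_date, as.Date("2012-03-01"))
  expect_equal(r$rating, 3L)
  expect_equal(r$bulk_flag, "no")
})

test_that("marketplace BTC prices convert at the daily rate", {
  rates <- tibble::tibble(date = as.Date("2012-10-05"), usd_per_btc = 11)
  path <- write_fixture_csv(c(
    "drug,strength_mg,quantity_units,price_btc,posting_date,ship_origin",
    "morphine,15,10,5.4545,2012-10-05,US"
  ))
  res <- read_reports(path, "marketplace", rates = rates)
  expect_equal(nrow(res$rejects), 0)
  expect_equal(res$reports$total_price_usd, 60.00)
  expect_equal(res$reports$price_per_mg, 0.40)

  # a posting date absent from the rate table rejects the row, by name
  path2 <- write_fixture_csv(c(
    "drug,strength_mg,quantity_units,price_btc,posting_date,ship_origin",
    "morphine,15,10,5.4545,2012-10-06,US"
  ))
  res2 <- read_reports(path2, "marketplace", rates = rates)
  expect_equal(nrow(res2$reports), 0)
  expect_equal(res2$rejects$reason, "no exchange rate")
})

test_that("empty files and unknown dialects behave per contract", {
  path <- write_fixture_csv(
    "drug,formulation,strength_mg,quantity_units,price_usd,rating,attribution,ip_hash,submitted_at,country,region,bulk_purchase")
  res <- read_reports(path, "crowdsourced")
  expect_equal(nrow(res$reports), 0)
  expect_equal(nrow(res$rejects), 0)
  expect_error(read_reports(path, "dark_web"), "arg")
})

test_that("law-enforcement rows carry quantity 1 and quarter dates", {
  path <- write_fixture_csv(c(
    "drug,strength_mg,price_usd,quarter",
    "morphine,30,20.10,2012Q2",
    "oxycodone,30,29,2012Q9"
  ))
  res <- read_reports(path, "law_enforcement")
  expect_equal(nrow(res$reports), 1)
  expect_equal(res$reports$quantity_units, 1L)
  expect_equal(res$reports$transaction_date, as.Date("2012-04-01"))
  expect_equal(res$reports$price_per_mg, 0.67)
  expect_equal(res$rejects$reason, "invalid quarter")
})

test_that("rows failing mandatory fields are rejected, never dropped", {
  path <- write_fixture_csv(c(
    "drug,formulation,strength_mg,quantity_units,price_usd,rating,attribution,ip_hash,submitted_at,country,region,bulk_purchase",
    "oxycodone,tab,30,1,30,3,personal,a,2012-03-01T12:00:00,US,NC,no",
    "notadrug,tab,30,1,30,3,personal,a,2012-03-01T12:00:00,US,NC,no",
    "oxycodone,tab,-5,1,30,3,personal,a,2012-03-01T12:00:00,US,NC,no",
    "oxycodone,tab,30,1,,3,personal,a,2012-03-01T12:00:00,US,NC,no",
    "oxycodone,tab,30,1,30,7,personal,a,2012-03-01T12:00:00,US,NC,no",
    "oxycodone,tab,,1,30,3,personal,a,2012-03-01T12:00:00,US,NC,no"
  ))
  res <- read_reports(path, "crowdsourced")
  # row conservation: parsed + rejected = input rows
  expect_equal(nrow(res$reports) + nrow(res$rejects), 6)
  expect_setequal(res$rejects$reason,
                  c("unknown drug", "invalid strength", "missing price",
                    "invalid rating"))
  # missing strength is not a parse failure; price_per_mg stays NA
  kept_na <- res$reports[is.na(res$reports$strength_mg), ]
  expect_equal(nrow(kept_na), 1)
  expect_true(is.na(kept_na$price_per_mg))
})

test_that("brand synonyms normalize and unknown names return NA", {
  expect_equal(normalize_drug_name(c("OxyContin", "Dilaudid", "morphine")),
               c("oxycodone", "hydromorphone", "morphine"))
  expect_true(is.na(normalize_drug_name("aspirin")))
  reg <- drug_registry(extra_synonyms = c(Temgesic = "buprenorphine"))
  expect_equal(normalize_drug_name("temgesic", reg), "buprenorphine")
})

test_that("currency conversion is exact at the day rate and linear", {
  rates <- tibble::tibble(date = as.Date("2012-10-01") + 0:9,
                          usd_per_btc = seq(10, 12.25, by = 0.25))
  expect_equal(convert_currency(0, as.Date("2012-10-01"), rates), 0)
  expect_equal(convert_currency(1, as.Date("2012-10-05"), rates), 11.00)
  expect_error(convert_currency(2, as.Date("2013-01-01"), rates),
               "2013-01-01")
  set.seed(42)
  for (i in 1:25) {
    a <- runif(1, 0, 5); b <- runif(1, 0, 5)
    d <- sample(rates$date, 1)
    expect_lt(abs(convert_currency(a + b, d, rates) -
                    convert_currency(a, d, rates) -
                    convert_currency(b, d, rates)), 0.01 + 1e-9)
  }
})

test_that("price_per_mg follows its arithmetic contract", {
  expect_equal(price_per_mg(80, 10, 8), 1.00)
  expect_equal(price_per_mg(3.29, 1, 1), 3.29)
  expect_equal(price_per_mg(60, 10, 15), 0.40)
  expect_error(price_per_mg(10, 0, 5), "quantity")
  expect_error(price_per_mg(10, 1, -5), "strength")
  set.seed(7)
  for (i in 1:25) {
    p <- runif(1, 1, 500); q <- sample(1:20, 1); s <- runif(1, 1, 80)
    base <- price_per_mg(p, q, s)
    expect_equal(price_per_mg(2 * p, q, s), round(2 * p / (q * s), 4))
    expect_gt(price_per_mg(2 * p, q, s), base * 2 - 2e-4)
    expect_lt(price_per_mg(p, 2 * q, s), base / 2 + 2e-4)
    expect_lt(price_per_mg(p, q, 2 * s), base / 2 + 2e-4)
  }
})

test_that("normalized CSV round-trips generated streams unchanged", {
  params <- default_generator_params(seed = 11)
  params$cells <- params$cells[params$cells$drug %in%
                                 c("oxycodone", "tramadol"), ]
  reports <- generate_reports(params)
  path <- tempfile(fileext = ".csv")
  write_reports(reports, path)
  back <- read_normalized_reports(path)
  expect_equal(as.data.frame(back), as.data.frame(reports),
               tolerance = 1e-9)
})
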