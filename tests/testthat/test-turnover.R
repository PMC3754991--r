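test_that("tissue-level model reproduces the reference turnover rates", {
  tab <- turnover_table()
  expect_equal(tab$from, 0:19)
  expect_equal(tab$to, 1:20)
  expect_true(all(tab$mineral > 0))
  expect_lt(max(abs(tab$mineral - ref_mineral)), 0.001)
  expect_lt(max(abs(tab$collagen - ref_collagen)), 0.005)
  expect_lt(max(abs(tab$collagen_qp - ref_qp)), 0.01)
  # discrete collagen rates fall strictly with age
  expect_true(all(diff(tab$collagen) < 0))
})

test_that("collagen outpaces mineral turnover until the late teens", {
  tab <- turnover_table()
  expect_true(all(tab$collagen[1:17] > tab$mineral[1:17]))
  expect_true(all(tab$collagen[19:20] < tab$mineral[19:20]))
})

test_that("zero growth and zero remodeling give zero turnover", {
  k <- turnover_constants()
  k$mass <- rep(100, 21)
  k$rate <- rep(0, 21)
  tab <- mineral_turnover_table(k)
  expect_equal(tab$mineral, rep(0, 20))
  tab2 <- collagen_turnover_table(tab, mineralization_law(k))
  expect_equal(tab2$collagen, rep(0, 20))
})

test_that("mineralization law is a cumulative, saturating schedule", {
  law <- mineralization_law()
  f <- mineralization_fraction(0:30, law)
  expect_gte(f[1], 0.7)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f <= 1))
  expect_equal(mineralization_fraction(500, law), 1, tolerance = 1e-3)
  expect_error(mineralization_fraction(-1, law), "non-negative")
})

test_that("identity mineralization law makes collagen equal mineral rates", {
  k <- turnover_constants()
  law <- structure(list(increments = 1, tail_start = 0, tail_ratio = 0),
                   class = "mineralization_law")
  tab <- collagen_turnover_table(mineral_turnover_table(k), law)
  expect_equal(tab$collagen, tab$mineral, tolerance = 1e-12)
})

test_that("deconvolution round-trip reproduces the mineral rates", {
  k <- turnover_constants()
  law <- mineralization_law(k)
  tab <- collagen_turnover_table(mineral_turnover_table(k), law)
  w <- weanabc:::.law_increments(law, 19)
  reconv <- vapply(1:20, function(x) sum(w[1:x] * tab$collagen[x:1]),
                   numeric(1))
  expect_lt(max(abs(reconv - tab$mineral)), 1e-6)
})

test_that("deconvolution errors name the offending interval", {
  tab <- mineral_turnover_table()
  tab$mineral[5] <- -2  # forces a negative cohort rate in interval 4-5
  expect_error(collagen_turnover_table(tab, mineralization_law()), "4-5")
})

test_that("quartic fit recovers an exact quartic and flags singular designs", {
  co_true <- c(1.5, -0.3, 0.04, -0.002, 4e-5)
  ages <- 1:20
  y <- co_true[1] + co_true[2] * ages + co_true[3] * ages^2 +
    co_true[4] * ages^3 + co_true[5] * ages^4
  tab <- data.frame(from = 0:19, to = ages, collagen = y)
  qp <- fit_qp(tab)
  expect_equal(qp$coefficients, co_true, tolerance = 1e-8)
  bad <- data.frame(from = 0:19, to = rep(1, 20), collagen = y)
  expect_error(fit_qp(bad), "singular")
})

test_that("quartic model fit has small residuals and sane shape", {
  tab <- turnover_table()
  qp <- attr(tab, "qp")
  resid <- tab$collagen - qp_rate(qp, tab$to)
  expect_lt(sqrt(mean(resid^2)), 0.06)
  grid <- seq(0, 20, by = 0.05)
  r <- qp_rate(qp, grid)
  expect_true(all(r > 0))
  expect_true(all(diff(r[grid >= 2]) < 0))  # decreasing on [2, 20]
})

test_that("integrated turnover matches quadrature and validates bounds", {
  qp <- shared_qp()
  num <- stats::integrate(function(x) qp_rate(qp, x), 0.3, 7.7)$value
  expect_equal(integrated_turnover(qp, 0.3, 7.7), num, tolerance = 1e-6)
  expect_identical(integrated_turnover(qp, 2.5, 2.5), 0)
  expect_error(integrated_turnover(qp, 3, 2), ">=")
  expect_error(integrated_turnover(qp, -1, 2), "non-negative")
})
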