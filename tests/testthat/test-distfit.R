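std <- c(15.9, 50, 84.1)
dense_ps <- c(5, 10, 15.9, 30, 50, 70, 84.1, 90, 95)

test_that("characteristic Normal: anchor table and exact quantile recovery", {
  tab <- quantity_table(std, c(8, 10, 12))
  fit <- fit_characteristic_normal(tab)
  expect_identical(fit$params$mean, 10)
  expect_identical(fit$diagnostics$halfwidth_sym, 2)
  expect_identical(fit$diagnostics$halfwidth_upper, 2)
  expect_identical(fit$diagnostics$halfwidth_lower, 2)
  expect_equal(fit$params$sd, 2 / qnorm(0.841), tolerance = 1e-12)

  tabn <- make_quantity_table("normal", list(mean = 3, sd = 0.7), dense_ps)
  fitn <- fit_characteristic_normal(tabn)
  expect_equal(fitn$params$mean, 3, tolerance = 1e-12)
  expect_equal(fitn$params$sd, 0.7, tolerance = 1e-12)
})

test_that("degenerate and decreasing tables are flagged", {
  fit0 <- fit_characteristic_normal(quantity_table(std, c(5, 5, 5)))
  expect_identical(fit0$params$sd, 0)
  expect_true(fit0$diagnostics$degenerate)
  fitd <- fit_characteristic_normal(quantity_table(std, c(12, 10, 8)))
  expect_true(fitd$diagnostics$decreasing)
  expect_gt(fitd$params$sd, 0)
  expect_error(fit_characteristic_normal(quantity_table(c(15.9, 50), c(1, 2))),
               "missing standard percentile.*84.1")
})

test_that("cdf and quantile are mutual inverses on every family", {
  # stay inside the tabulated range so the empirical interpolant is invertible
  p <- seq(0.08, 0.92, by = 0.06)
  fits <- list(
    fit_characteristic_normal(make_quantity_table(
      "normal", list(mean = 10, sd = 2), std)),
    fit_alternative(make_quantity_table(
      "beta", list(shape1 = 2, shape2 = 5, lower = 0, upper = 3), dense_ps),
      "beta", support = c(0, 3)),
    fit_alternative(make_quantity_table(
      "half_cauchy", list(location = 1, scale = 0.4), dense_ps), "half_cauchy"),
    fit_alternative(make_quantity_table(
      "normal", list(mean = 0, sd = 1), dense_ps), "empirical"))
  for (fit in fits) {
    q <- characteristic_quantile(fit, p)
    expect_lt(max(abs(characteristic_cdf(fit, q) - p)), 1e-10)
  }
  nd <- fit_characteristic_normal(quantity_table(std, c(10, 10, 10)))
  expect_identical(characteristic_cdf(nd, c(9, 10, 11)), c(0, 1, 1))  # step CDF
  expect_error(characteristic_quantile(nd, 1.2), "strictly inside")
})

test_that("Normal(10,2) anchors: cdf(10) = 0.5 and quadrature-checked quantile", {
  fit <- fit_characteristic_normal(
    make_quantity_table("normal", list(mean = 10, sd = 2), std))
  expect_identical(characteristic_cdf(fit, 10), 0.5)
  # independent quadrature of the fitted density up to the 0.841 quantile
  q841 <- characteristic_quantile(fit, 0.841)
  dens <- function(x) exp(-(x - 10)^2 / (2 * 2^2)) / sqrt(2 * pi * 4)
  quad <- integrate(dens, -Inf, q841, rel.tol = 1e-12)$value
  expect_equal(quad, 0.841, tolerance = 1e-9)
})

test_that("held-out assessment: zero for same-family, tail failure for beta", {
  tabn <- make_quantity_table("normal", list(mean = 3, sd = 0.7), dense_ps)
  fitn <- fit_characteristic_normal(tabn)
  a <- assess_characteristic_fit(fitn, tabn)
  expect_lt(a$max, 1e-10)
  expect_true(a$pass)

  tabb <- make_quantity_table("beta",
                              list(shape1 = 0.6, shape2 = 3, lower = 0,
                                   upper = 5), dense_ps)
  fitb <- fit_characteristic_normal(tabb)
  ab <- assess_characteristic_fit(fitb, tabb)
  expect_gt(ab$max, 0.05)
  expect_false(ab$pass)
  worst <- ab$per_point$percentile[which.max(ab$per_point$discrepancy)]
  expect_true(worst <= 15 || worst >= 85)  # failure concentrated in the tails

  expect_error(assess_characteristic_fit(fitn, quantity_table(std, 1:3)),
               "no held-out")
  one <- quantity_table(c(std, 70), c(8, 10, 12, characteristic_quantile(fitn, 0.7)))
  fit1 <- fit_characteristic_normal(quantity_table(std, c(8, 10, 12)))
  a1 <- assess_characteristic_fit(fit1,
    quantity_table(c(std, 70), c(8, 10, 12, characteristic_quantile(fit1, 0.7))))
  expect_lt(a1$per_point$discrepancy[1], 1e-12)
})

test_that("alternative families self-recover by quantile matching", {
  th <- make_quantity_table("half_cauchy", list(location = 2, scale = 0.5),
                            dense_ps)
  fh <- fit_alternative(th, "half_cauchy")
  expect_equal(fh$params$location, 2, tolerance = 1e-6)
  expect_equal(fh$params$scale, 0.5, tolerance = 1e-6)

  tb <- make_quantity_table("beta", list(shape1 = 2, shape2 = 5, lower = 0,
                                         upper = 3), dense_ps)
  fb <- fit_alternative(tb, "beta", support = c(0, 3))
  expect_equal(fb$params$shape1, 2, tolerance = 1e-4)
  expect_equal(fb$params$shape2, 5, tolerance = 1e-4)

  fe <- fit_alternative(th, "empirical")
  expect_identical(characteristic_quantile(fe, dense_ps / 100), th$value)

  expect_error(fit_alternative(quantity_table(std, 1:3), "beta"),
               "at least 4")
})

test_that("monotonicity guard flags reversals, escapes, matches a pairwise scan", {
  up <- quantity_table(c(10, 30, 50, 84.1, 90), 1:5)
  r1 <- check_monotonicity(up)
  expect_true(r1$monotone)
  expect_identical(r1$direction, "increasing")

  bad <- quantity_table(c(15.9, 50, 84.1), c(1, 5, 3))
  r2 <- check_monotonicity(bad)
  expect_false(r2$monotone)
  expect_identical(r2$escapes, 50)
  expect_error(fit_characteristic_normal(bad), "non-monotone")
  expect_s3_class(fit_characteristic_normal(bad, allow_nonmonotone = TRUE),
                  "characteristic_distribution")

  set.seed(73)
  ps <- sort(runif(8, 1, 99))
  vals <- sample(1:8)
  tab <- quantity_table(ps, vals)
  rep <- check_monotonicity(tab)
  pairwise_inc <- all(outer(seq_along(vals), seq_along(vals),
                            function(i, j) (i >= j) | (vals[i] >= vals[j])))
  pairwise_dec <- all(outer(seq_along(vals), seq_along(vals),
                            function(i, j) (i >= j) | (vals[i] <= vals[j])))
  expect_identical(rep$monotone, pairwise_inc || pairwise_dec)
})

test_that("quantity table validates its contract", {
  expect_error(quantity_table(c(50, 50), c(1, 2)), "unique")
  expect_error(quantity_table(c(0, 50), c(1, 2)), "strictly inside")
  expect_identical(nrow(make_quantity_table("normal", list(mean = 0, sd = 1),
                                            numeric(0))), 0L)
  tab <- make_quantity_table("normal", list(mean = 0, sd = 1), 84.1)
  expect_equal(tab$value, qnorm(0.841), tolerance = 1e-15)
})
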