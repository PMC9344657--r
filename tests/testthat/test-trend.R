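# average derivative of the fitted smooth over an interior grid
trend_slope <- function(fit, lo = 3, hi = 8) {
  gx <- seq(lo, hi, length.out = 100)
  v <- evaluate_trend(fit, NULL, gx)
  unname(coef(lm(v ~ gx))[2])
}

test_that("spline recovers a linear accumulation slope and a flat response", {
  agg <- linear_trend_agg(a = 1, b = 0.8, sd = 0.1, seed = 1)
  fit <- fit_trend(agg)
  expect_s3_class(fit, "trend_fit")
  expect_equal(trend_slope(fit), 0.8, tolerance = 0.07)

  flat <- linear_trend_agg(a = log(5), b = 0, sd = 0, seed = 2)
  flat$n <- 5
  ffit <- fit_trend(flat)
  gx <- seq(3, 8, length.out = 50)
  fr <- evaluate_trend(ffit, NULL, gx) - ffit$kappa
  expect_lt(max(abs(fr)), 0.05)
  expect_equal(ffit$kappa, log(5), tolerance = 0.01)
})

test_that("a spiked genus effect is detected, estimated, and BH-retained", {
  offs <- c(1, rep(0, 39))
  agg <- linear_trend_agg(a = 1, b = 0.8, sd = 0.1, seed = 5, genus_offsets = offs)
  fit <- fit_trend(agg)
  ge <- tidy(fit)
  g1 <- ge[ge$group == "G01", ]
  expect_true(g1$retained)
  expect_equal(g1$estimate, 1.0, tolerance = 0.15)
  # evaluation adds exactly the retained effect
  v0 <- evaluate_trend(fit, NULL, 5)
  v1 <- evaluate_trend(fit, "G01", 5)
  expect_equal(v1 - v0, g1$estimate)
})

test_that("null genus effects are rarely retained across seeded replicates", {
  retained_any <- vapply(1:12, function(s) {
    agg <- linear_trend_agg(a = 1, b = 0.8, sd = 0.1, n_genus = 25,
                            n_sample = 12, seed = 100 + s)
    any(tidy(fit_trend(agg))$retained)
  }, logical(1))
  # BH at 0.05 over all-null effects: retention should be the exception
  expect_lte(mean(retained_any), 0.25)
})

test_that("evaluation rules: zeroed effects, unseen genera, NaN rejection", {
  agg <- linear_trend_agg(seed = 8)
  fit <- fit_trend(agg)
  expect_false(any(tidy(fit)$retained))
  # non-retained genera evaluate identically to the baseline
  expect_equal(evaluate_trend(fit, "G03", 5), evaluate_trend(fit, NULL, 5))
  expect_equal(evaluate_trend(fit, "G03", 5), evaluate_trend(fit, "G07", 5))
  expect_equal(evaluate_trend(fit, "NotAGenus", 5), evaluate_trend(fit, NULL, 5))
  expect_error(evaluate_trend(fit, NULL, NaN), "finite")
})

test_that("loess trend reproduces an exact linear curve and clamps outside the range", {
  agg <- exact_linear_agg(a = 2, b = 0.5)
  fit <- fit_trend(agg, method = "loess")
  gx <- seq(3, 8, length.out = 25)
  expect_lt(max(abs(evaluate_trend(fit, NULL, gx) - (2 + 0.5 * gx))), 0.02)
  # clamping below/above observed range
  expect_equal(evaluate_trend(fit, NULL, -5), evaluate_trend(fit, NULL, min(log(agg$y))))
  expect_equal(evaluate_trend(fit, NULL, 50), evaluate_trend(fit, NULL, max(log(agg$y))))
  # genus effects are absent in the loess strategy
  expect_equal(nrow(tidy(fit)), 0)
})

test_that("spline and loess agree on a large null simulation", {
  agg <- linear_trend_agg(a = 1, b = 0.6, sd = 0.15, n_genus = 40,
                          n_sample = 25, seed = 21)
  fs <- fit_trend(agg, method = "spline")
  fl <- fit_trend(agg, method = "loess")
  gx <- seq(quantile(log(agg$y), 0.1), quantile(log(agg$y), 0.9), length.out = 50)
  rms <- sqrt(mean((evaluate_trend(fs, NULL, gx) - evaluate_trend(fl, NULL, gx))^2))
  expect_lt(rms, 0.1)
})

test_that("roughness penalty drives the fit to the least-squares line as lambda grows", {
  agg <- linear_trend_agg(a = 0.5, b = 0.7, sd = 0.2, n_genus = 15,
                          n_sample = 15, seed = 33)
  fit <- fit_trend(agg)
  path <- fit$gcv_path
  # curvature (edf) decreases monotonically in lambda
  expect_true(all(diff(path$edf) < 1e-8))
  # refit with lambda forced huge: slope matches OLS of z on log y + genus
  d <- dplyr::filter(tibble::as_tibble(agg), n >= 1)
  ols <- coef(lm(log(n) ~ log(y), data = d))[2]
  big <- richtrend:::spline_refit(
    within_lambda <- local({f <- fit; f$lambda <- fit$lambda * 1e9; f}), agg)
  expect_equal(trend_slope(big), unname(ols), tolerance = 1e-3)
})

test_that("trend fits are deterministic and survive JSON round-trip", {
  agg <- linear_trend_agg(seed = 13)
  f1 <- fit_trend(agg)
  f2 <- fit_trend(agg)
  expect_identical(f1$b_spline, f2$b_spline)
  expect_identical(tidy(f1), tidy(f2))

  p <- withr::local_tempfile(fileext = ".json")
  trend_to_json(f1, p)
  fr <- trend_from_json(p)
  gx <- seq(2.5, 8.5, length.out = 40)
  expect_equal(evaluate_trend(fr, "G01", gx), evaluate_trend(f1, "G01", gx),
               tolerance = 1e-12)
  # determinism of serialization bytes
  p2 <- withr::local_tempfile(fileext = ".json")
  trend_to_json(f2, p2)
  expect_identical(readLines(p), readLines(p2))
})

test_that("degenerate inputs are rejected", {
  tiny <- linear_trend_agg(n_genus = 2, n_sample = 3, seed = 3)
  expect_error(fit_trend(tiny[1:6, ]), "at least 10")
  same_y <- linear_trend_agg(n_genus = 4, n_sample = 5, seed = 3)
  same_y$y <- 100
  expect_error(fit_trend(same_y), "distinct")
})
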