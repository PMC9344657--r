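fit_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sv <- small_survey()
      agg <- suppressMessages(survey_aggregate(sv))
      cache <<- list(sv = sv, agg = agg, X = survey_design(sv),
                     trend = fit_trend(agg))
    }
    cache
  }
})

test_that("Poisson IRLS matches a brute-force likelihood maximizer on a small instance", {
  set.seed(4)
  n <- 20
  X <- cbind(1, x1 = runif(n, -1, 1), x2 = rbinom(n, 1, 0.5))
  beta0 <- c(1.2, 0.6, -0.4)
  y <- rpois(n, exp(drop(X %*% beta0)))
  fit <- richtrend:::fit_count_glm(y, X, family = "poisson")
  nll <- function(b) -sum(y * drop(X %*% b) - exp(drop(X %*% b)))
  opt <- optim(c(0, 0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(fit$estimate), opt$par, tolerance = 1e-6)
})

test_that("collection over all genera reproduces the sample-wide model", {
  fs <- fit_small()
  sw <- samplewide_differential_richness(fs$agg, fs$trend, fs$X)
  co <- collection_differential_richness(fs$agg, fs$trend, fs$X,
                                         genus_set = unique(fs$agg$group))
  expect_equal(co$terms$estimate, sw$terms$estimate, tolerance = 1e-6)
  expect_equal(co$terms$se, sw$terms$se, tolerance = 1e-6)
})

test_that("singleton collection's trend covariate equals the genus trend value", {
  fs <- fit_small()
  g <- unique(fs$agg$group)[1]
  tc <- richtrend:::samplewise_trend_covariate(fs$agg, fs$trend, genus_set = g)
  d <- dplyr::filter(fs$agg, group == g, y > 0)
  ft <- evaluate_trend(fs$trend, g, log(d$y))
  expect_equal(tc$T[match(d$sample, tc$sample)], ft)
})

test_that("disjoint collections partition the sample-wide response", {
  fs <- fit_small()
  gs <- unique(fs$agg$group)
  aggd <- dplyr::as_tibble(fs$agg)
  s1 <- gs[seq(1, length(gs), 2)]; s2 <- setdiff(gs, s1)
  n1 <- with(dplyr::filter(aggd, group %in% s1), tapply(n, sample, sum))
  n2 <- with(dplyr::filter(aggd, group %in% s2), tapply(n, sample, sum))
  np <- with(aggd, tapply(n_plus, sample, unique))
  expect_equal(n1[names(np)] + n2[names(np)], np)
})

test_that("genus model recovers nu = 1 on data generated from its own link", {
  # a trend with real spread, then responses drawn exactly from the link
  agg <- linear_trend_agg(a = 1, b = 0.8, sd = 0.1, n_genus = 30,
                          n_sample = 40, seed = 71)
  trend <- fit_trend(agg)
  g <- "G01"
  d <- dplyr::filter(dplyr::as_tibble(agg), group == g)
  X <- design_matrix(tibble::tibble(sample_id = d$sample,
                                    group = rep(c("A", "B"), length.out = nrow(d))))
  ft <- evaluate_trend(trend, g, log(d$y))
  nus <- vapply(1:20, function(s) {
    set.seed(900 + s)
    d$n <- rpois(nrow(d), exp(0.3 + 0.2 * X[, 2] + 1.0 * ft))
    dd <- d[d$n > 0, ]
    fit <- genus_differential_richness(dd, trend, X[dd$sample, ], g,
                                       offset_trend = FALSE)
    fit$nu
  }, numeric(1))
  expect_equal(mean(nus), 1, tolerance = 0.1)

  # offset mode pins nu at exactly 1 and barely moves the group contrast
  set.seed(901)
  d$n <- rpois(nrow(d), exp(0.3 + 0.2 * X[, 2] + 1.0 * ft))
  dd <- d[d$n > 0, ]
  free <- genus_differential_richness(dd, trend, X[dd$sample, ], g,
                                      offset_trend = FALSE)
  pinned <- genus_differential_richness(dd, trend, X[dd$sample, ], g)
  expect_equal(pinned$nu, 1)
  expect_lt(abs(free$terms$estimate[free$terms$term == "groupB"] -
                pinned$terms$estimate[pinned$terms$term == "groupB"]), 0.05)
})

test_that("weighted meta-regression closed forms", {
  set.seed(12)
  n <- 16
  X <- design_matrix(two_group_design(8))
  est <- exp(rnorm(n, 2, 0.3))
  # equal SEs -> equals OLS on log estimates
  w <- weighted_meta_regression(est, rep(0.5, n) * est, X)  # constant log-scale SE
  ols <- coef(lm(log(est) ~ X[, 2]))
  expect_equal(unname(w$terms$estimate), unname(ols), tolerance = 1e-10)
  # intercept-only: inverse-variance weighted mean
  ses <- runif(n, 0.1, 1)
  X0 <- matrix(1, n, 1, dimnames = list(rownames(X), "(Intercept)"))
  w0 <- weighted_meta_regression(est, ses, X0, log_transform = FALSE)
  expect_equal(w0$terms$estimate, sum(est / ses^2) / sum(1 / ses^2))
  expect_equal(w0$terms$se, sqrt(1 / sum(1 / ses^2)))
  # zero/undefined cells dropped with a count
  est2 <- est; est2[1:3] <- 0
  w2 <- weighted_meta_regression(est2, ses, X)
  expect_equal(w2$dropped, 3)
  expect_error(weighted_meta_regression(rep(0, n), ses, X), "too few")
})

test_that("sample-wide NB dispersion is recovered in the right range", {
  # response generated from the sample-wide link with NB dispersion 0.01
  fs <- fit_small()
  tc <- richtrend:::samplewise_trend_covariate(fs$agg, fs$trend)
  ok <- is.finite(tc$T)
  Xs <- fs$X[tc$sample[ok], , drop = FALSE]
  disp <- vapply(1:25, function(s) {
    set.seed(500 + s)
    mu <- exp(0.5 + 0.2 * Xs[, 2] + 1.0 * tc$T[ok])
    ynb <- MASS::rnegbin(length(mu), mu = mu, theta = 1 / 0.01)
    f <- richtrend:::fit_count_glm(ynb, cbind(Xs, trend = tc$T[ok]), family = "nb")
    f$dispersion
  }, numeric(1))
  expect_gte(mean(disp >= 1e-3 & disp <= 1e-1), 0.6)
})

test_that("separation and rank problems surface as errors or flags", {
  fs <- fit_small()
  # design constant on the usable samples
  Xbad <- fs$X
  Xbad[, 2] <- 0
  expect_error(samplewide_differential_richness(fs$agg, fs$trend, Xbad),
               "constant|rank")
  # genus detected in too few samples
  ag <- dplyr::as_tibble(fs$agg)
  rare <- ag[ag$group == ag$group[1], ]
  expect_error(genus_differential_richness(
    dplyr::mutate(ag, y = ifelse(group == "Genus001" & sample != "s001", 0, y)),
    fs$trend, fs$X, "Genus001"), "at least")
})

test_that("bootstrap-t intervals are seed-deterministic and error on degenerate designs", {
  fs <- fit_small()
  b1 <- suppressMessages(bootstrap_t_ci(fs$agg, fs$X, trend = fs$trend, B = 199, seed = 42))
  b2 <- suppressMessages(bootstrap_t_ci(fs$agg, fs$X, trend = fs$trend, B = 199, seed = 42))
  expect_identical(b1$conf.low, b2$conf.low)
  expect_identical(b1$conf.high, b2$conf.high)
  expect_true(all(b1$conf.low < b1$estimate & b1$estimate < b1$conf.high))
  # one sample per design cell -> stratified resampling impossible
  X1 <- fs$X[c(1, 13), , drop = FALSE]
  agg1 <- dplyr::filter(dplyr::as_tibble(fs$agg), sample %in% rownames(X1))
  expect_error(bootstrap_t_ci(agg1, X1, trend = fs$trend, B = 199, seed = 1),
               "2 samples per design cell")
})

test_that("genus_differential maps over genera with BH within coefficient family", {
  fs <- fit_small()
  res <- genus_differential(fs$agg, fs$trend, fs$X)
  grpB <- dplyr::filter(res, term == "groupB")
  expect_gt(nrow(grpB), 10)
  expect_equal(grpB$p.adjust, unname(p.adjust(grpB$p.value, "BH")))
  expect_true(all(grpB$conf.low <= grpB$estimate & grpB$estimate <= grpB$conf.high))
})

test_that("sample-wide inference resists asymmetric abundance shifts that fool the Chao1 route", {
  res <- t(vapply(1:20, function(s) {
    sv <- suppressWarnings(null_richness_confounding_scenario(
      n_per_group = 15, G = 30, depth = 2e4, depth_sd_log = 0.5,
      lfc = "asymmetric", seed = 900 + s))
    agg <- suppressMessages(survey_aggregate(sv))
    X <- survey_design(sv)
    tr <- fit_trend(agg)
    zp <- samplewide_differential_richness(agg, tr, X)$terms
    zp <- zp$statistic[zp$term == "groupB"]
    st <- samplewide_richness_table(sv$counts, "chao1")
    samples <- rownames(X)
    zc <- weighted_meta_regression(st$estimate[match(samples, st$sample)],
                                   st$se[match(samples, st$sample)], X)$terms$statistic[2]
    c(prok = abs(zp) > 1.96, chao = abs(zc) > 1.96)
  }, logical(2)))
  # all genera more abundant in group B, no richness change: the naive
  # asymptotic route is biased into rejecting; the trend-controlled one not
  expect_lte(mean(res[, "prok"]), 0.10)
  expect_gte(mean(res[, "chao"]), 0.30)
})

test_that("sample-wide type-I error is near nominal under symmetric shifts and depth imbalance", {
  z <- vapply(1:40, function(s) {
    sv <- suppressWarnings(null_richness_confounding_scenario(
      n_per_group = 15, G = 30, depth = 2e4, depth_sd_log = 0.5,
      lfc = "symmetric", seed = 100 + s))
    agg <- suppressMessages(survey_aggregate(sv))
    X <- survey_design(sv)
    tr <- fit_trend(agg)
    f <- samplewide_differential_richness(agg, tr, X)
    f$terms$statistic[f$terms$term == "groupB"]
  }, numeric(1))
  expect_lte(mean(abs(z) > 1.96), 0.10)
})
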