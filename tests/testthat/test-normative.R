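test_that("age-trend fits recover known generators", {
  # constant values: order 0, sd ~ 0
  tr <- fit_age_trend(seq(10, 70, by = 5), rep(3.2, 13))
  expect_equal(tr$order, 0)
  expect_equal(tr$coefficients[1], 3.2)
  expect_lt(tr$population_sd, 1e-10)

  # linear generator: slope recovered within its standard error
  set.seed(10)
  ages <- runif(300, 7, 79)
  y <- 2 + 0.1 * ages + rnorm(300)
  tr <- fit_age_trend(ages, y)
  expect_equal(tr$order, 1)
  expect_equal(tr$coefficients[2], 0.1, tolerance = 0.2)
  expect_lt(abs(tr$coefficients[2] - 0.1), 0.02)
  expect_equal(tr$population_sd, 1, tolerance = 0.15)
  expect_equal(unname(predict(tr, 40)), 2 + 0.1 * 40, tolerance = 0.05)

  # quadratic generator: order 2 selected in >= 95% of fits
  set.seed(11)
  n_sel <- 0
  for (b in 1:100) {
    a <- runif(120, 7, 79)
    y <- 1 + 0.05 * a + 0.002 * a^2 + rnorm(120)
    if (fit_age_trend(a, y)$order == 2) n_sel <- n_sel + 1
  }
  expect_gte(n_sel, 95)

  expect_error(fit_age_trend(1, 1), "two observations")
})

test_that("measurement error estimator matches its closed form", {
  expect_equal(estimate_measurement_error(c(1, 2, 3), c(1, 2, 3)), 0)
  # pairs differing by exactly +-d
  d <- 0.8
  expect_equal(estimate_measurement_error(c(1, 2, 3, 4) + d / 2,
                                          c(1, 2, 3, 4) - d / 2),
               d / sqrt(2))
  expect_warning(e0 <- estimate_measurement_error(numeric(0), numeric(0)),
                 "no repeat pairs")
  expect_equal(e0, 0)
  # recovery of a known measurement sigma from 30 pairs
  set.seed(12)
  sm <- 0.5
  x1 <- rnorm(30, sd = 2) + rnorm(30, sd = sm)
  x2 <- (x1 - rnorm(30, sd = sm)) + rnorm(30, sd = sm) # shared subject part
  bio <- rnorm(30, sd = 2)
  x1 <- bio + rnorm(30, sd = sm)
  x2 <- bio + rnorm(30, sd = sm)
  est <- estimate_measurement_error(x1, x2)
  expect_lt(abs(est - sm) / sm, 0.25)
})

test_that("artifact odds follow the smoothed outlier fraction", {
  set.seed(13)
  clean <- rnorm(322)
  res <- estimate_artifact_odds(clean)
  expect_lt(res$artifact_probability, 0.02)
  expect_gt(res$odds_valid, 50)

  dirty <- c(rnorm(290), rnorm(32, mean = 12))
  res <- estimate_artifact_odds(dirty)
  expect_equal(res$artifact_probability, 0.1, tolerance = 0.5)
  expect_gt(res$artifact_probability, 0.05)
  expect_equal(res$odds_valid, (1 - res$artifact_probability) /
                 res$artifact_probability)
  # odds always positive and finite, even for degenerate input
  for (v in list(rep(1, 50), c(rep(0, 49), 5), rnorm(20))) {
    r <- estimate_artifact_odds(v)
    expect_true(is.finite(r$odds_valid) && r$odds_valid > 0)
  }
})

test_that("abnormality p-values follow the two-sided Gaussian tail", {
  tr <- fit_age_trend(20:60, rep(5, 41))
  r0 <- abnormality_p(5, 35, tr, population_sd = 1)
  expect_equal(r0$p, 1)
  expect_equal(r0$sign, 0)
  # z = 2.5758 corresponds to p = 0.01
  r <- abnormality_p(5 + 2.575829 * sqrt(1 + 0.25), 35, tr,
                     population_sd = 1, measurement_sd = 0.5)
  expect_equal(r$p, 0.01, tolerance = 1e-4)
  expect_equal(r$sign, 1)
  # monotone in |z|, invariant under sign flip
  p_hi <- abnormality_p(8, 35, tr, 1)$p
  p_lo <- abnormality_p(6, 35, tr, 1)$p
  expect_lt(p_hi, p_lo)
  expect_equal(abnormality_p(3, 35, tr, 1)$p, abnormality_p(7, 35, tr, 1)$p)
  expect_equal(abnormality_p(3, 35, tr, 1)$sign, -1)
})

test_that("BH flags match a brute-force step-up oracle", {
  bh_oracle <- function(p, q) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    k <- which(ps <= q * seq_len(m) / m)
    flags <- rep(FALSE, m)
    if (length(k)) flags[o[seq_len(max(k))]] <- TRUE
    flags
  }
  expect_true(all(fdr_flag(rep(0.005, 2976), q = 0.01)))
  expect_false(any(fdr_flag(0.02, q = 0.01)))
  expect_identical(fdr_flag(numeric(0)), logical(0))
  set.seed(14)
  for (b in 1:1000) {
    m <- sample(1:200, 1)
    p <- runif(m)^sample(c(1, 3), 1)   # null and signal-rich mixtures
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_identical(fdr_flag(p, q), bh_oracle(p, q))
  }
})

test_that("FDR flags are a subset of uncorrected flags at q <= alpha", {
  set.seed(15)
  p <- c(runif(2900), runif(76, 0, 0.002))
  f <- fdr_flag(p, q = 0.01)
  expect_true(all(p[f] < 0.01))
})

test_that("null p-values from the fitted model are uniform", {
  m <- mn_model()
  nulls <- generate_patients(mn_world(), "MTLE-HS-left", n_patients = 5,
                             seed = 201, effect_scale = 0)
  sc <- score_cohort(m, nulls$cohort, profiles = FALSE)
  set.seed(16)
  p <- sample(as.numeric(sc$normalized$p), 2000)
  ks <- stats::ks.test(p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("a 4-width deviation in a feature is flagged uncorrected", {
  m <- mn_model()
  scan <- mn_null_scan()
  set.seed(17)
  feats <- sample(m$blocks$normalized$features, 50)
  flagged <- 0
  for (f in feats) {
    j <- match(f, m$blocks$raw$features)
    s <- scan
    # place the raw value exactly 4 total widths above the raw-trend value
    pred <- predict(m, s$age, features = f, block = "raw",
                    meta = s[, c("sex", "scanner_sequence")])
    s[[f]] <- pred[1] + 4 * m$blocks$raw$sigma[j]
    prof <- score_scan(m, s)
    row <- prof[prof$feature == f & prof$variant == "raw", ]
    if (row$flag != "none" && row$sign > 0) flagged <- flagged + 1
  }
  expect_gte(flagged, 50 * 0.99 - 1e-9)
})

test_that("scoring respects the extrapolation annotation and variants", {
  m <- mn_model()
  scan <- mn_null_scan()
  prof <- score_scan(m, scan)
  expect_s3_class(prof, "abnormality_profile")
  expect_equal(nrow(prof), 2 * 2976)
  expect_true(all(prof$p > 0 & prof$p <= 1))
  expect_false(attr(prof, "extrapolated"))
  scan$age <- m$age_range[2] + 5
  prof2 <- score_scan(m, scan)
  expect_true(attr(prof2, "extrapolated"))
})

test_that("model methods are coherent", {
  m <- mn_model()
  expect_output(print(m), "Normative morphometry model")
  s <- summary(m)
  expect_s3_class(s, "summary.normative_model")
  cf <- coef(m, "normalized")
  expect_equal(ncol(cf), 1989)
  pr <- predict(m, c(20, 40, 60), features = "Hippocampus|volume|left",
                block = "raw")
  expect_equal(dim(pr), c(3L, 1L))
  expect_true(all(pr > 2 & pr < 7))   # plausible hippocampal volumes (ml)
  sim <- simulate(m, nsim = 5, seed = 1, age = 40)
  expect_equal(dim(sim), c(5L, 1989L))
})
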