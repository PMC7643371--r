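test_that("reproducibility error reproduces hand-worked sessions", {
  expect_equal(reproducibility_error(c(2.1, 2.1, 2.1), c(1, 1, 1)), 0)
  expect_equal(reproducibility_error(c(2.0, 2.2), c(1, 1)),
               100 * 0.5 * (0.1 / 2.1 + 0.1 / 2.1))
  expect_equal(reproducibility_error(c(2.0, 2.2, 3.0, 3.0), c(1, 1, 2, 2)),
               (100 * 0.5 * (0.1 / 2.1 + 0.1 / 2.1)) / 2)
  # scale invariance
  expect_equal(reproducibility_error(7 * c(2.0, 2.2, 3.0, 3.0), c(1, 1, 2, 2)),
               reproducibility_error(c(2.0, 2.2, 3.0, 3.0), c(1, 1, 2, 2)))
  # zero iff all within-session measures equal
  expect_gt(reproducibility_error(c(2, 2.0001), c(1, 1)), 0)

  expect_warning(e <- reproducibility_error(c(2, 2.2, 5), c(1, 1, 2)),
                 "fewer than 2")
  expect_equal(e, reproducibility_error(c(2, 2.2), c(1, 1)))
  expect_error(reproducibility_error(c(-1, 1), c(1, 1)), "mean of zero")
})

test_that("Cohen's d matches hand computation and its invariances", {
  d <- cohens_d(c(1, 2, 3), c(2, 3, 4))
  expect_equal(d$d, -1)
  expect_equal(cohens_d(c(2, 3, 4), c(1, 2, 3))$d, 1)  # antisymmetry
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3))$d, 0)

  # invariant under common shift and positive scaling
  a <- rnorm(20, 2.5, 0.1); b <- rnorm(20, 2.3, 0.1)
  d0 <- cohens_d(a, b)$d
  expect_equal(cohens_d(a + 5, b + 5)$d, d0)
  expect_equal(cohens_d(3 * a, 3 * b)$d, d0)

  expect_error(cohens_d(c(2, 2), c(3, 3)), "pooled standard deviation")
  expect_error(cohens_d(1, c(1, 2)), "at least 2")

  # CI formula: d +/- 1.96 sqrt((na+nb)/(na nb) + d^2/(2(na+nb-2)))
  se <- sqrt(6 / 9 + 1 / 8)
  expect_equal(d$ci, c(-1 - stats::qnorm(0.975) * se, -1 + stats::qnorm(0.975) * se))
})

test_that("covariate model recovers an injected age slope and correction removes it", {
  cs <- cohort_spec(n_hc = 500, age_slope = -0.005, etiv_effect = 0,
                    sigma_between = 0, sigma_noise = 0.01, seed = 3)
  sim <- simulate_cohort(cs)
  df <- merge(sim$thickness, sim$cohort, by = c("subject", "session", "scan"))
  df$thickness <- df$mean_thickness_mm
  m <- fit_covariate_model(df)
  expect_lt(abs(m$age_slope_mm_per_year - (-0.005)), 0.001)

  corr <- apply_correction(m, df)
  expect_lt(abs(stats::cor(corr$thickness_corrected, corr$age)), 0.05)
  # intercept retained: corrected HC mean equals observed HC mean
  expect_equal(mean(corr$thickness_corrected), mean(df$thickness), tolerance = 1e-10)
})

test_that("null covariates give near-zero coefficients; degenerate designs error", {
  set.seed(9)
  df <- data.frame(thickness = rnorm(300, 2.5, 0.1),
                   etiv = rnorm(300, 1.5e6, 1e5),
                   age = runif(300, 50, 80), group = "HC")
  m <- fit_covariate_model(df)
  cf <- summary(m$fit)$coefficients
  expect_lt(abs(cf["etiv", "Estimate"]), 2 * cf["etiv", "Std. Error"])
  expect_lt(abs(cf["age", "Estimate"]), 2 * cf["age", "Std. Error"])

  expect_error(fit_covariate_model(df[1:2, ]), "at least 3")
  dfc <- df; dfc$age <- 70
  expect_error(fit_covariate_model(dfc), "rank-deficient")

  # zero-coefficient model: correction is the identity
  m0 <- m
  m0$fit$coefficients[c("etiv", "age")] <- 0
  corr0 <- apply_correction(m0, df)
  expect_equal(corr0$thickness_corrected, df$thickness)

  dfm <- df; dfm$etiv[1] <- NA
  expect_warning(corrm <- apply_correction(m, dfm), "missing covariates")
  expect_equal(nrow(corrm), 299)
})

test_that("longitudinal atrophy rates: hand slope, inclusion rules, recovery", {
  two <- data.frame(subject = "s1", time_years = c(70, 72),
                    value = c(2.50, 2.46), group = "HC")
  r <- longitudinal_atrophy_rates(two)
  expect_equal(r$rates$rate_mm_per_year, -0.02)
  # endpoint-difference variant agrees for two timepoints
  r2 <- longitudinal_atrophy_rates(two, method = "first_last")
  expect_equal(r2$rates$rate_mm_per_year, -0.02)

  mixed <- rbind(
    data.frame(subject = "chg", time_years = c(0, 2), value = c(2.5, 2.4),
               group = c("HC", "dementia")),
    data.frame(subject = "short", time_years = c(0, 0.5), value = c(2.5, 2.49),
               group = "HC"),
    two)
  rm <- longitudinal_atrophy_rates(mixed)
  expect_equal(rm$rates$subject, "s1")
  expect_setequal(rm$excluded$subject, c("chg", "short"))
  expect_match(rm$excluded$reason[rm$excluded$subject == "chg"], "sub-cohort")

  cl <- cohort_spec(n_hc = 50, age_slope = -0.02, sigma_between = 0.1,
                    sigma_noise = 0.01, n_visits = 3, seed = 11)
  sim <- simulate_cohort(cl)
  df <- merge(sim$thickness, sim$cohort, by = c("subject", "session", "scan"))
  df$value <- df$mean_thickness_mm
  out <- longitudinal_atrophy_rates(df)
  expect_lt(abs(out$summary$mean_rate - (-0.02)), 0.005)
  expect_equal(out$summary$n, 50)
})

test_that("rate comparison is paired and handles zero-variance differences", {
  set.seed(21)
  base <- rnorm(12, -0.02, 0.05)  # large between-subject spread
  ra <- data.frame(subject = sprintf("s%d", 1:12), rate_mm_per_year = base)
  rb <- ra
  rb$rate_mm_per_year <- base + 0.01 + rnorm(12, 0, 0.001)

  same <- compare_rates_paired(ra, ra)
  expect_equal(same$mean_difference, 0)
  expect_equal(same$p_value, 1)

  paired <- compare_rates_paired(ra, rb)
  expect_lt(paired$p_value, 0.05)
  # the unpaired test on the same data is not significant: the paired
  # variant is really what is computed
  unpaired <- stats::t.test(ra$rate_mm_per_year, rb$rate_mm_per_year)$p.value
  expect_gt(unpaired, 0.05)

  expect_error(compare_rates_paired(ra[1, ], rb[1, ]), "at least 2")
})

test_that("cross-sectional age slope: recovery and shift invariance", {
  set.seed(33)
  df <- data.frame(age = runif(2000, 50, 90))
  df$value <- 2.5 - 0.007 * df$age + rnorm(2000, 0, 0.1)
  expect_lt(abs(cross_sectional_age_slope(df) - (-0.007)), 0.002)
  df2 <- df; df2$value <- df$value + 10
  expect_equal(cross_sectional_age_slope(df2), cross_sectional_age_slope(df))

  flat <- data.frame(age = runif(500, 50, 90), value = 2.5)
  expect_lt(abs(cross_sectional_age_slope(flat)), 1e-10)
  expect_error(cross_sectional_age_slope(df[1:2, ]), "at least 3")
})

test_that("method agreement: self-comparison, known shift, sign", {
  set.seed(44)
  a <- data.frame(scan = sprintf("s%d", 1:500), region = "global_mean",
                  value = rnorm(500, 2.5, 0.2))
  self <- method_agreement(a, a)
  expect_equal(self$r, 1)
  expect_equal(self$bias, 0)
  expect_equal(self$lower_limit, 0)
  expect_equal(self$upper_limit, 0)

  b <- a; b$value <- a$value + rnorm(500, 0.1, 0.05)
  ag <- method_agreement(a, b)
  expect_lt(abs(ag$bias - (-0.1)), 0.01)
  expect_lt(abs((ag$upper_limit - ag$lower_limit) / 2 - 1.96 * 0.05), 0.02)

  anti <- a; anti$value <- -a$value
  expect_lt(method_agreement(a, anti)$r, -0.99)

  expect_error(method_agreement(a[1:2, ], a[1:2, ]), "fewer than 3")
})

test_that("CDR maps onto the three sub-cohorts", {
  expect_equal(cdr_group(c(0, 0.5, 1, 2, 3)),
               c("HC", "questionable", "dementia", "dementia", "dementia"))
})
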