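test_that("group comparison contracts: rank test, t-test, chi-square", {
  # identical samples: no evidence of a difference
  x <- c(1.2, 3.4, 5.6, 7.8, 9.1)
  expect_gt(compare_groups(x, x)$p_value, 0.99)
  # exact two-sided rank test on fully separated tiny arms: 2/20
  r <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)
  expect_equal(r$p_value, exact_rank_p_twosided(c(1, 2, 3), c(4, 5, 6)))
  # balanced 2x2 table: statistic 0, p 1
  d <- rep(c("m", "f"), each = 50)
  r2 <- compare_groups(d, d, var_kind = "categorical")
  expect_equal(unname(r2$statistic), 0)
  expect_equal(r2$p_value, 1)
  # symmetric route reports means and uses the t-test
  r3 <- compare_groups(rnorm(20, 5), rnorm(20, 5),
                       var_kind = "continuous_symmetric")
  expect_equal(r3$test, "t-test")
  expect_true(all(c("mean", "sd") %in% names(r3$dead)))
})

test_that("an empty arm yields a flagged missing comparison", {
  out <- compare_groups(numeric(0), c(1, 2, 3))
  expect_true(out$flagged)
  expect_true(is.na(out$p_value))
})

test_that("unadjusted OR is near 1 under independence and recovers a true effect", {
  set.seed(31)
  x <- rnorm(5000, 20, 5)
  y <- rbinom(5000, 1, 0.3)
  r <- unadjusted_or(x, y)
  expect_false(r$separation)
  expect_lt(r$ci_low, 1)
  expect_gt(r$ci_high, 1)
  expect_equal(r$or, 1, tolerance = 0.05)

  # parameter recovery: true OR 1.02 per unit
  set.seed(32)
  x2 <- rnorm(20000, 20, 8)
  p <- plogis(-1 + log(1.02) * x2)
  y2 <- rbinom(20000, 1, p)
  r2 <- unadjusted_or(x2, y2)
  # estimate within two CI half-widths (~4 SE) of the truth
  half_width <- log(r2$ci_high) - log(r2$or)
  expect_lt(abs(log(r2$or) - log(1.02)), 2 * half_width)
})

test_that("complete separation is flagged without an estimate", {
  x <- c(1, 2, 3, 4, 10, 11, 12, 13)
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  r <- unadjusted_or(x, y)
  expect_true(r$separation)
  expect_true(is.na(r$or))
})

test_that("exchangeable arms never produce a safe limit", {
  x <- c(2.2, 3.1, 4.5, 5.0, 6.7)
  r <- safe_upper_limit(x, x)
  expect_true(is.na(r$limit))
  expect_gt(r$p_value, 0.5)
})

test_that("fully separated tiny arms give the enumerated p and the interpolated percentile", {
  surv <- c(1, 2, 3, 4)
  nons <- c(5, 6, 7, 8)
  r <- safe_upper_limit(surv, nons, alpha = 0.05)
  expect_equal(r$p_value, 1 / 70)
  expect_equal(r$p_value, exact_rank_p_greater(nons, surv))
  # survivors' 95th percentile, linear interpolation: 3.85
  expect_equal(r$limit, 3.85)
  expect_equal(r$n_survivors, 4)
  expect_equal(r$n_nonsurvivors, 4)
})

test_that("exact one-sided p-values match brute-force enumeration for arms <= 8", {
  set.seed(41)
  for (nx in c(2, 4, 6, 8)) {
    for (ny in c(3, 5, 8)) {
      x <- round(rnorm(nx, 1, 2), 6)
      y <- round(rnorm(ny, 0, 2), 6)
      r <- safe_upper_limit(y, x, alpha = 0.049)
      expect_equal(r$p_value, exact_rank_p_greater(x, y), tolerance = 1e-12)
    }
  }
})

test_that("a clear shift yields the survivors' empirical 95th percentile", {
  set.seed(51)
  surv <- rnorm(500, 0, 1)
  nons <- rnorm(500, 1, 1)
  r <- safe_upper_limit(surv, nons)
  expect_lt(r$p_value, 1e-10)
  expect_equal(r$limit, unname(quantile(surv, 0.95)))
  expect_gte(r$limit, min(surv))
  expect_lte(r$limit, max(surv))
})

test_that("the limit is order-based: monotone transforms commute with it", {
  set.seed(52)
  surv <- rlnorm(200, 0, 0.5)
  nons <- rlnorm(200, 0.6, 0.5)
  r_raw <- safe_upper_limit(surv, nons)
  r_log <- safe_upper_limit(log(surv), log(nons))
  expect_equal(r_raw$p_value, r_log$p_value)
  # quantile interpolation is applied on the transformed scale, so map the
  # order statistics: log is monotone, interpolation commutes approximately;
  # the gate decision and bracketing order statistics are exactly shared
  expect_equal(findInterval(r_raw$limit, sort(surv)),
               findInterval(r_log$limit, sort(log(surv))))
})

test_that("under the null the limit appears at roughly the alpha rate", {
  set.seed(61)
  hits <- vapply(seq_len(400), function(i) {
    a <- rnorm(60)
    b <- rnorm(60)
    !is.na(safe_upper_limit(a, b, alpha = 0.05)$limit)
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(mean(hits) - 0.05), 3.5 * se)
})

test_that("per-stratum limits include a pooled row and skip tiny arms", {
  coh <- small_cohort()
  adm <- coh$admissions
  tf <- build_twa_features(coh$vent_series, adm)
  hy <- assign_hypoxemia(coh$vent_series, adm)
  lim <- suppressWarnings(limits_by_stratum(tf, adm, hy))
  expect_true("all" %in% lim$stratum)
  expect_true(all(lim$variable %in% c("mp", "mp_ibw")))
  expect_true(all(lim$window_h %in% c(24, 48)))
  # a present limit always lies within the survivors' observed range
  for (i in which(!is.na(lim$limit) & lim$stratum == "all")) {
    t_sub <- merge(tf[tf$window_h == lim$window_h[i], ],
                   adm[, c("admission_id", "icu_mortality")], "admission_id")
    v <- if (lim$variable[i] == "mp") t_sub$twa_mp else t_sub$twa_mp_ibw
    surv <- v[t_sub$icu_mortality == 0]
    expect_gte(lim$limit[i], min(surv, na.rm = TRUE))
    expect_lte(lim$limit[i], max(surv, na.rm = TRUE))
  }
})

test_that("an injected mortality step is recovered as the survivor percentile", {
  coh <- generate_cohort(synth_config(
    n_admissions = 500, seed = 88, sampling_interval_min = 240,
    horizon_hours = 48, missing_rate = 0))
  tau <- stats::median(coh$truth$mp_ibw48)
  coh <- inject_mortality_threshold(coh, tau, 3)
  adm <- coh$admissions
  tf <- build_twa_features(coh$vent_series, adm)
  hy <- assign_hypoxemia(coh$vent_series, adm)
  lim <- suppressWarnings(limits_by_stratum(tf, adm, hy))
  row <- lim[lim$stratum == "all" & lim$variable == "mp_ibw" &
               lim$window_h == 48, ]
  expect_false(is.na(row$limit))
  t48 <- merge(tf[tf$window_h == 48, ], adm[, c("admission_id", "icu_mortality")],
               "admission_id")
  surv <- t48$twa_mp_ibw[t48$icu_mortality == 0]
  expect_equal(row$limit, unname(quantile(surv, 0.95)))
})

test_that("per-kg limits convert to absolute MP by exact multiplication", {
  expect_equal(to_absolute_mp(0.22, 70.57), 15.53)
  expect_equal(to_absolute_mp(0.27, 70.57), 19.05)
  expect_equal(to_absolute_mp(0.34, 70.57), 23.99)
  expect_equal(to_absolute_mp(0, 123), 0)
  # multiplicative and unit-scaling commutation
  expect_equal(to_absolute_mp(0.5, 80), to_absolute_mp(1, 40))
})

test_that("survival by limit: null groups give HR near 1, known HR is recovered", {
  set.seed(71)
  n <- 1000
  # synthetic features: exposure defines the groups through the limit
  mp_ibw <- c(runif(n / 2, 0.1, 0.3), runif(n / 2, 0.31, 0.6))
  below <- mp_ibw <= 0.3
  # exponential survival with true HR 0.5 for the below-limit group
  rate <- ifelse(below, 0.01 * 0.5, 0.01)
  t_event <- rexp(n, rate)
  event <- as.integer(t_event <= 90)
  tf <- data.frame(admission_id = paste0("s", 1:n), window_h = 48,
                   twa_mp_ibw = mp_ibw)
  outc <- data.frame(admission_id = paste0("s", 1:n),
                     icu_mortality = event,
                     followup_days = pmin(t_event, 90))
  strata <- data.frame(admission_id = paste0("s", 1:n),
                       hypoxemia_group = "mild")
  lim <- data.frame(stratum = "all", variable = "mp_ibw", window_h = 48,
                    p_value = 0.001, limit = 0.3,
                    n_survivors = sum(event == 0), n_nonsurvivors = sum(event))
  rep <- survival_by_limit(tf, outc, lim, strata)
  r <- rep$reports$all
  expect_false(isTRUE(r$degenerate))
  expect_gt(0.5, r$ci_low)
  expect_lt(0.5, r$ci_high)
  # KM curves are valid survival functions
  for (g in unique(r$km$group)) {
    s <- r$km$surv[r$km$group == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
  }

  # identical hazards: HR CI covers 1
  rate2 <- rep(0.008, n)
  t2 <- rexp(n, rate2)
  outc2 <- data.frame(admission_id = paste0("s", 1:n),
                      icu_mortality = as.integer(t2 <= 90),
                      followup_days = pmin(t2, 90))
  rep2 <- survival_by_limit(tf, outc2, lim, strata)
  expect_gt(1, rep2$reports$all$ci_low)
  expect_lt(1, rep2$reports$all$ci_high)
})

test_that("strata without a limit are omitted; degenerate fits are flagged", {
  n <- 40
  tf <- data.frame(admission_id = paste0("s", 1:n), window_h = 48,
                   twa_mp_ibw = runif(n, 0.1, 0.6))
  outc <- data.frame(admission_id = paste0("s", 1:n),
                     icu_mortality = rep(0L, n), followup_days = rep(90, n))
  strata <- data.frame(admission_id = paste0("s", 1:n),
                       hypoxemia_group = "severe")
  lim <- data.frame(stratum = c("all", "severe"), variable = "mp_ibw",
                    window_h = 48, p_value = c(0.01, 0.4),
                    limit = c(0.3, NA), n_survivors = n, n_nonsurvivors = 0)
  rep <- survival_by_limit(tf, outc, lim, strata)
  expect_equal(rep$omitted, "severe")
  # all-censored data cannot support a fit
  expect_true(rep$reports$all$degenerate)
})
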