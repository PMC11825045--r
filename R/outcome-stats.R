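#' Compare a variable between nonsurvivors and survivors
#'
#' Two-sided comparison in the descriptive-table style: Mann-Whitney rank
#' test with median/IQR for skewed continuous variables, Welch t-test with
#' mean/SD for symmetric ones, chi-square for categorical.
#'
#' @param values_dead,values_alive Observations per arm. For
#'   `var_kind = "categorical"` both are factors/character vectors; otherwise
#'   numeric.
#' @param var_kind `"continuous_nonsymmetric"` (default),
#'   `"continuous_symmetric"`, or `"categorical"`.
#' @return List with `p_value`, `test`, and per-arm descriptives (`dead`,
#'   `alive`: median/IQR or mean/SD, or category counts).
#' @export
compare_groups <- function(values_dead, values_alive,
                           var_kind = c("continuous_nonsymmetric",
                                        "continuous_symmetric",
                                        "categorical")) {
  var_kind <- match.arg(var_kind)
  values_dead <- values_dead[!is.na(values_dead)]
  values_alive <- values_alive[!is.na(values_alive)]
  if (length(values_dead) < 2 || length(values_alive) < 2) {
    return(list(p_value = NA_real_, test = "insufficient_data",
                flagged = TRUE, dead = NULL, alive = NULL))
  }
  if (var_kind == "categorical") {
    lv <- union(unique(values_dead), unique(values_alive))
    tab <- rbind(dead = table(factor(values_dead, levels = lv)),
                 alive = table(factor(values_alive, levels = lv)))
    ht <- suppressWarnings(stats::chisq.test(tab))
    return(list(p_value = ht$p.value, test = "chi-square",
                statistic = unname(ht$statistic),
                dead = tab["dead", ], alive = tab["alive", ]))
  }
  describe <- function(x, symmetric) {
    if (symmetric) {
      c(mean = mean(x), sd = stats::sd(x))
    } else {
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
      c(median = q[2], q1 = q[1], q3 = q[3])
    }
  }
  if (var_kind == "continuous_symmetric") {
    ht <- stats::t.test(values_dead, values_alive)
    list(p_value = ht$p.value, test = "t-test",
         dead = describe(values_dead, TRUE), alive = describe(values_alive, TRUE))
  } else {
    ht <- rank_test(values_dead, values_alive, alternative = "two.sided")
    list(p_value = ht$p.value, test = "mann-whitney",
         dead = describe(values_dead, FALSE), alive = describe(values_alive, FALSE))
  }
}

# Mann-Whitney with the small-sample policy used throughout: exact
# enumeration when both arms have <= `exact_max` observations and no ties,
# normal approximation with tie correction (and continuity correction)
# otherwise.
rank_test <- function(x, y, alternative, exact_max = 8) {
  ties <- any(duplicated(c(x, y)))
  use_exact <- length(x) <= exact_max && length(y) <= exact_max && !ties
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative,
                       exact = use_exact, correct = TRUE)
  )
}

#' Unadjusted odds ratio of a binary outcome per unit of exposure
#'
#' Exponentiated slope of a single-predictor logistic regression, with a Wald
#' 95 percent confidence interval. Complete or quasi-complete separation is
#' flagged and no estimate is returned.
#'
#' @param exposure Numeric exposure.
#' @param outcome 0/1 (or logical) outcome; both classes must occur.
#' @return List: `or`, `ci_low`, `ci_high`, `p_value`, `separation` flag.
#' @export
unadjusted_or <- function(exposure, outcome) {
  outcome <- as.integer(outcome)
  keep <- !is.na(exposure) & !is.na(outcome)
  exposure <- exposure[keep]; outcome <- outcome[keep]
  if (length(unique(outcome)) < 2) {
    stop("outcome must contain both classes", call. = FALSE)
  }
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(outcome ~ exposure, family = stats::binomial()),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  beta <- stats::coef(fit)[["exposure"]]
  se <- sqrt(stats::vcov(fit)["exposure", "exposure"])
  separated <- warned && (abs(beta) > 15 || se > 100)
  if (separated) {
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                p_value = NA_real_, separation = TRUE))
  }
  z <- stats::qnorm(0.975)
  list(or = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
       p_value = summary(fit)$coefficients["exposure", "Pr(>|z|)"],
       separation = FALSE)
}

#' Safe upper limit from a rank-test-gated survivor percentile
#'
#' Tests, one-sided, whether the exposure distribution is stochastically
#' greater among nonsurvivors (Mann-Whitney). If significant at `alpha`, the
#' safe upper limit is the survivors' `(1 - alpha) * 100`th percentile
#' (linearly interpolated by default); otherwise no limit is returned.
#'
#' @param survivor_values,nonsurvivor_values Exposure per arm (both
#'   non-empty).
#' @param alpha Significance level in (0, 0.5), default 0.05.
#' @param quantile_type Percentile definition passed to [stats::quantile()]
#'   (default 7, linear interpolation between order statistics).
#' @return List of class `safe_limit_result`: `p_value`, `alpha`, `limit`
#'   (`NA` when the gate fails), `n_survivors`, `n_nonsurvivors`.
#' @export
safe_upper_limit <- function(survivor_values, nonsurvivor_values, alpha = 0.05,
                             quantile_type = 7) {
  survivor_values <- survivor_values[!is.na(survivor_values)]
  nonsurvivor_values <- nonsurvivor_values[!is.na(nonsurvivor_values)]
  stopifnot(length(survivor_values) > 0, length(nonsurvivor_values) > 0,
            alpha > 0, alpha < 0.5)
  ht <- rank_test(nonsurvivor_values, survivor_values, alternative = "greater")
  p <- ht$p.value
  limit <- if (is.finite(p) && p < alpha) {
    stats::quantile(survivor_values, 1 - alpha, type = quantile_type,
                    names = FALSE)
  } else {
    NA_real_
  }
  structure(list(p_value = p, alpha = alpha, limit = limit,
                 n_survivors = length(survivor_values),
                 n_nonsurvivors = length(nonsurvivor_values)),
            class = "safe_limit_result")
}

#' Safe upper limits per hypoxemia stratum
#'
#' Runs [safe_upper_limit()] for MP and MP/IBW, per analysis window, within
#' each hypoxemia stratum and pooled over all admissions. Strata with fewer
#' than two observations in either arm are skipped with a warning.
#'
#' @param twa_features Output of [build_twa_features()].
#' @param outcomes Data frame (`admission_id`, `icu_mortality`).
#' @param strata Data frame (`admission_id`, `hypoxemia_group`), e.g. from
#'   [assign_hypoxemia()].
#' @param alpha Significance level (default 0.05).
#' @param variables Which exposures to threshold (columns `twa_mp`,
#'   `twa_mp_ibw`).
#' @return Data frame with one row per stratum x variable x window:
#'   `stratum`, `variable`, `window_h`, `p_value`, `limit`, `n_survivors`,
#'   `n_nonsurvivors`.
#' @export
limits_by_stratum <- function(twa_features, outcomes, strata, alpha = 0.05,
                              variables = c("twa_mp", "twa_mp_ibw")) {
  df <- merge(twa_features, outcomes[, c("admission_id", "icu_mortality")],
              by = "admission_id")
  df <- merge(df, strata[, c("admission_id", "hypoxemia_group")],
              by = "admission_id", all.x = TRUE)
  stratum_sets <- c(list(all = rep(TRUE, nrow(df))),
                    lapply(stats::setNames(nm = hypoxemia_levels()), function(g) {
                      !is.na(df$hypoxemia_group) & df$hypoxemia_group == g
                    }))
  rows <- list()
  for (sname in names(stratum_sets)) {
    sel <- stratum_sets[[sname]]
    if (sname != "all" && !any(sel)) next
    for (w in unique(df$window_h)) {
      for (v in variables) {
        sub <- df[sel & df$window_h == w, , drop = FALSE]
        x <- sub[[v]]
        dead <- sub$icu_mortality == 1
        surv <- x[!dead & !is.na(x)]
        nons <- x[dead & !is.na(x)]
        if (length(surv) < 2 || length(nons) < 2) {
          warning("stratum ", sname, " window ", w, " variable ", v,
                  ": fewer than 2 observations per arm, skipped")
          next
        }
        r <- safe_upper_limit(surv, nons, alpha)
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = sname, variable = sub_variable_name(v), window_h = w,
          p_value = r$p_value, limit = r$limit,
          n_survivors = r$n_survivors, n_nonsurvivors = r$n_nonsurvivors,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

sub_variable_name <- function(v) {
  switch(v, twa_mp = "mp", twa_mp_ibw = "mp_ibw", v)
}

#' Convert a per-kg MP limit to absolute mechanical power
#'
#' @param limit_per_kg Safe upper limit in J/min/kg.
#' @param ibw_kg Ideal body weight in kg.
#' @return Absolute limit in J/min, rounded to 2 decimals.
#' @examples
#' to_absolute_mp(0.22, 70.57)  # 15.53
#' @export
to_absolute_mp <- function(limit_per_kg, ibw_kg) {
  stopifnot(all(limit_per_kg >= 0), all(ibw_kg >= 0))
  round(limit_per_kg * ibw_kg, 2)
}

#' Survival analysis stratified by safe limits
#'
#' Within each stratum holding a limit, admissions are grouped by whether
#' their exposure stayed at or below the limit; a Cox proportional-hazards
#' model is fitted on the group indicator (optionally covariate-adjusted) and
#' Kaplan-Meier curves are estimated per group with administrative censoring
#' at `horizon_days`.
#'
#' @param twa_features Output of [build_twa_features()], one window.
#' @param outcomes Data frame with `admission_id`, `icu_mortality`,
#'   `followup_days`.
#' @param limits Data frame as returned by [limits_by_stratum()] (rows with
#'   `NA` limit are reported as omitted).
#' @param strata Data frame (`admission_id`, `hypoxemia_group`).
#' @param covariates Character vector of adjustment columns present in
#'   `outcomes` (explicit, possibly empty).
#' @param variable Exposure column, default `"twa_mp_ibw"`.
#' @param window_h Analysis window to use, default 48.
#' @param horizon_days Administrative censoring horizon, default 90.
#' @return List of class `survival_report` entries, one per stratum with a
#'   limit: `stratum`, `hazard_ratio`, `ci_low`, `ci_high`, `p_value`, `km`
#'   (data frame: `group`, `time`, `surv`), `degenerate` flag. Strata without
#'   limits are listed in `$omitted`.
#' @export
survival_by_limit <- function(twa_features, outcomes, limits, strata,
                              covariates = character(0),
                              variable = "twa_mp_ibw", window_h = 48,
                              horizon_days = 90) {
  vshort <- sub_variable_name(variable)
  lim <- limits[limits$variable == vshort & limits$window_h == window_h, ,
                drop = FALSE]
  df <- merge(twa_features[twa_features$window_h == window_h, ], outcomes,
              by = "admission_id")
  df <- merge(df, strata[, c("admission_id", "hypoxemia_group")],
              by = "admission_id", all.x = TRUE)
  df$time <- pmin(df$followup_days, horizon_days)
  df$event <- as.integer(df$icu_mortality == 1 & df$followup_days <= horizon_days)

  reports <- list()
  omitted <- character(0)
  for (i in seq_len(nrow(lim))) {
    sname <- lim$stratum[i]
    if (is.na(lim$limit[i])) {
      omitted <- c(omitted, sname)
      next
    }
    sub <- if (sname == "all") df else df[!is.na(df$hypoxemia_group) &
                                            df$hypoxemia_group == sname, ]
    sub$below_limit <- as.integer(sub[[variable]] <= lim$limit[i])
    if (length(unique(sub$below_limit)) < 2 || sum(sub$event) == 0) {
      reports[[sname]] <- list(stratum = sname, degenerate = TRUE)
      next
    }
    fml <- stats::reformulate(c("below_limit", covariates),
                              response = "survival::Surv(time, event)")
    fit <- tryCatch(survival::coxph(fml, data = sub),
                    error = function(e) NULL,
                    warning = function(w) {
                      suppressWarnings(survival::coxph(fml, data = sub))
                    })
    if (is.null(fit) || !is.finite(stats::coef(fit)[["below_limit"]])) {
      reports[[sname]] <- list(stratum = sname, degenerate = TRUE)
      next
    }
    beta <- stats::coef(fit)[["below_limit"]]
    se <- sqrt(stats::vcov(fit)["below_limit", "below_limit"])
    km_fit <- survival::survfit(survival::Surv(time, event) ~ below_limit,
                                data = sub)
    km <- data.frame(
      group = rep(sub("below_limit=", "", names(km_fit$strata)),
                  km_fit$strata),
      time = km_fit$time, surv = km_fit$surv, stringsAsFactors = FALSE)
    reports[[sname]] <- list(
      stratum = sname,
      hazard_ratio = exp(beta),
      ci_low = exp(beta - stats::qnorm(0.975) * se),
      ci_high = exp(beta + stats::qnorm(0.975) * se),
      p_value = summary(fit)$coefficients["below_limit", "Pr(>|z|)"],
      km = km,
      degenerate = se > 100
    )
  }
  structure(list(reports = reports, omitted = omitted),
            class = "survival_report")
}
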