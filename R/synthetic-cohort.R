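#' Configuration for the synthetic ICU cohort generator
#'
#' Bundles the generative assumptions of the simulated cohort: the hypoxemia
#' mix, the ventilation sampling scheme, the physiological sampling bounds and
#' the logistic mortality model linking death probability to IBW-normalised
#' mechanical power and covariates.
#'
#' @param n_admissions Number of admissions to generate (>= 0).
#' @param seed Integer seed; fixes every random draw in the generator.
#' @param group_mix Probabilities over the four hypoxemia strata
#'   (nonhypoxemic, mild, moderate, severe); must sum to 1. Defaults follow a
#'   mixed medical/surgical adult ICU case mix.
#' @param sampling_interval_min Minutes between validated ventilation samples.
#' @param horizon_hours Length of the emitted ventilation series per
#'   admission; must be >= 48 so both analysis windows are fully covered.
#' @param beta_mp_ibw Log-odds of ICU death per 1 J/min/kg of 48-hour
#'   time-weighted-average MP/IBW.
#' @param beta_covariates Named log-odds vector; names must be admission-table
#'   columns (default: `age_years`, `lactate_highest`).
#' @param baseline_log_odds Intercept of the mortality model.
#' @param missing_rate Fraction of values blanked completely at random per
#'   affected feature, in [0, 0.5].
#' @param compliance_mean_sd Mean and SD of respiratory-system compliance in
#'   mL/cmH2O; tidal volume is generated as compliance x driving pressure.
#' @param rr_range,peep_range,dp_range Physiological sampling bounds for
#'   respiratory rate (breaths/min), PEEP and driving pressure (cmH2O).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_admissions = 1000L,
                         seed = 1L,
                         group_mix = c(nonhypoxemic = 0.263, mild = 0.3148,
                                       moderate = 0.3593, severe = 0.0629),
                         sampling_interval_min = 60,
                         horizon_hours = 72,
                         beta_mp_ibw = 1.4,
                         beta_covariates = c(age_years = 0.026,
                                             lactate_highest = 0.153),
                         baseline_log_odds = -3.9,
                         missing_rate = 0.05,
                         compliance_mean_sd = c(35, 8),
                         rr_range = c(13, 27),
                         peep_range = c(5, 15),
                         dp_range = c(8, 20)) {
  if (length(n_admissions) != 1 || is.na(n_admissions) || n_admissions < 0) {
    stop("n_admissions must be a single non-negative count", call. = FALSE)
  }
  if (length(group_mix) != 4 || abs(sum(group_mix) - 1) > 1e-9) {
    stop("group_mix must be four probabilities summing to 1", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate > 0.5) {
    stop("missing_rate must lie in [0, 0.5]", call. = FALSE)
  }
  if (horizon_hours < 48) {
    stop("horizon_hours must be >= 48", call. = FALSE)
  }
  names(group_mix) <- hypoxemia_levels()
  structure(list(
    n_admissions = as.integer(n_admissions),
    seed = as.integer(seed),
    group_mix = group_mix,
    sampling_interval_min = sampling_interval_min,
    horizon_hours = horizon_hours,
    beta_mp_ibw = beta_mp_ibw,
    beta_covariates = beta_covariates,
    baseline_log_odds = baseline_log_odds,
    missing_rate = missing_rate,
    compliance_mean_sd = compliance_mean_sd,
    rr_range = rr_range,
    peep_range = peep_range,
    dp_range = dp_range
  ), class = "synth_config")
}

#' Read a generator configuration from YAML
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [synth_config()].
#' @return A `synth_config` object.
#' @export
synth_config_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$group_mix)) cfg$group_mix <- unlist(cfg$group_mix)
  if (!is.null(cfg$beta_covariates)) cfg$beta_covariates <- unlist(cfg$beta_covariates)
  if (!is.null(cfg$compliance_mean_sd)) cfg$compliance_mean_sd <- unlist(cfg$compliance_mean_sd)
  do.call(synth_config, cfg)
}

hypoxemia_levels <- function() c("nonhypoxemic", "mild", "moderate", "severe")

#' Generate a synthetic ICU cohort
#'
#' Emits an admissions table (demographics, worst/best laboratory values,
#' outcome), a per-admission pressure-controlled ventilation time series
#' (piecewise-constant settings with occasional changes), and a truth table
#' carrying each admission's latent hypoxemia stratum and configured death
#' probability. The death indicator is drawn from a logistic model on the
#' 48-hour time-weighted-average MP/IBW plus the configured covariates, so
#' parameter-recovery experiments downstream have a known target.
#'
#' @param config A [synth_config()] object.
#' @return An object of class `synthetic_cohort`: a list with data frames
#'   `admissions`, `vent_series`, `truth`, and the `config` used.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_admissions
  if (n == 0L) {
    return(empty_cohort(config))
  }
  set.seed(config$seed)
  adm <- draw_admissions(n, config)
  series <- draw_vent_series(adm, config)

  feats <- build_twa_features(series, adm, windows_h = 48)
  mp_ibw48 <- feats$twa_mp_ibw[match(adm$admission_id, feats$admission_id)]

  lp <- config$baseline_log_odds + config$beta_mp_ibw * mp_ibw48
  for (nm in names(config$beta_covariates)) {
    if (!nm %in% names(adm)) {
      stop("beta_covariates names an unknown admission column: ", nm, call. = FALSE)
    }
    lp <- lp + config$beta_covariates[[nm]] * adm[[nm]]
  }
  p_death <- stats::plogis(lp)
  adm$icu_mortality <- stats::rbinom(n, 1L, p_death)
  adm$followup_days <- draw_followup(adm$icu_mortality)

  truth <- data.frame(
    admission_id = adm$admission_id,
    stratum = adm$stratum_true,
    p_death = p_death,
    mp_ibw48 = mp_ibw48,
    stringsAsFactors = FALSE
  )
  adm$stratum_true <- NULL

  out <- inject_missingness(adm, series, config)
  structure(list(admissions = out$admissions, vent_series = out$vent_series,
                 truth = truth, config = config),
            class = "synthetic_cohort")
}

empty_cohort <- function(config) {
  adm <- draw_admissions(0L, config)
  adm$icu_mortality <- integer(0)
  adm$followup_days <- numeric(0)
  adm$stratum_true <- NULL
  structure(list(
    admissions = adm,
    vent_series = draw_vent_series(adm, config),
    truth = data.frame(admission_id = character(0), stratum = character(0),
                       p_death = numeric(0), mp_ibw48 = numeric(0),
                       stringsAsFactors = FALSE),
    config = config
  ), class = "synthetic_cohort")
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

draw_admissions <- function(n, config) {
  id <- sprintf("adm%05d", seq_len(n))
  stratum <- sample(hypoxemia_levels(), n, replace = TRUE, prob = config$group_mix)
  sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(2, 1) / 3)
  height_cm <- clip(stats::rnorm(n, 175, 10), 150, 200)
  weight_kg <- clip(stats::rnorm(n, 80, 15), 40, 160)
  data.frame(
    admission_id = id,
    age_years = round(clip(stats::rnorm(n, 63, 16), 18, 95)),
    sex = sex,
    height_cm = height_cm,
    weight_kg = weight_kg,
    urgency = stats::rbinom(n, 1L, 0.55),
    specialty = sample(c("cardio_surgery", "cardiology", "neurosurgery",
                         "general_surgery", "internal_medicine", "trauma"),
                       n, replace = TRUE,
                       prob = c(0.28, 0.20, 0.13, 0.12, 0.17, 0.10)),
    sofa_total = round(clip(stats::rnorm(n, 7.3, 2.6), 0, 24)),
    sofa_resp = round(clip(stats::rnorm(n, 1.9, 0.4), 0, 4)),
    mv_duration_h = stats::rlnorm(n, log(140), 0.75),
    wbc_highest = stats::rlnorm(n, log(17), 0.35),
    hemoglobin_lowest = clip(stats::rnorm(n, 5.6, 1.2), 2, 12),
    thrombocytes_lowest = stats::rlnorm(n, log(130), 0.6),
    asat_highest = stats::rlnorm(n, log(90), 1.0),
    aptt_highest = stats::rlnorm(n, log(60), 0.5),
    crp_highest = stats::rlnorm(n, log(97), 1.0),
    lactate_highest = stats::rlnorm(n, log(3.8), 0.7),
    creatinine_highest = stats::rlnorm(n, log(115), 0.5),
    urea_highest = stats::rlnorm(n, log(9), 0.5),
    sodium_highest = stats::rnorm(n, 145, 3),
    potassium_highest = stats::rnorm(n, 4.8, 0.4),
    ph_lowest = clip(stats::rnorm(n, 7.21, 0.07), 6.8, 7.45),
    pco2_highest = clip(stats::rnorm(n, 54, 8), 30, 90),
    stratum_true = stratum,
    stringsAsFactors = FALSE
  )
}

# Per-stratum sampling envelopes: worse hypoxemia ventilates harder (higher
# driving pressures, rates and PEEP), reproducing the MP gradient across
# strata seen in practice.
stratum_profiles <- function() {
  list(
    nonhypoxemic = list(pfr = c(305, 440), fio2 = c(0.30, 0.45), shift = c(rr = -1, peep = -1, dp = -2)),
    mild         = list(pfr = c(205, 298), fio2 = c(0.35, 0.50), shift = c(rr =  0, peep =  0, dp =  0)),
    moderate     = list(pfr = c(105, 196), fio2 = c(0.40, 0.70), shift = c(rr =  1, peep =  1, dp =  2)),
    severe       = list(pfr = c(55,  97),  fio2 = c(0.60, 1.00), shift = c(rr =  3, peep =  2, dp =  4))
  )
}

draw_vent_series <- function(adm, config) {
  n <- nrow(adm)
  empty <- data.frame(admission_id = character(0), t_min = numeric(0),
                      tv_L = numeric(0), rr = numeric(0), peep = numeric(0),
                      dp = numeric(0), ti_s = numeric(0), fio2 = numeric(0),
                      pao2 = numeric(0), paco2 = numeric(0), ph = numeric(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)

  profiles <- stratum_profiles()
  times <- seq(0, config$horizon_hours * 60, by = config$sampling_interval_min)
  m <- length(times)
  pieces <- vector("list", n)

  for (i in seq_len(n)) {
    prof <- profiles[[adm$stratum_true[i]]]
    compliance_L <- clip(stats::rnorm(1, config$compliance_mean_sd[1],
                                      config$compliance_mean_sd[2]), 15, 80) / 1000
    pfr_target <- stats::runif(1, prof$pfr[1], prof$pfr[2])
    fio2_i <- stats::runif(1, prof$fio2[1], prof$fio2[2])
    ie_i <- clip(stats::rnorm(1, 0.52, 0.04), 0.35, 0.8)
    paco2_i <- clip(stats::rnorm(1, 45, 8), 25, 90)
    ph_i <- clip(7.72 - 0.008 * paco2_i + stats::rnorm(1, 0, 0.04), 6.9, 7.6)

    # Piecewise-constant settings: changes arrive as a Poisson process with
    # one expected change per 12 h.
    n_changes <- stats::rpois(1, config$horizon_hours / 12)
    change_t <- sort(stats::runif(n_changes, 0, config$horizon_hours * 60))
    seg_starts <- c(0, change_t)
    draw_settings <- function() {
      c(rr = clip(stats::runif(1, config$rr_range[1], config$rr_range[2]) +
                    prof$shift[["rr"]], config$rr_range[1], config$rr_range[2]),
        peep = clip(stats::runif(1, config$peep_range[1], config$peep_range[2]) +
                      prof$shift[["peep"]], config$peep_range[1], config$peep_range[2]),
        dp = clip(stats::runif(1, config$dp_range[1], config$dp_range[2]) +
                    prof$shift[["dp"]], config$dp_range[1], config$dp_range[2]))
    }
    segs <- t(vapply(seq_along(seg_starts), function(j) draw_settings(), numeric(3)))
    seg_idx <- findInterval(times, seg_starts)
    rr <- segs[seg_idx, "rr"]
    peep <- segs[seg_idx, "peep"]
    dp <- segs[seg_idx, "dp"]
    tv_L <- clip(compliance_L * dp, 0.2, 0.9)
    ti_s <- (60 / rr) * ie_i / (1 + ie_i)

    # PFR is held exactly at the stratum target over the first 6 h (the
    # stratification window), with multiplicative noise afterwards.
    noise <- ifelse(times < 360, 1, 1 + stats::rnorm(m, 0, 0.08))
    pao2 <- pfr_target * noise * fio2_i

    pieces[[i]] <- data.frame(
      admission_id = adm$admission_id[i], t_min = times,
      tv_L = tv_L, rr = rr, peep = peep, dp = dp, ti_s = ti_s,
      fio2 = fio2_i, pao2 = pao2,
      paco2 = paco2_i + stats::rnorm(m, 0, 2),
      ph = ph_i + stats::rnorm(m, 0, 0.02),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

draw_followup <- function(death) {
  n <- length(death)
  t_death <- clip(stats::rweibull(n, shape = 1.3, scale = 14), 2.1, 90)
  ifelse(death == 1L, t_death, 90)
}

# MCAR blanking. Laboratory values and measured (non-setting) ventilation
# signals can be missing; charted ventilator settings are always present.
inject_missingness <- function(adm, series, config) {
  rate <- config$missing_rate
  if (rate > 0) {
    lab_cols <- c("wbc_highest", "hemoglobin_lowest", "thrombocytes_lowest",
                  "asat_highest", "aptt_highest", "crp_highest",
                  "lactate_highest", "creatinine_highest", "urea_highest",
                  "sodium_highest", "potassium_highest", "ph_lowest",
                  "pco2_highest")
    for (cl in lab_cols) {
      adm[[cl]][stats::runif(nrow(adm)) < rate] <- NA_real_
    }
    for (cl in c("pao2", "ti_s")) {
      series[[cl]][stats::runif(nrow(series)) < rate] <- NA_real_
    }
  }
  list(admissions = adm, vent_series = series)
}

#' Inject a mortality step above an MP/IBW threshold
#'
#' Test scaffolding for limit-recovery experiments: raises the death
#' probability, on the log-odds scale, by `jump` for exactly those admissions
#' whose 48-hour TWA MP/IBW exceeds `tau`, redraws their death indicators with
#' a seed derived from the cohort's, and leaves every other admission
#' untouched.
#'
#' @param cohort A `synthetic_cohort`.
#' @param tau Threshold in J/min/kg; must lie inside the observed MP/IBW
#'   range, otherwise the cohort is returned unchanged with a warning.
#' @param jump Log-odds increment (0 leaves the cohort identical).
#' @return The modified `synthetic_cohort`.
#' @export
inject_mortality_threshold <- function(cohort, tau, jump) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  mp <- cohort$truth$mp_ibw48
  if (length(mp) == 0 || tau < min(mp, na.rm = TRUE) || tau > max(mp, na.rm = TRUE)) {
    warning("tau lies outside the observed MP/IBW range; cohort unchanged")
    attr(cohort, "tau_out_of_range") <- TRUE
    return(cohort)
  }
  if (jump == 0) {
    return(cohort)
  }
  hit <- !is.na(mp) & mp > tau
  p_new <- stats::plogis(stats::qlogis(cohort$truth$p_death) + jump)
  cohort$truth$p_death[hit] <- p_new[hit]

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed((cohort$config$seed + 77003L) %% .Machine$integer.max)
  death <- stats::rbinom(sum(hit), 1L, p_new[hit])
  cohort$admissions$icu_mortality[hit] <- death
  cohort$admissions$followup_days[hit] <- draw_followup(death)
  cohort
}

#' Write a synthetic cohort to disk
#'
#' Emits `admissions.csv` (one row per admission), `vent_series.csv` (long
#' format: admission_id, t_min, variable, value) and `manifest.json` recording
#' the seed and configuration.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$admissions, file.path(dir, "admissions.csv"),
                   row.names = FALSE)
  long <- vent_series_to_long(cohort$vent_series)
  utils::write.csv(long, file.path(dir, "vent_series.csv"), row.names = FALSE)
  cfg <- cohort$config
  manifest <- list(seed = cfg$seed, n_admissions = cfg$n_admissions,
                   config = unclass(cfg))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding `admissions.csv` and `vent_series.csv`.
#' @return A list with data frames `admissions` and `vent_series` (wide,
#'   one row per sample).
#' @export
read_cohort <- function(dir) {
  adm <- utils::read.csv(file.path(dir, "admissions.csv"),
                         stringsAsFactors = FALSE)
  long <- utils::read.csv(file.path(dir, "vent_series.csv"),
                          stringsAsFactors = FALSE)
  list(admissions = adm, vent_series = vent_series_from_long(long))
}

vent_series_to_long <- function(series) {
  vars <- setdiff(names(series), c("admission_id", "t_min"))
  pieces <- lapply(vars, function(v) {
    data.frame(admission_id = series$admission_id, t_min = series$t_min,
               variable = v, value = series[[v]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out[!is.na(out$value), , drop = FALSE]
}

vent_series_from_long <- function(long) {
  stopifnot(all(c("admission_id", "t_min", "variable", "value") %in% names(long)))
  key <- paste(long$admission_id, format(long$t_min, trim = TRUE), sep = "@")
  base <- unique(data.frame(admission_id = long$admission_id,
                            t_min = long$t_min, key = key,
                            stringsAsFactors = FALSE))
  for (v in unique(long$variable)) {
    sub_idx <- long$variable == v
    base[[v]] <- long$value[sub_idx][match(base$key, key[sub_idx])]
  }
  base$key <- NULL
  base <- base[order(base$admission_id, base$t_min), , drop = FALSE]
  rownames(base) <- NULL
  base
}
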