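#' Ideal body weight (Devine formula)
#'
#' Reference weight from height and sex, used to normalise tidal volume
#' (mL/kg IBW) and mechanical power (J/min/kg). Males: 50 + 0.91 x
#' (height - 152.4); females: 45.5 + 0.91 x (height - 152.4).
#'
#' @param height_cm Height in centimetres (> 0). Vectorised.
#' @param sex `"male"` or `"female"` (recycled against `height_cm`).
#' @return Ideal body weight in kg (unrounded; round only when reporting).
#' @examples
#' ibw(175, "male")    # 70.57 kg at the typical adult male height
#' ibw(152.4, "female")
#' @export
ibw <- function(height_cm, sex) {
  if (any(!is.finite(height_cm)) || any(height_cm <= 0)) {
    stop("height_cm must be positive and finite", call. = FALSE)
  }
  sex <- rep_len(as.character(sex), length(height_cm))
  bad <- !sex %in% c("male", "female")
  if (any(bad)) {
    stop("unknown sex code: ", paste(unique(sex[bad]), collapse = ", "),
         call. = FALSE)
  }
  base <- ifelse(sex == "male", 50, 45.5)
  base + 0.91 * (height_cm - 152.4)
}

#' Surrogate mechanical power of ventilation
#'
#' Energy per minute delivered by the ventilator in pressure-controlled
#' ventilation, from a surrogate of the full elastic-power equation:
#' \deqn{MP = 0.098 \times TV \times RR \times (PEEP + \Delta P)}
#' where TV is tidal volume (L), RR respiratory rate (breaths/min), PEEP the
#' end-expiratory pressure and \eqn{\Delta P} the inspiratory driving pressure
#' above PEEP (both cmH2O); their sum is the peak inspiratory pressure.
#'
#' @param tv_L Tidal volume in litres.
#' @param rr Respiratory rate, breaths/min.
#' @param peep Positive end-expiratory pressure, cmH2O.
#' @param dp Inspiratory driving pressure above PEEP, cmH2O.
#' @param pressure_mode `"sum"` (the surrogate; default) or `"product"`, an
#'   audit-only literal reading multiplying PEEP by driving pressure. The
#'   product form yields implausible magnitudes and is never used by the
#'   pipeline.
#' @return Mechanical power in J/min.
#' @examples
#' mechanical_power(0.5, 15, 5, 15)  # 14.7 J/min
#' @export
mechanical_power <- function(tv_L, rr, peep, dp, pressure_mode = c("sum", "product")) {
  pressure_mode <- match.arg(pressure_mode)
  args <- list(tv_L = tv_L, rr = rr, peep = peep, dp = dp)
  for (nm in names(args)) {
    if (any(args[[nm]] < 0, na.rm = TRUE)) {
      stop(nm, " must be non-negative", call. = FALSE)
    }
  }
  pressure <- if (pressure_mode == "sum") peep + dp else peep * dp
  0.098 * tv_L * rr * pressure
}

#' Minute ventilation
#'
#' @param tv_L Tidal volume, litres.
#' @param rr Respiratory rate, breaths/min.
#' @return Minute ventilation in L/min (`tv_L * rr`).
#' @export
minute_ventilation <- function(tv_L, rr) {
  tv_L * rr
}

#' Time-weighted average of a piecewise-constant signal
#'
#' Ventilator settings are step functions: a value holds until the next
#' recorded sample. The TWA over `[0, window_min]` is the sample-and-hold
#' integral divided by the covered duration. The last sample before the window
#' end is held to the boundary; samples at or after the boundary are ignored.
#' If the first sample falls after time 0, coverage starts there.
#'
#' @param t_min Sample times in minutes since ventilation start (sorted,
#'   non-negative).
#' @param value Sample values, same length as `t_min`. `NA` samples are
#'   dropped before integration.
#' @param window_min Window length in minutes (> 0).
#' @return The time-weighted mean, or `NA_real_` if no sample falls inside the
#'   window.
#' @examples
#' twa(c(0, 30), c(10, 20), 60)          # 15
#' twa(c(0, 10, 40), c(8, 12, 10), 60)   # 10.6667
#' @export
twa <- function(t_min, value, window_min) {
  stopifnot(length(t_min) == length(value), window_min > 0)
  keep <- !is.na(value) & !is.na(t_min)
  t_min <- t_min[keep]
  value <- value[keep]
  if (is.unsorted(t_min)) {
    o <- order(t_min)
    t_min <- t_min[o]
    value <- value[o]
  }
  inside <- t_min >= 0 & t_min < window_min
  if (!any(inside)) {
    return(NA_real_)
  }
  t <- t_min[inside]
  v <- value[inside]
  bounds <- c(t, window_min)
  durations <- diff(bounds)
  sum(durations * v) / (window_min - t[1])
}

#' Time-weighted ventilation features per admission
#'
#' Aggregates a per-admission ventilation series into the analysis features:
#' time-weighted averages over the first 24 and 48 hours of ventilation of the
#' PaO2/FiO2 ratio, respiratory rate, inspiratory time, I:E ratio, PEEP, tidal
#' volume (L and mL/kg IBW), driving pressure, peak pressure and mechanical
#' power, plus the 48-hour standard deviation of per-sample MP. MP is computed
#' per sample and then time-weighted, never as the product of the input TWAs
#' (the two differ whenever settings co-vary in time).
#'
#' @param vent_series Data frame of ventilation samples with columns
#'   `admission_id`, `t_min`, and any of `tv_L`, `rr`, `peep`, `dp`, `ti_s`,
#'   `fio2`, `pao2`.
#' @param admissions Data frame with columns `admission_id`, `height_cm`,
#'   `sex` (used for IBW).
#' @param windows_h Analysis windows in hours, default `c(24, 48)`.
#' @return Data frame, one row per admission per window, with columns
#'   `admission_id`, `window_h`, `ibw_kg`, `twa_pfr`, `twa_rr`, `twa_ti_s`,
#'   `twa_ie`, `twa_peep`, `twa_tv_L`, `twa_tv_mlkg`, `twa_dp`, `twa_ppeak`,
#'   `twa_mp`, `twa_mp_ibw`, `sd48_mp` (`NA` outside the 48 h window).
#' @export
build_twa_features <- function(vent_series, admissions, windows_h = c(24, 48)) {
  stopifnot(all(c("admission_id", "t_min") %in% names(vent_series)),
            all(c("admission_id", "height_cm", "sex") %in% names(admissions)))
  ids <- admissions$admission_id
  ibw_kg <- ibw(admissions$height_cm, admissions$sex)
  series_split <- split(vent_series, factor(vent_series$admission_id, levels = ids))

  rows <- vector("list", length(ids) * length(windows_h))
  k <- 0L
  for (i in seq_along(ids)) {
    s <- series_split[[i]]
    w_ibw <- ibw_kg[i]
    per_sample <- derive_sample_signals(s)
    for (w in windows_h) {
      k <- k + 1L
      rows[[k]] <- twa_feature_row(ids[i], per_sample, w, w_ibw)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Per-sample derived signals: PFR, I:E ratio, peak pressure, MP.
derive_sample_signals <- function(s) {
  n <- if (is.null(s)) 0L else nrow(s)
  get <- function(nm) if (n > 0 && nm %in% names(s)) s[[nm]] else rep(NA_real_, n)
  tv <- get("tv_L"); rr <- get("rr"); peep <- get("peep"); dp <- get("dp")
  ti <- get("ti_s"); fio2 <- get("fio2"); pao2 <- get("pao2")
  exp_s <- 60 / rr - ti
  data.frame(
    t_min = if (n > 0) s$t_min else numeric(0),
    pfr = pao2 / fio2,
    rr = rr,
    ti_s = ti,
    ie = ifelse(!is.na(exp_s) & exp_s > 0, ti / exp_s, NA_real_),
    peep = peep,
    tv_L = tv,
    dp = dp,
    ppeak = peep + dp,
    mp = 0.098 * tv * rr * (peep + dp)
  )
}

twa_feature_row <- function(id, ps, window_h, ibw_kg) {
  wmin <- window_h * 60
  agg <- function(col) twa(ps$t_min, ps[[col]], wmin)
  twa_tv <- agg("tv_L")
  twa_mp <- agg("mp")
  in48 <- ps$t_min >= 0 & ps$t_min < 48 * 60 & !is.na(ps$mp)
  data.frame(
    admission_id = id,
    window_h = window_h,
    ibw_kg = ibw_kg,
    twa_pfr = agg("pfr"),
    twa_rr = agg("rr"),
    twa_ti_s = agg("ti_s"),
    twa_ie = agg("ie"),
    twa_peep = agg("peep"),
    twa_tv_L = twa_tv,
    twa_tv_mlkg = twa_tv * 1000 / ibw_kg,
    twa_dp = agg("dp"),
    twa_ppeak = agg("ppeak"),
    twa_mp = twa_mp,
    twa_mp_ibw = twa_mp / ibw_kg,
    sd48_mp = if (window_h == 48 && sum(in48) >= 2) stats::sd(ps$mp[in48]) else NA_real_
  )
}
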