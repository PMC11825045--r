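#' Configuration for the ventilator-setting individualizer
#'
#' Grids, safety bounds and thresholds for the closed-loop search. The tidal
#' volume grid is a lung-protective 4-8 mL/kg IBW envelope; PEEP is never
#' searched (its titration is delegated to a parallel workflow).
#'
#' @param tv_mlkg_grid Tidal volume grid in mL/kg IBW (default 4-8 by 0.5).
#' @param rr_grid Respiratory-rate grid in breaths/min (default 10-35 by 1).
#' @param dp_bounds Allowed driving-pressure interval, cmH2O (default 2-30);
#'   grid combinations whose compliance-implied driving pressure falls
#'   outside are infeasible.
#' @param ve_tolerance Fractional tolerance on the minute-ventilation target
#'   for acidotic patients (default 0.05).
#' @param ve_increment L/min added to the current minute ventilation to form
#'   the acidotic patient's VE target (default 0).
#' @param cut Probability cut above which the model's prediction counts as
#'   death (default 0.5).
#' @param paco2_threshold,ph_threshold Respiratory-acidosis gate: acidotic
#'   iff PaCO2 > `paco2_threshold` (mmHg) and pH < `ph_threshold`
#'   (defaults 45 and 7.35).
#' @return A list of class `individualizer_config`.
#' @export
individualizer_config <- function(tv_mlkg_grid = seq(4, 8, by = 0.5),
                                  rr_grid = seq(10, 35, by = 1),
                                  dp_bounds = c(2, 30),
                                  ve_tolerance = 0.05,
                                  ve_increment = 0,
                                  cut = 0.5,
                                  paco2_threshold = 45,
                                  ph_threshold = 7.35) {
  structure(list(tv_mlkg_grid = tv_mlkg_grid, rr_grid = rr_grid,
                 dp_bounds = dp_bounds, ve_tolerance = ve_tolerance,
                 ve_increment = ve_increment, cut = cut,
                 paco2_threshold = paco2_threshold,
                 ph_threshold = ph_threshold),
            class = "individualizer_config")
}

#' Respiratory acidosis state
#'
#' Acidotic if and only if PaCO2 exceeds the CO2 threshold AND pH falls below
#' the pH threshold. The acidosis state selects the search objective:
#' acidotic patients maximise minute ventilation, others minimise mechanical
#' power.
#'
#' @param paco2 Arterial CO2 tension, mmHg.
#' @param ph Blood pH.
#' @param paco2_threshold,ph_threshold Gate thresholds (defaults 45, 7.35).
#' @return List (`paco2`, `ph`, `acidotic`); `acidotic` is `NA` when either
#'   input is missing.
#' @export
acidosis_status <- function(paco2, ph, paco2_threshold = 45,
                            ph_threshold = 7.35) {
  acidotic <- if (is.na(paco2) || is.na(ph)) {
    NA
  } else {
    paco2 > paco2_threshold && ph < ph_threshold
  }
  list(paco2 = paco2, ph = ph, acidotic = acidotic)
}

#' Enumerate feasible candidate ventilator settings
#'
#' Builds the tidal-volume x respiratory-rate grid, derives the driving
#' pressure each tidal volume implies through the patient's estimated
#' respiratory-system compliance (`tv_L = C x dp`), drops combinations whose
#' driving pressure leaves the safety bounds, applies the objective's
#' constraint (non-acidotic: MP not above the current MP; acidotic: VE within
#' tolerance of the VE target), and orders the survivors by the active
#' objective - descending VE when maximising ventilation, ascending MP when
#' minimising power - with ties broken by lower MP then lower RR.
#'
#' @param ibw_kg Ideal body weight, kg.
#' @param peep Current PEEP, cmH2O (held fixed).
#' @param compliance Respiratory-system compliance, L/cmH2O.
#' @param objective `"min_MP"` or `"max_VE"`.
#' @param current List with the current `tv_L`, `rr`, `dp` (used for the
#'   objective constraints).
#' @param config An [individualizer_config()].
#' @return Data frame of candidates (`tv_L`, `tv_mlkg`, `rr`, `dp`, `peep`,
#'   `ve`, `mp`), best first; zero rows when nothing is feasible.
#' @export
candidate_settings <- function(ibw_kg, peep, compliance,
                               objective = c("min_MP", "max_VE"),
                               current, config = individualizer_config()) {
  objective <- match.arg(objective)
  stopifnot(ibw_kg > 0, compliance > 0)
  grid <- expand.grid(tv_mlkg = config$tv_mlkg_grid, rr = config$rr_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$tv_L <- grid$tv_mlkg * ibw_kg / 1000
  grid$dp <- grid$tv_L / compliance
  grid <- grid[grid$dp >= config$dp_bounds[1] & grid$dp <= config$dp_bounds[2], ,
               drop = FALSE]
  if (nrow(grid) == 0) return(empty_candidates())
  grid$peep <- peep
  grid$ve <- minute_ventilation(grid$tv_L, grid$rr)
  grid$mp <- mechanical_power(grid$tv_L, grid$rr, grid$peep, grid$dp)

  current_ve <- minute_ventilation(current$tv_L, current$rr)
  current_mp <- mechanical_power(current$tv_L, current$rr, peep, current$dp)
  if (objective == "min_MP") {
    grid <- grid[grid$mp <= current_mp, , drop = FALSE]
    ord <- order(grid$mp, grid$rr)
  } else {
    target_ve <- current_ve + config$ve_increment
    grid <- grid[grid$ve >= target_ve * (1 - config$ve_tolerance), ,
                 drop = FALSE]
    ord <- order(-grid$ve, grid$mp, grid$rr)
  }
  if (nrow(grid) == 0) return(empty_candidates())
  out <- grid[ord, c("tv_L", "tv_mlkg", "rr", "dp", "peep", "ve", "mp")]
  rownames(out) <- NULL
  out
}

empty_candidates <- function() {
  data.frame(tv_L = numeric(0), tv_mlkg = numeric(0), rr = numeric(0),
             dp = numeric(0), peep = numeric(0), ve = numeric(0),
             mp = numeric(0))
}

# Uniform risk interface: a fitted mortality model or a plain function
# row -> P(death).
predict_risk <- function(model, row) {
  if (is.function(model)) {
    as.numeric(model(row))
  } else {
    predict(model, row, type = "prob")
  }
}

# Overwrite the ventilation-derived feature columns of a patient row from a
# candidate setting; non-ventilation covariates are never touched.
apply_settings_to_row <- function(row, settings, ibw_kg) {
  mp <- mechanical_power(settings$tv_L, settings$rr, settings$peep,
                         settings$dp)
  updates <- list(
    mp = mp,
    mp_ibw = mp / ibw_kg,
    tv_mlkg = settings$tv_L * 1000 / ibw_kg,
    rr = settings$rr,
    dp = settings$dp,
    peep = settings$peep,
    ve = minute_ventilation(settings$tv_L, settings$rr)
  )
  for (nm in names(updates)) {
    if (nm %in% names(row)) row[[nm]] <- updates[[nm]]
  }
  row
}

#' Individualize the ventilator settings of one patient
#'
#' Closed-loop what-if search: the acidosis gate picks the objective
#' (acidotic: maximise VE; otherwise minimise MP), candidates are enumerated
#' in objective order, and each candidate's ventilation-derived features are
#' fed to the frozen mortality model until the prediction flips to survival.
#' If no candidate flips the prediction, the settings are left unchanged.
#'
#' @param patient_row One-row data frame holding the model's feature columns
#'   plus `paco2`, `ph` and `ibw_kg`.
#' @param model A `mortality_fit` or a function mapping a feature row to
#'   P(death).
#' @param settings Current settings: list with `tv_L`, `rr`, `dp`, `peep`.
#' @param config An [individualizer_config()].
#' @param compliance Respiratory-system compliance (L/cmH2O); defaults to
#'   `settings$tv_L / settings$dp`.
#' @return List of class `individualization_outcome`: `admission_id` (if
#'   present in the row), `initial`, `final` (settings lists with `ve`, `mp`
#'   attached), `objective`, `initial_pred`, `final_pred` (`"death"` /
#'   `"survival"`), `flipped`, `iterations`, `skipped` (+ `skip_reason`).
#' @export
individualize <- function(patient_row, model, settings,
                          config = individualizer_config(),
                          compliance = NULL) {
  patient_row <- as.data.frame(patient_row)
  stopifnot(nrow(patient_row) == 1)
  skip <- function(reason) {
    structure(list(admission_id = patient_row$admission_id %||% NA_character_,
                   initial = settings, final = settings, objective = NA_character_,
                   initial_pred = NA_character_, final_pred = NA_character_,
                   flipped = FALSE, iterations = 0L, skipped = TRUE,
                   skip_reason = reason),
              class = "individualization_outcome")
  }
  acid <- acidosis_status(patient_row$paco2 %||% NA_real_,
                          patient_row$ph %||% NA_real_,
                          config$paco2_threshold, config$ph_threshold)
  if (is.na(acid$acidotic)) return(skip("acidosis state unknown"))
  objective <- if (acid$acidotic) "max_VE" else "min_MP"
  ibw_kg <- patient_row$ibw_kg
  if (is.null(ibw_kg) || is.na(ibw_kg)) return(skip("ibw unknown"))
  if (is.null(compliance)) compliance <- settings$tv_L / settings$dp

  annotate <- function(s) {
    s$ve <- minute_ventilation(s$tv_L, s$rr)
    s$mp <- mechanical_power(s$tv_L, s$rr, s$peep, s$dp)
    s
  }
  initial <- annotate(settings)
  row0 <- apply_settings_to_row(patient_row, initial, ibw_kg)
  p0 <- tryCatch(predict_risk(model, row0), error = function(e) NA_real_)
  if (is.na(p0)) return(skip("model prediction failure"))
  iterations <- 1L
  initial_pred <- if (p0 >= config$cut) "death" else "survival"
  if (initial_pred == "survival") {
    return(structure(list(
      admission_id = patient_row$admission_id %||% NA_character_,
      initial = initial, final = initial, objective = objective,
      initial_pred = "survival", final_pred = "survival", flipped = FALSE,
      iterations = iterations, skipped = FALSE),
      class = "individualization_outcome"))
  }

  cands <- candidate_settings(ibw_kg, settings$peep, compliance,
                              objective = objective,
                              current = settings, config = config)
  final <- initial
  final_pred <- "death"
  flipped <- FALSE
  for (j in seq_len(nrow(cands))) {
    cand <- annotate(as.list(cands[j, c("tv_L", "rr", "dp", "peep")]))
    rowj <- apply_settings_to_row(patient_row, cand, ibw_kg)
    pj <- tryCatch(predict_risk(model, rowj), error = function(e) NA_real_)
    if (is.na(pj)) return(skip("model prediction failure"))
    iterations <- iterations + 1L
    if (pj < config$cut) {
      final <- cand
      final_pred <- "survival"
      flipped <- TRUE
      break
    }
  }
  structure(list(
    admission_id = patient_row$admission_id %||% NA_character_,
    initial = initial, final = final, objective = objective,
    initial_pred = "death", final_pred = final_pred, flipped = flipped,
    iterations = iterations, skipped = FALSE),
    class = "individualization_outcome")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Case-study summary arithmetic
#'
#' @param n_initial Number of model-predicted nonsurvivors entered.
#' @param n_flipped Number whose prediction flipped to survival.
#' @return List (`n_initial`, `n_flipped`, `percent`), percent to 1 decimal
#'   (0 when `n_initial` is 0).
#' @examples
#' case_summary(614, 58)$percent  # 9.4
#' @export
case_summary <- function(n_initial, n_flipped) {
  stopifnot(n_initial >= 0, n_flipped >= 0, n_flipped <= max(n_initial, 0))
  pct <- if (n_initial == 0) 0 else round(100 * n_flipped / n_initial, 1)
  list(n_initial = n_initial, n_flipped = n_flipped, percent = pct)
}

#' Run the individualizer over predicted nonsurvivors
#'
#' Applies [individualize()] to each supplied patient and summarises how many
#' predictions flipped to survival. Rows whose initial prediction is already
#' survival are excluded from the denominator, as are skipped rows.
#'
#' @param patient_rows Data frame, one row per patient, holding the model's
#'   feature columns plus `paco2`, `ph`, `ibw_kg` and the current settings
#'   columns `tv_L`, `rr`, `dp`, `peep`.
#' @param model A `mortality_fit` or a risk function.
#' @param config An [individualizer_config()].
#' @return List of class `case_study`: `n_initial`, `n_flipped`, `percent`,
#'   `outcomes` (list of `individualization_outcome`), `n_skipped`.
#' @export
case_study <- function(patient_rows, model, config = individualizer_config()) {
  patient_rows <- as.data.frame(patient_rows)
  outcomes <- list()
  n_initial <- 0L
  n_flipped <- 0L
  n_skipped <- 0L
  for (i in seq_len(nrow(patient_rows))) {
    row <- patient_rows[i, , drop = FALSE]
    settings <- list(tv_L = row$tv_L, rr = row$rr, dp = row$dp,
                     peep = row$peep)
    out <- individualize(row, model, settings, config)
    outcomes[[length(outcomes) + 1L]] <- out
    if (isTRUE(out$skipped)) {
      n_skipped <- n_skipped + 1L
    } else if (identical(out$initial_pred, "death")) {
      n_initial <- n_initial + 1L
      if (out$flipped) n_flipped <- n_flipped + 1L
    }
  }
  s <- case_summary(n_initial, n_flipped)
  structure(list(n_initial = s$n_initial, n_flipped = s$n_flipped,
                 percent = s$percent, outcomes = outcomes,
                 n_skipped = n_skipped),
            class = "case_study")
}
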