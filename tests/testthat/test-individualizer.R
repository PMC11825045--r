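test_that("the acidosis gate is the conjunction of both thresholds", {
  expect_true(acidosis_status(50, 7.30)$acidotic)
  expect_false(acidosis_status(50, 7.40)$acidotic)
  expect_false(acidosis_status(40, 7.30)$acidotic)
  expect_false(acidosis_status(45, 7.30)$acidotic)   # strictly greater
  expect_false(acidosis_status(50, 7.35)$acidotic)   # strictly lower
  expect_true(is.na(acidosis_status(NA, 7.30)$acidotic))
  # thresholds are configurable
  expect_true(acidosis_status(48, 7.30, paco2_threshold = 45)$acidotic)
  expect_false(acidosis_status(48, 7.30, paco2_threshold = 50)$acidotic)
})

test_that("infeasible bounds give an empty candidate list", {
  cfg <- individualizer_config(dp_bounds = c(29, 30))
  out <- candidate_settings(ibw_kg = 70, peep = 8, compliance = 0.05,
                            objective = "min_MP",
                            current = list(tv_L = 0.5, rr = 18, dp = 10),
                            config = cfg)
  expect_equal(nrow(out), 0)
})

test_that("the grid contains the expected lung-protective combinations", {
  out <- candidate_settings(ibw_kg = 70, peep = 8, compliance = 0.035,
                            objective = "max_VE",
                            current = list(tv_L = 0.25, rr = 12, dp = 7.1),
                            config = individualizer_config())
  # 5 mL/kg x 70 kg = 0.35 L at RR 20 -> VE 7.0
  hit <- out[abs(out$tv_L - 0.35) < 1e-9 & out$rr == 20, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$ve, 7.0)
  expect_equal(hit$dp, 0.35 / 0.035)
  # acidotic ordering: VE descending, ties by lower MP then lower RR
  expect_true(all(diff(out$ve) <= 1e-9))
})

test_that("non-acidotic candidates start at the feasible-grid MP minimum", {
  cfg <- individualizer_config()
  current <- list(tv_L = 0.6, rr = 28, dp = 17)
  out <- candidate_settings(ibw_kg = 70, peep = 8, compliance = 0.035,
                            objective = "min_MP", current = current,
                            config = cfg)
  # brute-force oracle over the full enumerated grid
  grid <- expand.grid(tv_mlkg = cfg$tv_mlkg_grid, rr = cfg$rr_grid)
  grid$tv_L <- grid$tv_mlkg * 70 / 1000
  grid$dp <- grid$tv_L / 0.035
  grid <- grid[grid$dp >= cfg$dp_bounds[1] & grid$dp <= cfg$dp_bounds[2], ]
  grid$mp <- 0.098 * grid$tv_L * grid$rr * (8 + grid$dp)
  current_mp <- 0.098 * current$tv_L * current$rr * (8 + current$dp)
  grid <- grid[grid$mp <= current_mp, ]
  expect_equal(out$mp[1], min(grid$mp))
  expect_true(all(diff(out$mp) >= -1e-9))
  # every candidate respects the do-not-worsen MP constraint
  expect_true(all(out$mp <= current_mp + 1e-9))
})

test_that("a patient already predicted to survive is left alone", {
  row <- data.frame(admission_id = "p1", mp = 20, mp_ibw = 0.28,
                    tv_mlkg = 7, rr = 18, dp = 14, peep = 8, ve = 9,
                    paco2 = 40, ph = 7.4, ibw_kg = 70)
  out <- individualize(row, function(r) 0.1,
                       settings = list(tv_L = 0.5, rr = 18, dp = 14, peep = 8))
  expect_equal(out$initial_pred, "survival")
  expect_false(out$flipped)
  expect_equal(out$iterations, 1L)
  expect_equal(out$final, out$initial)
})

test_that("an unflippable patient keeps the initial settings", {
  row <- data.frame(mp = 25, mp_ibw = 0.36, tv_mlkg = 7, rr = 20, dp = 15,
                    peep = 8, paco2 = 40, ph = 7.4, ibw_kg = 70)
  out <- individualize(row, function(r) 0.99,
                       settings = list(tv_L = 0.5, rr = 20, dp = 15, peep = 8))
  expect_false(out$flipped)
  expect_equal(out$final_pred, "death")
  expect_equal(out$final$tv_L, 0.5)
  expect_equal(out$final$rr, 20)
})

test_that("a monotone MP-threshold model flips to the minimum-MP candidate", {
  # toy model: death iff MP > 15 J/min
  model <- function(r) as.numeric(r$mp > 15)
  settings <- list(tv_L = 0.56, rr = 24, dp = 16, peep = 8)
  row <- data.frame(mp = mechanical_power(0.56, 24, 8, 16),
                    mp_ibw = NA, tv_mlkg = 8, rr = 24, dp = 16, peep = 8,
                    paco2 = 40, ph = 7.4, ibw_kg = 70)
  row$mp_ibw <- row$mp / 70
  out <- individualize(row, model, settings, compliance = 0.035)
  expect_true(out$flipped)
  expect_equal(out$final_pred, "survival")
  # oracle: first (minimum-MP) feasible candidate with MP <= 15
  cands <- candidate_settings(70, 8, 0.035, "min_MP", settings)
  oracle <- cands[cands$mp <= 15, ][1, ]
  expect_equal(out$final$tv_L, oracle$tv_L)
  expect_equal(out$final$rr, oracle$rr)
  expect_equal(out$final$mp, oracle$mp)
  # candidates are walked best-first, so the flip lands on the grid minimum
  expect_equal(out$final$mp, min(cands$mp))
})

test_that("missing blood gas or model failure skips the patient with a note", {
  row <- data.frame(mp = 20, rr = 18, dp = 14, peep = 8,
                    paco2 = NA, ph = 7.3, ibw_kg = 70)
  out <- individualize(row, function(r) 0.9,
                       settings = list(tv_L = 0.5, rr = 18, dp = 14, peep = 8))
  expect_true(out$skipped)
  expect_equal(out$skip_reason, "acidosis state unknown")

  row2 <- row
  row2$paco2 <- 40
  out2 <- individualize(row2, function(r) stop("boom"),
                        settings = list(tv_L = 0.5, rr = 18, dp = 14, peep = 8))
  expect_true(out2$skipped)
  expect_equal(out2$skip_reason, "model prediction failure")
})

test_that("flipped outcomes obey the objective constraints", {
  set.seed(121)
  model <- function(r) as.numeric(r$mp > 16)
  n <- 60
  rows <- data.frame(
    admission_id = paste0("p", 1:n),
    tv_L = runif(n, 0.45, 0.65), rr = round(runif(n, 16, 30)),
    dp = runif(n, 12, 20), peep = round(runif(n, 5, 12)),
    paco2 = sample(c(40, 55), n, replace = TRUE),
    ph = sample(c(7.25, 7.45), n, replace = TRUE),
    ibw_kg = round(runif(n, 55, 85), 1))
  rows$mp <- mechanical_power(rows$tv_L, rows$rr, rows$peep, rows$dp)
  rows$mp_ibw <- rows$mp / rows$ibw_kg
  rows$tv_mlkg <- rows$tv_L * 1000 / rows$ibw_kg
  rows$ve <- rows$tv_L * rows$rr
  cfg <- individualizer_config()
  for (i in seq_len(n)) {
    row <- rows[i, , drop = FALSE]
    settings <- list(tv_L = row$tv_L, rr = row$rr, dp = row$dp,
                     peep = row$peep)
    out <- individualize(row, model, settings, cfg)
    if (isTRUE(out$skipped) || !out$flipped) next
    # flip soundness: re-prediction under the same frozen model is survival
    refit_row <- row
    refit_row$mp <- out$final$mp
    expect_lt(model(refit_row), cfg$cut)
    if (out$objective == "min_MP") {
      expect_lte(out$final$mp, out$initial$mp + 1e-9)
    } else {
      expect_gte(out$final$ve,
                 (out$initial$ve + cfg$ve_increment) * (1 - cfg$ve_tolerance))
    }
  }
})

test_that("case-study arithmetic matches hand values", {
  expect_equal(case_summary(614, 58)$percent, 9.4)
  expect_equal(case_summary(100, 0)$percent, 0)
  expect_equal(case_summary(40, 40)$percent, 100)
  expect_equal(case_summary(0, 0)$percent, 0)
  expect_error(case_summary(10, 11))
})

test_that("case_study counts initial nonsurvivors, flips and skips", {
  rows <- data.frame(
    admission_id = c("a", "b", "c"),
    tv_L = 0.56, rr = 24, dp = 16, peep = 8,
    paco2 = c(40, 40, NA), ph = 7.4, ibw_kg = 70)
  rows$mp <- mechanical_power(rows$tv_L, rows$rr, rows$peep, rows$dp)
  rows$mp_ibw <- rows$mp / 70
  rows$tv_mlkg <- rows$tv_L * 1000 / 70
  # patient a flippable (MP threshold), b unflippable, c skipped
  model <- function(r) {
    if (r$admission_id == "b") return(0.99)
    as.numeric(r$mp > 15)
  }
  out <- case_study(rows, model)
  expect_equal(out$n_initial, 2)
  expect_equal(out$n_flipped, 1)
  expect_equal(out$n_skipped, 1)
  expect_equal(out$percent, 50)
})
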