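#' Apply cohort inclusion criteria
#'
#' Retains adult admissions (age >= 18) that received at least `min_mv_hours`
#' of pressure-controlled ventilation and have a known ICU mortality outcome.
#' Admissions that died or were extubated before the minimum ventilation time
#' fail the duration rule. An exclusion tally, the flow-chart surrogate, is
#' attached as the `"exclusions"` attribute.
#'
#' @param admissions Admission table; must contain `admission_id`,
#'   `age_years`, `mv_duration_h`, `icu_mortality`.
#' @param min_age Minimum age in years (default 18).
#' @param min_mv_hours Minimum ventilation duration in hours (default 48).
#' @return The filtered admission table, with attribute `exclusions`: a named
#'   list of per-rule exclusion counts (`age_below_minimum`,
#'   `mv_shorter_than_minimum`, `outcome_unknown`, `screened`, `retained`).
#'   Rules are assessed independently on the full input, so one admission can
#'   count against several rules.
#' @export
apply_inclusion <- function(admissions, min_age = 18, min_mv_hours = 48) {
  required <- c("admission_id", "age_years", "mv_duration_h", "icu_mortality")
  missing_cols <- setdiff(required, names(admissions))
  if (length(missing_cols) > 0) {
    stop("admissions table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ok_age <- !is.na(admissions$age_years) & admissions$age_years >= min_age
  ok_mv <- !is.na(admissions$mv_duration_h) & admissions$mv_duration_h >= min_mv_hours
  ok_outcome <- !is.na(admissions$icu_mortality)
  keep <- ok_age & ok_mv & ok_outcome
  out <- admissions[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- list(
    screened = nrow(admissions),
    age_below_minimum = sum(!ok_age),
    mv_shorter_than_minimum = sum(!ok_mv),
    outcome_unknown = sum(!ok_outcome),
    retained = nrow(out)
  )
  out
}

#' Default plausibility bounds for ventilation samples
#'
#' Named list of `c(lower, upper)` bounds per variable. Values outside the
#' bounds are treated as charting errors, not physiology.
#'
#' @return Named list of 2-vectors.
#' @export
default_plausibility_bounds <- function() {
  list(
    tv_L = c(0.05, 1.5),
    rr = c(4, 60),
    peep = c(0, 30),
    dp = c(1, 60),
    ti_s = c(0.2, 5),
    fio2 = c(0.21, 1.0),
    pao2 = c(20, 600),
    paco2 = c(10, 200),
    ph = c(6.5, 7.9)
  )
}

#' Remove implausible and duplicate ventilation samples
#'
#' Drops exact duplicate rows (keeping the first) and any sample whose value
#' falls outside the per-variable plausibility bounds. `NA` values are not
#' judged against bounds. Every removal is logged with its reason.
#'
#' @param vent_series Wide sample table (`admission_id`, `t_min`, variables).
#' @param bounds Named list of `c(lower, upper)` per variable; defaults to
#'   [default_plausibility_bounds()].
#' @return The cleaned table, with attribute `removal_log`: a data frame of
#'   (`admission_id`, `t_min`, `reason`) rows.
#' @export
plausibility_clean <- function(vent_series, bounds = default_plausibility_bounds()) {
  log_rows <- list()
  dup <- duplicated(vent_series)
  if (any(dup)) {
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      admission_id = vent_series$admission_id[dup],
      t_min = vent_series$t_min[dup],
      reason = "duplicate_row", stringsAsFactors = FALSE)
  }
  out <- vent_series[!dup, , drop = FALSE]

  bad <- rep(FALSE, nrow(out))
  reason <- rep(NA_character_, nrow(out))
  for (v in intersect(names(bounds), names(out))) {
    x <- out[[v]]
    viol <- !is.na(x) & (x < bounds[[v]][1] | x > bounds[[v]][2])
    newly <- viol & !bad
    reason[newly] <- paste0("out_of_bounds:", v)
    bad <- bad | viol
  }
  if (any(bad)) {
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      admission_id = out$admission_id[bad], t_min = out$t_min[bad],
      reason = reason[bad], stringsAsFactors = FALSE)
  }
  cleaned <- out[!bad, , drop = FALSE]
  rownames(cleaned) <- NULL
  attr(cleaned, "removal_log") <- if (length(log_rows) > 0) {
    do.call(rbind, log_rows)
  } else {
    data.frame(admission_id = character(0), t_min = numeric(0),
               reason = character(0), stringsAsFactors = FALSE)
  }
  cleaned
}

#' k-nearest-neighbour imputation of a numeric feature table
#'
#' Features with more than `max_missing_frac` missing values are dropped (and
#' named in the report) rather than imputed. Each remaining missing cell is
#' filled with the mean of that feature over the `k` nearest rows, where
#' distance is the root-mean-square difference over mutually observed,
#' z-score-standardised features; candidate neighbours must have the target
#' feature observed. Observed cells are never altered. If fewer than `k`
#' candidate rows exist the column mean is used and the cell is flagged.
#'
#' @param feature_table Data frame; only numeric columns are imputed.
#' @param k Number of neighbours (default 7).
#' @param max_missing_frac Maximum tolerated missing fraction per feature
#'   (default 0.10).
#' @return The completed table (dropped features removed), with attribute
#'   `impute_report`: list with `dropped_features`, `n_imputed`,
#'   `fallback_cells` (data frame of row/feature pairs that used the column
#'   mean).
#' @export
knn_impute <- function(feature_table, k = 7, max_missing_frac = 0.10) {
  stopifnot(k >= 1)
  num_cols <- names(feature_table)[vapply(feature_table, is.numeric, logical(1))]
  miss_frac <- vapply(num_cols, function(cl) mean(is.na(feature_table[[cl]])),
                      numeric(1))
  dropped <- num_cols[miss_frac > max_missing_frac]
  out <- feature_table[, setdiff(names(feature_table), dropped), drop = FALSE]
  num_cols <- setdiff(num_cols, dropped)

  X <- as.matrix(out[, num_cols, drop = FALSE])
  mu <- colMeans(X, na.rm = TRUE)
  sg <- apply(X, 2, stats::sd, na.rm = TRUE)
  sg[!is.finite(sg) | sg == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sg, "/")

  n_imputed <- 0L
  fallback <- list()
  for (j in seq_along(num_cols)) {
    miss_rows <- which(is.na(X[, j]))
    if (length(miss_rows) == 0) next
    cand <- which(!is.na(X[, j]))
    for (i in miss_rows) {
      if (length(cand) == 0) {
        next  # feature entirely missing yet under threshold only if n tiny
      }
      if (length(cand) < k) {
        X[i, j] <- mean(X[cand, j])
        fallback[[length(fallback) + 1L]] <- data.frame(
          row = i, feature = num_cols[j], stringsAsFactors = FALSE)
      } else {
        d <- row_distances(Z, i, cand)
        nn <- cand[order(d, cand)[seq_len(k)]]
        X[i, j] <- mean(X[nn, j])
      }
      n_imputed <- n_imputed + 1L
    }
  }
  out[num_cols] <- as.data.frame(X)
  attr(out, "impute_report") <- list(
    dropped_features = dropped,
    n_imputed = n_imputed,
    fallback_cells = if (length(fallback) > 0) do.call(rbind, fallback) else
      data.frame(row = integer(0), feature = character(0))
  )
  out
}

# RMS distance between row i and each candidate row over mutually observed
# standardized features; rows sharing no feature get +Inf.
row_distances <- function(Z, i, cand) {
  zi <- Z[i, ]
  vapply(cand, function(r) {
    shared <- !is.na(zi) & !is.na(Z[r, ])
    if (!any(shared)) return(Inf)
    sqrt(mean((zi[shared] - Z[r, shared])^2))
  }, numeric(1))
}

#' Assign hypoxemia strata from early oxygenation
#'
#' Classifies each admission by its PaO2/FiO2 ratio (PFR) over the first six
#' hours of ventilation: > 300 nonhypoxemic, 200-300 mild, [100, 200)
#' moderate, < 100 severe. The window summary is the time-weighted mean PFR
#' by default; `summary = "worst"` uses the window minimum instead.
#'
#' @param vent_series Sample table with `admission_id`, `t_min`, `pao2`,
#'   `fio2`.
#' @param admissions Admission table (`admission_id`).
#' @param window_h Stratification window in hours (default 6).
#' @param summary `"twa"` (default) or `"worst"`.
#' @return Data frame (`admission_id`, `pfr_summary`, `hypoxemia_group`);
#'   admissions with no PaO2/FiO2 pair in the window get `NA` group and are
#'   listed in the `unclassifiable` attribute.
#' @export
assign_hypoxemia <- function(vent_series, admissions, window_h = 6,
                             summary = c("twa", "worst")) {
  summary <- match.arg(summary)
  stopifnot(all(c("admission_id", "t_min", "pao2", "fio2") %in% names(vent_series)))
  ids <- admissions$admission_id
  res <- vapply(ids, function(id) {
    s <- vent_series[vent_series$admission_id == id, , drop = FALSE]
    pfr <- s$pao2 / s$fio2
    ok <- !is.na(pfr) & s$t_min >= 0 & s$t_min < window_h * 60
    if (!any(ok)) return(NA_real_)
    if (summary == "twa") {
      twa(s$t_min, pfr, window_h * 60)
    } else {
      min(pfr[ok])
    }
  }, numeric(1))
  group <- classify_pfr(res)
  out <- data.frame(admission_id = ids, pfr_summary = res,
                    hypoxemia_group = group, stringsAsFactors = FALSE)
  attr(out, "unclassifiable") <- ids[is.na(res)]
  out
}

#' Map PFR values to hypoxemia strata
#'
#' @param pfr PaO2/FiO2 ratios (mmHg).
#' @return Character vector over `nonhypoxemic`, `mild`, `moderate`, `severe`
#'   (boundaries: 300 and 200 belong to mild, 100 to moderate).
#' @export
classify_pfr <- function(pfr) {
  ifelse(is.na(pfr), NA_character_,
    ifelse(pfr > 300, "nonhypoxemic",
      ifelse(pfr >= 200, "mild",
        ifelse(pfr >= 100, "moderate", "severe"))))
}
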