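# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# One-sided exact Mann-Whitney p-value P(rank-sum of x >= observed) by full
# enumeration of all label arrangements of the pooled sample (no ties).
exact_rank_p_greater <- function(x, y) {
  pool <- c(x, y)
  nx <- length(x)
  ranks <- rank(pool)
  obs <- sum(ranks[seq_len(nx)])
  sets <- utils::combn(length(pool), nx)
  stats <- apply(sets, 2, function(idx) sum(ranks[idx]))
  mean(stats >= obs)
}

# Two-sided exact Mann-Whitney p-value by enumeration (doubled tail, capped).
exact_rank_p_twosided <- function(x, y) {
  pool <- c(x, y)
  nx <- length(x)
  ranks <- rank(pool)
  obs <- sum(ranks[seq_len(nx)])
  sets <- utils::combn(length(pool), nx)
  stats <- apply(sets, 2, function(idx) sum(ranks[idx]))
  min(1, 2 * min(mean(stats >= obs), mean(stats <= obs)))
}

# Sample-and-hold integral oracle: explicit segment-by-segment arithmetic.
hand_twa <- function(t, v, window) {
  bounds <- c(t, window)
  sum(diff(bounds) * v) / (window - t[1])
}

# Small piecewise-constant ventilation series for one admission.
make_series <- function(id = "a1", t_min, tv_L = 0.5, rr = 15, peep = 5,
                        dp = 15, ti_s = 1.0, fio2 = 0.4, pao2 = 100,
                        paco2 = 40, ph = 7.4) {
  n <- length(t_min)
  data.frame(admission_id = id, t_min = t_min,
             tv_L = rep_len(tv_L, n), rr = rep_len(rr, n),
             peep = rep_len(peep, n), dp = rep_len(dp, n),
             ti_s = rep_len(ti_s, n), fio2 = rep_len(fio2, n),
             pao2 = rep_len(pao2, n), paco2 = rep_len(paco2, n),
             ph = rep_len(ph, n), stringsAsFactors = FALSE)
}

make_admission <- function(id = "a1", height_cm = 175, sex = "male",
                           age = 60, mv_h = 72, dead = 0L) {
  data.frame(admission_id = id, age_years = age, sex = sex,
             height_cm = height_cm, weight_kg = 80, mv_duration_h = mv_h,
             icu_mortality = dead, stringsAsFactors = FALSE)
}

# A small ready-made synthetic cohort shared by slower tests.
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(synth_config(
        n_admissions = 250, seed = 301, sampling_interval_min = 120,
        horizon_hours = 48, missing_rate = 0))
    }
    cache
  }
})
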