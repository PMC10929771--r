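# Deterministic expected-value cohort recursion for a homogeneous stratum.
# Independent of the microsimulation engine: it evolves the exact occupancy
# distribution over (cascade state, complication occupancy) using the same
# event hierarchy, so the engine's empirical occupancies must match it within
# Monte Carlo error. Used as the oracle for the engine tests.

# States tracked: cascade 1..6 crossed with complication occupancy
# (0 = none, 7..16 = occupying that complication this cycle), plus the two
# death states. Returns a cycles x 18 matrix of expected occupancy fractions
# on the same accounting convention as run_strategy()$occupancy (state during
# the cycle; deaths recorded in their death state from the death cycle on).
oracle_occupancy <- function(age0, sex, quintile, state0_probs, strategy,
                             params) {
  H <- params$horizon_years
  arr_sex <- if (sex == "female") 1L else 2L
  strata <- params$strata
  rate_at <- function(col, age) {
    band <- pmin(pmax((age - 25L) %/% 5L, 0L), 14L) * 5L + 25L
    row <- strata[
      strata$age_lo == band & strata$sex == sex &
        strata$quintile == quintile,
    ]
    row[[col]]
  }
  elig <- quintile %in% strategy$eligible_quintiles
  pick_or <- function(x) {
    if (is.null(x) || is.na(x)) params$effect$odds_ratio else x
  }
  or_d <- pick_or(params$effect$or_diagnosis)
  or_t <- pick_or(params$effect$or_treatment)
  odds_boost <- function(p, or) (p * or) / (1 - p + p * or)
  p_dx <- params$cascade$p_dx
  if (strategy$covers_diagnosis && elig) p_dx <- odds_boost(p_dx, or_d)
  p_dt <- params$cascade$p_dt
  p_re <- params$cascade$p_reinit
  p_tna <- params$cascade$p_tna
  if (strategy$covers_treatment && elig) {
    p_tna <- 1 - odds_boost(1 - params$cascade$p_tna, or_t)
    if (isTRUE(params$treatment_boosts_initiation)) {
      p_dt <- odds_boost(p_dt, or_t)
      p_re <- odds_boost(p_re, or_t)
    }
  }
  split <- params$therapy_split
  comp <- params$complications
  n_comp <- nrow(comp)

  # mass[c, m+1]: cascade c (1..6), m = 0 or complication index 1..10
  mass <- matrix(0, 6, n_comp + 1)
  mass[, 1] <- state0_probs
  dead_dm <- 0
  dead_other <- 0
  occ <- matrix(0, H, 18, dimnames = list(NULL, health_states()))

  for (t in seq_len(H) - 1L) {
    age <- age0 + t
    p_bg <- rate_at("bg_mortality", age)
    p_dmm_raw <- rate_at("dm_mortality", age)
    p_inc <- rate_at("dm_incidence", age)
    new_mass <- matrix(0, 6, n_comp + 1)
    for (c in 1:6) {
      p_dmm <- if (c >= 2) {
        p_dmm_raw * if (c >= 4) params$cascade$therapy_effect_mortality else 1
      } else {
        0
      }
      p_die <- p_bg + (1 - p_bg) * p_dmm
      for (m in 0:n_comp) {
        w <- mass[c, m + 1]
        if (w == 0) next
        dead_other <- dead_other + w * p_bg
        dead_dm <- dead_dm + w * (1 - p_bg) * p_dmm
        ws <- w * (1 - p_die)
        occ_state <- if (m > 0) 6L + m else c
        occ[t + 1, occ_state] <- occ[t + 1, occ_state] + ws
        if (m > 0) {
          # return to prior cascade state, no other events
          new_mass[c, 1] <- new_mass[c, 1] + ws
          next
        }
        # cascade transition distribution over c'
        cdist <- numeric(6)
        if (c == 1) {
          cdist[1] <- 1 - p_inc
          cdist[2] <- p_inc
        } else if (c == 2) {
          cdist[2] <- 1 - p_dx
          cdist[3] <- p_dx * (1 - p_dt)
          cdist[4:6] <- p_dx * p_dt * split
        } else if (c == 3) {
          cdist[3] <- 1 - p_re
          cdist[4:6] <- p_re * split
        } else {
          cdist[c] <- 1 - p_tna
          cdist[3] <- p_tna
        }
        # complication draw (risk set: diabetic at cycle start, m == 0)
        if (c >= 2) {
          eff <- if (c >= 4) comp$therapy_effect else rep(1, n_comp)
          pj <- comp$untreated_incidence * eff
          p_none <- 1 - sum(pj)
          for (cp in 1:6) {
            if (cdist[cp] == 0) next
            new_mass[cp, 1] <- new_mass[cp, 1] + ws * cdist[cp] * p_none
            new_mass[cp, 2:(n_comp + 1)] <-
              new_mass[cp, 2:(n_comp + 1)] + ws * cdist[cp] * pj
          }
        } else {
          new_mass[, 1] <- new_mass[, 1] + ws * cdist
        }
      }
    }
    occ[t + 1, 17] <- dead_dm
    occ[t + 1, 18] <- dead_other
    mass <- new_mass
  }
  occ
}
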