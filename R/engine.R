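# The annual-cycle microsimulation engine. Each alive individual resolves, in
# a fixed hierarchical order: other-cause death, diabetes death, diabetes
# onset, diagnosis, treatment initiation (or re-initiation), non-adherence,
# then a single complication draw. Earlier events pre-empt later ones, so the
# realised per-cycle event distribution is a valid categorical distribution.
# All random draws come from per-(cycle, decision) streams derived from one
# seed, giving common random numbers across strategy arms run on the same
# cohort and seed.

#' Define a CCT programme strategy
#'
#' @param covers_diagnosis Does the transfer cover screening/diagnosis visits?
#' @param covers_treatment Does the transfer cover treatment attendance?
#' @param eligible_quintiles Income quintiles eligible for transfers.
#' @param name Optional label; a descriptive one is built if omitted.
#' @return An `ecea_strategy` list.
#' @export
strategy <- function(covers_diagnosis = FALSE, covers_treatment = FALSE,
                     eligible_quintiles = 1L, name = NULL) {
  if (!all(eligible_quintiles %in% 1:5)) {
    abort("`eligible_quintiles` must be a subset of 1:5")
  }
  name <- name %||% {
    svc <- c(
      if (covers_diagnosis) "diagnosis",
      if (covers_treatment) "treatment"
    )
    if (length(svc) == 0) "no_programme" else paste(svc, collapse = "_")
  }
  structure(
    list(
      covers_diagnosis = isTRUE(covers_diagnosis),
      covers_treatment = isTRUE(covers_treatment),
      eligible_quintiles = sort(unique(as.integer(eligible_quintiles))),
      name = name
    ),
    class = "ecea_strategy"
  )
}

#' The four study arms
#'
#' @param eligible_quintiles Quintiles eligible for transfers (study scenarios:
#'   `1` or `1:2`).
#' @return Named list of [strategy()] objects: `no_programme`,
#'   `diagnosis_only`, `treatment_only`, `diagnosis_treatment`.
#' @export
cct_strategies <- function(eligible_quintiles = 1:2) {
  list(
    no_programme = strategy(FALSE, FALSE, eligible_quintiles, "no_programme"),
    diagnosis_only = strategy(TRUE, FALSE, eligible_quintiles, "diagnosis_only"),
    treatment_only = strategy(FALSE, TRUE, eligible_quintiles, "treatment_only"),
    diagnosis_treatment = strategy(
      TRUE, TRUE, eligible_quintiles,
      "diagnosis_treatment"
    )
  )
}

#' Apply an odds ratio to a probability
#'
#' Converts `p` to odds, multiplies by `or`, and back-transforms:
#' `(p * or) / (1 - p + p * or)`. Monotone increasing in `or`; returns `p`
#' unchanged when `or = 1` and preserves 0 and 1.
#'
#' @param p Probability (vectorised), in \[0, 1\].
#' @param or Odds ratio, > 0.
#' @return Adjusted probability in \[0, 1\].
#' @export
apply_odds_ratio <- function(p, or) {
  if (any(p < 0 | p > 1)) abort("`p` must lie in [0, 1]")
  if (any(or <= 0)) abort("`or` must be > 0")
  (p * or) / (1 - p + p * or)
}

effective_ors <- function(params) {
  pick <- function(x) {
    if (is.null(x) || is.na(x)) params$effect$odds_ratio else x
  }
  list(
    diagnosis = pick(params$effect$or_diagnosis),
    treatment = pick(params$effect$or_treatment)
  )
}

# Shared per-individual transition components (also the public
# build_transitions surface). `cascade` is the integer cascade code 1..6.
transition_components <- function(arr, age, sex_i, quintile, cascade, elig,
                                  strategy, params) {
  pos <- strata_pos(arr, age, sex_i, quintile)
  p_bg <- arr$bg_mortality[pos]
  if (anyNA(p_bg)) {
    bad <- which(is.na(p_bg))[1]
    abort(sprintf(
      "Missing strata cell for (age=%d, sex=%s, quintile=%d)",
      age[bad], c("female", "male")[sex_i[bad]], quintile[bad]
    ))
  }
  ors <- effective_ors(params)
  on_therapy <- cascade >= 4L
  p_dmm <- arr$dm_mortality[pos] *
    ifelse(on_therapy, params$cascade$therapy_effect_mortality, 1)
  p_dx_boost <- apply_odds_ratio(params$cascade$p_dx, ors$diagnosis)
  p_dx_i <- if (strategy$covers_diagnosis) {
    ifelse(elig, p_dx_boost, params$cascade$p_dx)
  } else {
    rep(params$cascade$p_dx, length(age))
  }
  p_sc <- params$cascade$p_screen %||% params$cascade$p_dx
  p_screen_i <- if (strategy$covers_diagnosis) {
    ifelse(elig, apply_odds_ratio(p_sc, ors$diagnosis), p_sc)
  } else {
    rep(p_sc, length(age))
  }
  adh_boost <- apply_odds_ratio(1 - params$cascade$p_tna, ors$treatment)
  p_tna_i <- if (strategy$covers_treatment) {
    ifelse(elig, 1 - adh_boost, params$cascade$p_tna)
  } else {
    rep(params$cascade$p_tna, length(age))
  }
  p_dt_i <- rep(params$cascade$p_dt, length(age))
  p_reinit_i <- rep(params$cascade$p_reinit, length(age))
  if (strategy$covers_treatment &&
    isTRUE(params$treatment_boosts_initiation)) {
    p_dt_i[elig] <- apply_odds_ratio(params$cascade$p_dt, ors$treatment)
    p_reinit_i[elig] <-
      apply_odds_ratio(params$cascade$p_reinit, ors$treatment)
  }
  list(
    pos = pos,
    p_other_death = p_bg,
    p_dm_death = p_dmm,
    p_dm_incidence = arr$dm_incidence[pos],
    p_diagnosis = p_dx_i,
    p_screening = p_screen_i,
    p_initiate = p_dt_i,
    p_reinitiate = p_reinit_i,
    p_nonadherence = p_tna_i,
    on_therapy = on_therapy
  )
}

#' Per-individual annual transition probabilities
#'
#' Returns the probability bundle the engine uses for one cycle: competing
#' mortality risks, diabetes onset, (possibly transfer-boosted) diagnosis and
#' adherence probabilities, and per-complication event probabilities with the
#' therapy effect applied for individuals on pharmacological treatment.
#' Transfer effects are applied on the odds scale: diagnosis coverage boosts
#' the odds of `p_dx`; treatment coverage boosts the odds of adherence
#' `1 - p_tna`. Probabilities that cannot apply to an individual's state
#' (e.g. onset for a diabetic) are returned as `NA`.
#'
#' @param cohort Cohort tibble from [generate_population()] (columns `age`,
#'   `sex`, `quintile`, `state`).
#' @param strategy An [strategy()] object.
#' @param params An `ecea_params` list with strata tables.
#' @return Tibble, one row per individual.
#' @export
build_transitions <- function(cohort, strategy, params) {
  arr <- strata_arrays(params$strata)
  cascade <- match(cohort$state, health_states())
  if (any(cascade > 6L)) {
    abort("`cohort$state` must contain cascade states only")
  }
  sex_i <- ifelse(cohort$sex == "female", 1L, 2L)
  elig <- cohort$quintile %in% strategy$eligible_quintiles
  tc <- transition_components(
    arr, cohort$age, sex_i, cohort$quintile, cascade, elig, strategy, params
  )
  diabetic <- cascade >= 2L
  out <- tibble(
    id = cohort$id,
    p_other_death = tc$p_other_death,
    p_dm_death = ifelse(diabetic, tc$p_dm_death, NA_real_),
    p_dm_incidence = ifelse(!diabetic, tc$p_dm_incidence, NA_real_),
    p_diagnosis = ifelse(cascade == 2L, tc$p_diagnosis, NA_real_),
    p_screening = ifelse(cascade == 1L, tc$p_screening, NA_real_),
    p_initiate_treatment = dplyr::case_when(
      cascade == 2L ~ tc$p_initiate,
      cascade == 3L ~ tc$p_reinitiate,
      .default = NA_real_
    ),
    p_nonadherence = ifelse(cascade >= 4L, tc$p_nonadherence, NA_real_)
  )
  comp <- params$complications
  for (j in seq_len(nrow(comp))) {
    pj <- comp$untreated_incidence[j] *
      ifelse(tc$on_therapy, comp$therapy_effect[j], 1)
    out[[paste0("p_", tolower(comp$state[j]))]] <-
      ifelse(diabetic, pj, NA_real_)
  }
  out
}

# ---- engine state -----------------------------------------------------------

#' Initialise engine state for a cohort and strategy
#'
#' Mostly useful for tests and instrumentation; [run_strategy()] drives the
#' same machinery over the whole horizon.
#'
#' @inheritParams build_transitions
#' @param sim_seed Seed for the per-cycle random streams (defaults to the
#'   cohort's generation seed). Runs of different strategies with the same
#'   cohort and `sim_seed` share random numbers (common random numbers).
#' @return An environment of class `ecea_engine`.
#' @export
engine_state <- function(cohort, strategy, params,
                         sim_seed = attr(cohort, "seed")) {
  if (is.null(sim_seed)) abort("`sim_seed` is required")
  cascade <- match(cohort$state, health_states())
  if (anyNA(cascade) || any(cascade > 6L)) {
    abort("`cohort$state` must contain cascade states only")
  }
  E <- new.env(parent = emptyenv())
  E$n <- nrow(cohort)
  E$id <- cohort$id
  E$age <- as.integer(cohort$age)
  E$sex <- cohort$sex
  E$sex_i <- ifelse(cohort$sex == "female", 1L, 2L)
  E$q <- as.integer(cohort$quintile)
  E$income <- cohort$income
  E$cascade <- as.integer(cascade)
  E$comp <- integer(E$n)
  E$alive <- rep(TRUE, E$n)
  E$dead_state <- integer(E$n)
  E$died_cycle <- rep(NA_integer_, E$n)
  E$elig <- E$q %in% strategy$eligible_quintiles
  E$strategy <- strategy
  E$params <- params
  E$arr <- strata_arrays(params$strata)
  E$seed <- as.integer(sim_seed)
  ors <- effective_ors(params)
  E$rr_mort <- params$cascade$therapy_effect_mortality
  p_dx <- params$cascade$p_dx
  E$p_dx_i <- rep(p_dx, E$n)
  p_sc <- params$cascade$p_screen %||% p_dx
  E$p_screen_i <- rep(p_sc, E$n)
  if (strategy$covers_diagnosis) {
    E$p_dx_i[E$elig] <- apply_odds_ratio(p_dx, ors$diagnosis)
    E$p_screen_i[E$elig] <- apply_odds_ratio(p_sc, ors$diagnosis)
  }
  p_tna <- params$cascade$p_tna
  E$p_tna_i <- rep(p_tna, E$n)
  E$p_dt_i <- rep(params$cascade$p_dt, E$n)
  E$p_reinit_i <- rep(params$cascade$p_reinit, E$n)
  if (strategy$covers_treatment) {
    E$p_tna_i[E$elig] <- 1 - apply_odds_ratio(1 - p_tna, ors$treatment)
    if (isTRUE(params$treatment_boosts_initiation)) {
      E$p_dt_i[E$elig] <- apply_odds_ratio(params$cascade$p_dt, ors$treatment)
      E$p_reinit_i[E$elig] <-
        apply_odds_ratio(params$cascade$p_reinit, ors$treatment)
    }
  }
  E$cum_therapy <- cumsum(params$therapy_split)[1:2]
  E$comp_inc <- params$complications$untreated_incidence
  E$comp_eff <- params$complications$therapy_effect
  E$admin <- params$econ$admin_cost_fraction
  E$H <- as.integer(params$horizon_years)
  E$df <- discount_factor(0:(E$H - 1), params$econ$discount_rate)
  E$df_daly <- if (isTRUE(params$discount_dalys)) E$df else rep(1, E$H)
  E$cumrem_daly <- rev(cumsum(rev(E$df_daly)))
  st <- params$states
  E$cost_state <- st$direct_cost
  E$oop_state <- st$oop_cost
  E$dw_state <- st$disability_weight
  E$capacity <- pmax(
    E$income - params$econ$food_poverty_line,
    params$econ$capacity_floor
  )
  E$thresholds <- params$econ$che_thresholds
  E$hs_cost <- numeric(E$n)
  E$oop_disc <- numeric(E$n)
  E$oop_undisc <- numeric(E$n)
  E$oop_net_undisc <- numeric(E$n)
  E$oop_net_disc <- numeric(E$n)
  E$cct_disc <- numeric(E$n)
  E$cct_undisc <- numeric(E$n)
  E$dalys <- numeric(E$n)
  E$treated_years_disc <- numeric(E$n)
  E$treated_years <- numeric(E$n)
  E$n_complications <- integer(E$n)
  E$che <- matrix(0L, E$n, length(E$thresholds))
  E$occupancy <- matrix(
    0L, E$H, length(health_states()),
    dimnames = list(NULL, health_states())
  )
  E$events_mat <- matrix(
    0, E$H, 11L,
    dimnames = list(NULL, c(
      "cycle", "deaths_other", "deaths_dm", "onsets", "diagnoses",
      "screening_visits", "initiations", "reinitiations", "nonadherence",
      "complications", "cct_disbursed"
    ))
  )
  E$cycle <- 0L
  class(E) <- "ecea_engine"
  E
}

#' Advance the engine by one annual cycle
#'
#' Resolves, in order, for each alive individual: other-cause death, diabetes
#' death, diabetes onset, diagnosis (with transfer), treatment initiation or
#' re-initiation, non-adherence, then at most one complication event (first
#' drawn in the fixed complication order wins). Complication occupants spend
#' exactly one cycle in the complication state and then return to their prior
#' cascade position; no other cascade event fires for them in the interrupted
#' cycle. Deaths accrue a disability weight of one for the death cycle and all
#' remaining horizon cycles (discounted years of life lost); dead individuals
#' accrue nothing further.
#'
#' The probabilities applied are exactly those reported by
#' [build_transitions()] for the current cohort state.
#'
#' @param E An `ecea_engine` environment from [engine_state()]. Modified in
#'   place (environment semantics) and returned invisibly.
#' @return `E`, with `E$last_events` holding the cycle's event counts.
#' @export
step_cycle <- function(E) {
  t <- E$cycle
  if (t >= E$H) abort("Horizon already reached")
  n <- E$n
  us <- withr::with_preserve_seed(
    lapply(1:8, function(k) cycle_uniforms(E$seed, t, k, n))
  )
  u1 <- us[[1]]
  u2 <- us[[2]]
  u3 <- us[[3]]
  u4 <- us[[4]]
  u5 <- us[[5]]
  u6 <- us[[6]]
  u7 <- us[[7]]
  u8 <- us[[8]]

  alive0 <- E$alive
  arr <- E$arr
  pos <- strata_pos(arr, E$age, E$sex_i, E$q)
  p_bg <- arr$bg_mortality[pos]
  if (anyNA(p_bg[alive0])) {
    bad <- which(alive0 & is.na(p_bg))[1]
    abort(sprintf(
      "Missing strata cell for (age=%d, sex=%s, quintile=%d)",
      E$age[bad], c("female", "male")[E$sex_i[bad]], E$q[bad]
    ))
  }

  die_o <- alive0 & (u1 < p_bg)
  diabetic <- E$cascade >= 2L
  on_th <- E$cascade >= 4L
  p_dmm <- arr$dm_mortality[pos] * (1 + (E$rr_mort - 1) * on_th)
  die_d <- alive0 & !die_o & diabetic & (u2 < p_dmm)
  died <- die_o | die_d
  if (any(died)) {
    E$dalys[died] <- E$dalys[died] + E$cumrem_daly[t + 1L]
    E$alive[died] <- FALSE
    E$died_cycle[died] <- t
    E$dead_state[die_d] <- STATE[["DiabetesDeath"]]
    E$dead_state[die_o] <- STATE[["OtherDeath"]]
  }
  surv <- alive0 & !died

  occ <- E$cascade
  has_comp <- E$comp > 0L
  occ[has_comp] <- E$comp[has_comp]
  dfc <- E$df[t + 1L]
  dfd <- E$df_daly[t + 1L]
  E$hs_cost[surv] <- E$hs_cost[surv] + E$cost_state[occ[surv]] * dfc
  oop_now <- numeric(n)
  oop_now[surv] <- E$oop_state[occ[surv]]
  E$oop_disc <- E$oop_disc + oop_now * dfc
  E$oop_undisc <- E$oop_undisc + oop_now
  E$dalys[surv] <- E$dalys[surv] + E$dw_state[occ[surv]] * dfd
  occ_treated <- surv & occ >= 4L & occ <= 6L
  E$treated_years_disc[occ_treated] <- E$treated_years_disc[occ_treated] + dfc
  E$treated_years[occ_treated] <- E$treated_years[occ_treated] + 1

  casc0 <- E$cascade
  incomp <- surv & has_comp
  E$comp[incomp] <- 0L
  free <- surv & !incomp

  healthy <- free & casc0 == 1L
  onset <- healthy & (u3 < arr$dm_incidence[pos])
  E$cascade[onset] <- STATE[["UndiagnosedDM"]]

  undiag <- free & casc0 == 2L
  dx <- undiag & (u4 < E$p_dx_i)
  screen <- if (E$strategy$covers_diagnosis && isTRUE(E$params$screening_transfers)) {
    healthy & (u4 < E$p_screen_i)
  } else {
    rep(FALSE, n)
  }

  init <- dx & (u5 < E$p_dt_i)
  E$cascade[dx & !init] <- STATE[["DiagnosedUntreated"]]
  th_assign <- 4L + findInterval(u6, E$cum_therapy)
  E$cascade[init] <- th_assign[init]

  du <- free & casc0 == 3L
  reinit <- du & (u5 < E$p_reinit_i)
  E$cascade[reinit] <- th_assign[reinit]

  treated0 <- free & casc0 >= 4L
  nonadh <- treated0 & (u7 < E$p_tna_i)
  E$cascade[nonadh] <- STATE[["DiagnosedUntreated"]]

  cct_now <- disburse_cct(
    E$strategy, E$params,
    quintile = E$q, diagnosis_visit = dx, screening_visit = screen,
    treated_year = treated0
  )
  E$cct_disc <- E$cct_disc + cct_now * dfc
  E$cct_undisc <- E$cct_undisc + cct_now
  E$hs_cost <- E$hs_cost + cct_now * (1 + E$admin) * dfc

  atrisk <- free & casc0 >= 2L
  on_th0 <- casc0 >= 4L
  cum <- numeric(n)
  newcomp <- integer(n)
  for (j in seq_along(E$comp_inc)) {
    pj <- E$comp_inc[j] * (1 + (E$comp_eff[j] - 1) * on_th0)
    hit <- atrisk & newcomp == 0L & (u8 < cum + pj)
    newcomp[hit] <- 6L + j
    cum <- cum + pj
  }
  got_comp <- atrisk & newcomp > 0L
  E$comp[got_comp] <- newcomp[got_comp]
  E$n_complications[got_comp] <- E$n_complications[got_comp] + 1L

  oop_che <- if (isTRUE(E$params$net_cct_from_oop)) {
    pmax(oop_now - cct_now, 0)
  } else {
    oop_now
  }
  E$oop_net_undisc <- E$oop_net_undisc + oop_che
  E$oop_net_disc <- E$oop_net_disc + oop_che * dfc
  for (k in seq_along(E$thresholds)) {
    in_che <- surv & (oop_che > E$thresholds[k] * E$capacity)
    E$che[, k] <- E$che[, k] + as.integer(in_che)
  }

  state_now <- occ
  state_now[!E$alive] <- E$dead_state[!E$alive]
  E$occupancy[t + 1L, ] <- tabulate(state_now, nbins = length(health_states()))

  E$age[E$alive] <- E$age[E$alive] + 1L
  ev <- c(
    cycle = t,
    deaths_other = sum(die_o),
    deaths_dm = sum(die_d),
    onsets = sum(onset),
    diagnoses = sum(dx),
    screening_visits = sum(screen),
    initiations = sum(init),
    reinitiations = sum(reinit),
    nonadherence = sum(nonadh),
    complications = sum(got_comp),
    cct_disbursed = sum(cct_now)
  )
  E$events_mat[t + 1L, ] <- ev
  E$last_events <- ev
  E$cycle <- t + 1L
  invisible(E)
}

#' Snapshot the current cohort state of an engine
#'
#' @param E An `ecea_engine` environment.
#' @return Tibble with `id`, `age`, `sex`, `quintile`, `income`, `state`
#'   (complication occupants show their complication state; the dead show
#'   their death state), `alive`.
#' @export
as_cohort <- function(E) {
  occ <- ifelse(E$comp > 0L, E$comp, E$cascade)
  state_i <- ifelse(E$alive, occ, E$dead_state)
  tibble(
    id = E$id, age = E$age, sex = E$sex, quintile = E$q, income = E$income,
    state = health_states()[state_i], alive = E$alive
  )
}

#' Run one strategy arm over the full horizon
#'
#' Advances the cohort through `params$horizon_years` annual cycles, accruing
#' discounted health-system costs (state costs plus transfer outlays and any
#' administrative loading), discounted and undiscounted out-of-pocket costs,
#' transfers received, DALYs (years lived with disability plus discounted
#' years of life lost truncated at the horizon), person-years in therapy, and
#' per-threshold catastrophic-expenditure person-years.
#'
#' Runs that share a cohort and `sim_seed` use identical random streams in
#' every cycle and decision (common random numbers), so incremental contrasts
#' between arms difference out first-order Monte Carlo noise.
#'
#' @inheritParams engine_state
#' @return An `ecea_run` object: `ledger` (per-person tibble), `occupancy`
#'   (cycle x state counts), `events` (per-cycle tibble), `strategy`, and
#'   metadata (`n`, `scale_factor`, seeds, cohort fingerprint).
#' @export
run_strategy <- function(cohort, strategy, params,
                         sim_seed = attr(cohort, "seed")) {
  E <- engine_state(cohort, strategy, params, sim_seed = sim_seed)
  for (t in seq_len(E$H)) step_cycle(E)
  che <- as.data.frame(E$che)
  names(che) <- paste0("che_", formatC(100 * E$thresholds, format = "d"))
  ledger <- tibble(
    id = E$id,
    sex = E$sex,
    quintile = E$q,
    income = E$income,
    capacity = E$capacity,
    hs_cost = E$hs_cost,
    oop_disc = E$oop_disc,
    oop_undisc = E$oop_undisc,
    oop_net_undisc = E$oop_net_undisc,
    oop_net_disc = E$oop_net_disc,
    cct_disc = E$cct_disc,
    cct_undisc = E$cct_undisc,
    dalys = E$dalys,
    treated_years = E$treated_years,
    treated_years_disc = E$treated_years_disc,
    n_complications = E$n_complications,
    died_cycle = E$died_cycle,
    death_state = ifelse(
      E$dead_state > 0L, health_states()[E$dead_state], NA_character_
    )
  )
  ledger <- dplyr::bind_cols(ledger, as_tibble(che))
  structure(
    list(
      ledger = ledger,
      occupancy = E$occupancy,
      events = as_tibble(as.data.frame(E$events_mat)),
      strategy = strategy,
      n = E$n,
      horizon = E$H,
      thresholds = E$thresholds,
      scale_factor = attr(cohort, "scale_factor") %||% 1,
      sim_seed = as.integer(sim_seed),
      cohort_seed = attr(cohort, "seed"),
      cohort_fingerprint = cohort_fingerprint(cohort),
      ce_threshold = params$econ$ce_threshold
    ),
    class = "ecea_run"
  )
}

#' @export
print.ecea_run <- function(x, ...) {
  cat(sprintf(
    "<ecea_run> arm `%s` | n = %d (x%.1f represented) | %d cycles\n",
    x$strategy$name, x$n, x$scale_factor, x$horizon
  ))
  g <- glance(x)
  cat(sprintf(
    "  mean/person: cost $%.2f, OOP $%.2f, CCT $%.2f, DALYs %.3f\n",
    g$cost_pp, g$oop_pp, g$cct_pp, g$daly_pp
  ))
  invisible(x)
}

#' One-row summary of a strategy run
#'
#' @param x An `ecea_run`.
#' @param ... Unused.
#' @return Tibble with per-person means and population-scaled totals.
#' @export
glance.ecea_run <- function(x, ...) {
  ld <- x$ledger
  che <- dplyr::select(ld, dplyr::starts_with("che_"))
  out <- tibble(
    arm = x$strategy$name,
    n = x$n,
    scale_factor = x$scale_factor,
    cost_pp = mean(ld$hs_cost),
    oop_pp = mean(ld$oop_disc),
    cct_pp = mean(ld$cct_disc),
    daly_pp = mean(ld$dalys),
    treated_years_pp = mean(ld$treated_years_disc),
    deaths = sum(!is.na(ld$died_cycle)),
    cost_total = sum(ld$hs_cost) * x$scale_factor,
    daly_total = sum(ld$dalys) * x$scale_factor
  )
  for (k in names(che)) {
    out[[paste0(k, "_cases")]] <- sum(che[[k]]) * x$scale_factor
  }
  out
}

#' Per-person ledger of a run
#'
#' @param x An `ecea_run`.
#' @param ... Unused.
#' @return The per-person ledger tibble.
#' @export
tidy.ecea_run <- function(x, ...) x$ledger
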