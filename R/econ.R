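# Incremental analysis: costs, DALYs averted, ICER, incremental net monetary
# benefit (INMB), and subgroup disaggregation. The incremental cost uses the
# health-system perspective (state direct medical costs plus transfer outlays
# and any administrative loading); out-of-pocket costs enter only the
# financial-risk-protection outcomes.

#' Incremental cost-effectiveness ratio
#'
#' @param delta_cost Incremental cost (USD).
#' @param delta_daly Incremental DALYs averted.
#' @return `delta_cost / delta_daly`; `NA` when `delta_daly` is zero (the
#'   undefined-ICER signal). Negative `delta_daly` yields a ratio that should
#'   be read through [summarize_ecea()]'s `dominated` flag rather than as a
#'   bare number.
#' @export
icer <- function(delta_cost, delta_daly) {
  ifelse(delta_daly == 0, NA_real_, delta_cost / delta_daly)
}

#' Incremental net monetary benefit per person
#'
#' @param delta_cost_pp Incremental cost per eligible person (USD).
#' @param delta_daly_pp Incremental DALYs averted per eligible person.
#' @param threshold Cost-effectiveness threshold (USD per DALY averted).
#' @return `threshold * delta_daly_pp - delta_cost_pp`.
#' @export
inmb <- function(delta_cost_pp, delta_daly_pp, threshold = 3015) {
  if (any(threshold <= 0)) abort("`threshold` must be > 0")
  threshold * delta_daly_pp - delta_cost_pp
}

increments_for <- function(base_ld, arm_ld, sf, thresholds, ce_threshold) {
  n <- nrow(base_ld)
  d_cost_pp <- mean(arm_ld$hs_cost) - mean(base_ld$hs_cost)
  d_daly_pp <- mean(base_ld$dalys) - mean(arm_ld$dalys)
  d_oop_pp <- mean(base_ld$oop_net_disc) - mean(arm_ld$oop_net_disc)
  out <- tibble(
    n_eligible = n * sf,
    d_cost_total = d_cost_pp * n * sf,
    d_cost_pp = d_cost_pp,
    d_daly_total = d_daly_pp * n * sf,
    d_daly_pp = d_daly_pp,
    icer = icer(d_cost_pp, d_daly_pp),
    inmb = inmb(d_cost_pp, d_daly_pp, ce_threshold),
    dominated = d_daly_pp < 0 & d_cost_pp > 0,
    dominant = d_daly_pp > 0 & d_cost_pp < 0,
    d_oop_averted_total = d_oop_pp * n * sf
  )
  for (th in thresholds) {
    col <- paste0("che_", formatC(100 * th, format = "d"))
    out[[paste0(col, "_averted")]] <-
      (sum(base_ld[[col]]) - sum(arm_ld[[col]])) * sf
  }
  out
}

#' Incremental summary of an arm against the no-programme comparator
#'
#' Computes population-scaled incremental totals, per-eligible-person
#' increments, the ICER, the INMB at the configured threshold, incremental
#' net out-of-pocket costs averted and CHE person-years averted per threshold,
#' optionally disaggregated by sex or income quintile. Per-person figures use
#' the eligible (simulated, population-scaled) individuals of the group as
#' denominator.
#'
#' @param base `ecea_run` for the comparator.
#' @param arm `ecea_run` for the intervention arm (same cohort and seed).
#' @param by `"none"`, `"sex"` or `"quintile"`.
#' @param ce_threshold Cost-effectiveness threshold (defaults to the one the
#'   runs carry, $3015/DALY under default parameters).
#' @return Tibble, one row per group, with a `group` column.
#' @export
summarize_ecea <- function(base, arm, by = c("none", "sex", "quintile"),
                           ce_threshold = base$ce_threshold) {
  by <- match.arg(by)
  check_comparable(base, arm)
  sf <- base$scale_factor
  th <- base$thresholds
  if (by == "none") {
    res <- increments_for(base$ledger, arm$ledger, sf, th, ce_threshold)
    return(mutate(res, group = "overall", arm = arm$strategy$name, .before = 1))
  }
  groups <- sort(unique(base$ledger[[by]]))
  purrr::map_dfr(groups, function(g) {
    bsel <- base$ledger[base$ledger[[by]] == g, ]
    asel <- arm$ledger[arm$ledger[[by]] == g, ]
    increments_for(bsel, asel, sf, th, ce_threshold) %>%
      mutate(group = as.character(g), arm = arm$strategy$name, .before = 1)
  })
}

#' Run and summarise all strategy arms against no programme
#'
#' Runs the no-programme comparator plus each CCT arm on one cohort under
#' common random numbers and assembles the study-shaped results table
#' (incremental cost, DALYs averted, ICER, INMB overall and by sex,
#' out-of-pocket costs averted, CHE cases averted per threshold).
#'
#' @param cohort Cohort tibble from [generate_population()].
#' @param params An `ecea_params` list.
#' @param arms Named list of [strategy()] objects; defaults to the three CCT
#'   arms for the cohort's quintiles.
#' @param sim_seed Simulation seed shared by all arms.
#' @return An `ecea_comparison` tibble (one row per arm) with the base and arm
#'   runs attached as attributes `base_run` and `arm_runs`.
#' @export
compare_strategies <- function(cohort, params, arms = NULL,
                               sim_seed = attr(cohort, "seed")) {
  elig <- attr(cohort, "quintiles") %||% sort(unique(cohort$quintile))
  if (is.null(arms)) {
    arms <- cct_strategies(elig)[c(
      "diagnosis_only", "treatment_only", "diagnosis_treatment"
    )]
  }
  base <- run_strategy(
    cohort, strategy(FALSE, FALSE, elig, "no_programme"), params,
    sim_seed = sim_seed
  )
  arm_runs <- purrr::map(arms, function(s) {
    run_strategy(cohort, s, params, sim_seed = sim_seed)
  })
  rows <- purrr::map_dfr(arm_runs, function(r) {
    overall <- summarize_ecea(base, r)
    by_sex <- summarize_ecea(base, r, by = "sex")
    overall$inmb_female <- by_sex$inmb[by_sex$group == "female"]
    overall$inmb_male <- by_sex$inmb[by_sex$group == "male"]
    overall
  })
  rows$eligibility <- paste(
    "quintile", paste(elig, collapse = "+")
  )
  out <- dplyr::relocate(rows, "arm", "eligibility") %>% select(-"group")
  attr(out, "base_run") <- base
  attr(out, "arm_runs") <- arm_runs
  class(out) <- c("ecea_comparison", class(out))
  out
}

#' @export
tidy.ecea_comparison <- function(x, ...) {
  as_tibble(x)
}

#' One-row overview of a strategy comparison
#'
#' @param x An `ecea_comparison`.
#' @param ... Unused.
#' @return Tibble with the best arm by INMB and its key outcomes.
#' @export
glance.ecea_comparison <- function(x, ...) {
  best <- x[which.max(x$inmb), ]
  tibble(
    n_arms = nrow(x),
    best_arm = best$arm,
    best_inmb = best$inmb,
    best_icer = best$icer,
    any_dominated = any(x$dominated)
  )
}
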