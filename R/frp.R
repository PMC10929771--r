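# Financial risk protection: catastrophic health expenditure (CHE) assessment
# and cases averted. CHE is assessed per person-year: annual out-of-pocket
# spending (net of transfers received that year, by default) against a
# threshold share of capacity to pay, where capacity to pay is income minus
# the food poverty line, floored at a small positive amount.

#' Is a person-year a catastrophic health expenditure case?
#'
#' @param annual_oop Annual out-of-pocket health spending (USD).
#' @param income Annual income (USD), must be positive.
#' @param fpl Food poverty line (annual subsistence expenditure, USD).
#' @param threshold Capacity-to-pay fraction in (0, 1).
#' @param floor Positive floor applied to capacity to pay.
#' @return Logical: `annual_oop > threshold * max(income - fpl, floor)`
#'   (strict inequality).
#' @export
is_che <- function(annual_oop, income, fpl, threshold, floor = 1e-6) {
  if (any(threshold <= 0 | threshold >= 1)) {
    abort("`threshold` must lie in (0, 1)")
  }
  if (any(income <= 0)) abort("`income` must be > 0")
  annual_oop > threshold * pmax(income - fpl, floor)
}

check_comparable <- function(base, arm) {
  if (!inherits(base, "ecea_run") || !inherits(arm, "ecea_run")) {
    abort("`base` and `arm` must be `ecea_run` objects")
  }
  if (!identical(base$cohort_fingerprint, arm$cohort_fingerprint) ||
    !identical(base$sim_seed, arm$sim_seed)) {
    abort(
      "Runs are not comparable: they must share the cohort and simulation seed",
      class = "eceasim_comparison_error"
    )
  }
  invisible(TRUE)
}

#' Catastrophic health expenditure cases averted by an arm
#'
#' Counts CHE person-years in the comparator and the intervention arm at one
#' capacity-to-pay threshold and returns the population-scaled difference.
#' Both runs must share the cohort and simulation seed (common random
#' numbers).
#'
#' @param base `ecea_run` for the no-programme comparator.
#' @param arm `ecea_run` for the intervention arm.
#' @param threshold One of the thresholds the runs were accrued at (e.g. 0.10).
#' @return Population-scaled count of CHE person-years averted.
#' @export
che_cases_averted <- function(base, arm, threshold) {
  check_comparable(base, arm)
  k <- match(TRUE, abs(base$thresholds - threshold) < 1e-9)
  if (is.na(k)) {
    abort(sprintf(
      "Threshold %.3g not accrued in these runs (available: %s)",
      threshold, paste(base$thresholds, collapse = ", ")
    ))
  }
  col <- paste0("che_", formatC(100 * base$thresholds[k], format = "d"))
  (sum(base$ledger[[col]]) - sum(arm$ledger[[col]])) * base$scale_factor
}

#' FRP summary across thresholds and sex
#'
#' @inheritParams che_cases_averted
#' @return Tibble with columns `threshold`, `sex` (including `"all"`),
#'   `cases_base`, `cases_arm`, `cases_averted` (population-scaled).
#' @export
frp_summary <- function(base, arm) {
  check_comparable(base, arm)
  sf <- base$scale_factor
  purrr::map_dfr(seq_along(base$thresholds), function(k) {
    col <- paste0("che_", formatC(100 * base$thresholds[k], format = "d"))
    by_sex <- tibble(
      sex = base$ledger$sex,
      b = base$ledger[[col]],
      a = arm$ledger[[col]]
    ) %>%
      group_by(.data$sex) %>%
      summarise(
        cases_base = sum(.data$b) * sf,
        cases_arm = sum(.data$a) * sf,
        .groups = "drop"
      )
    tot <- tibble(
      sex = "all",
      cases_base = sum(base$ledger[[col]]) * sf,
      cases_arm = sum(arm$ledger[[col]]) * sf
    )
    bind_rows(tot, by_sex) %>%
      mutate(
        threshold = base$thresholds[k],
        cases_averted = .data$cases_base - .data$cases_arm,
        .before = 1
      )
  })
}
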