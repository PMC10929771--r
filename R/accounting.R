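# Discounting, disability and transfer accounting. Per-cycle accrual happens
# inside the engine loop, but every rule it applies is defined here so the
# accounting semantics are testable in isolation.

#' Discount factor for an annual cycle
#'
#' @param year Cycle index (0 = present) or vector of indices.
#' @param rate Annual discount rate (default 0.05 per South African guidance).
#' @return `(1 + rate)^(-year)`.
#' @export
discount_factor <- function(year, rate = 0.05) {
  if (any(year < 0)) abort("`year` must be >= 0")
  if (rate < 0) abort("`rate` must be >= 0")
  (1 + rate)^(-year)
}

# Discounted years-of-life-lost weight for a death in cycle `t`: the death
# state's disability weight of 1 applies from the death cycle to the end of
# the 45-year horizon (truncated there rather than at life expectancy).
remaining_discounted_years <- function(horizon, rate) {
  df <- discount_factor(seq_len(horizon) - 1, rate)
  rev(cumsum(rev(df)))
}

#' Conditional cash transfer disbursed in one cycle
#'
#' Implements the disbursement rules: a one-off $13 transfer for attending a
#' screening/diagnosis visit when the strategy covers diagnosis services, and
#' $51 for a full adherent treatment-year (four quarterly transfers, not
#' pro-rated) when the strategy covers treatment services -- in both cases only
#' for individuals in an eligible income quintile. In diagnosis-covering arms
#' with `params$screening_transfers = TRUE`, screening attendance by people
#' without a diagnosis also earns the $13 transfer regardless of test result.
#'
#' @param strategy An [strategy()] object.
#' @param params An `ecea_params` list.
#' @param quintile Integer vector of income quintiles.
#' @param diagnosis_visit Logical: attended a diagnosis visit (was diagnosed)
#'   this cycle.
#' @param screening_visit Logical: attended screening without a diabetes
#'   diagnosis this cycle.
#' @param treated_year Logical: occupied a therapy state for the full cycle.
#' @return Numeric vector of USD disbursed per person for the cycle.
#' @export
disburse_cct <- function(strategy, params, quintile,
                         diagnosis_visit = FALSE, screening_visit = FALSE,
                         treated_year = FALSE) {
  elig <- quintile %in% strategy$eligible_quintiles
  amt <- numeric(length(quintile))
  if (isTRUE(strategy$covers_diagnosis)) {
    visit <- diagnosis_visit |
      (isTRUE(params$screening_transfers) & screening_visit)
    amt <- amt + params$econ$cct_diagnosis_amount * (elig & visit)
  }
  if (isTRUE(strategy$covers_treatment)) {
    amt <- amt + params$econ$cct_treatment_amount * (elig & treated_year)
  }
  amt
}
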