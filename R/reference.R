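#' Published benchmark estimates for the South African CCT programme
#'
#' The externally reported incremental outcomes of the three CCT strategies
#' against no programme, for the two eligibility scenarios (income quintile 1
#' only; quintiles 1 and 2), as printed: total and per-eligible-person
#' incremental health-system cost (USD 2020), total and per-person incremental
#' DALYs averted, INMB at $3015 per DALY averted (overall and by sex),
#' incremental out-of-pocket costs averted, and CHE cases averted at the 10%,
#' 25% and 40% capacity-to-pay thresholds. `NA` marks outcomes reported as
#' not estimable for the diagnosis-only arm.
#'
#' These values serve as arithmetic anchors: the net-monetary-benefit identity
#' `INMB = threshold x DALYs_pp - cost_pp` can be recomputed from the printed
#' per-person columns, and total / per-person ratios recover the eligible
#' population sizes (about 6 and 12 million).
#'
#' @return A tibble with one row per (eligibility, strategy).
#' @export
reference_estimates <- function() {
  tibble(
    eligibility = rep(c("quintile 1", "quintiles 1+2"), each = 3),
    arm = rep(
      c("diagnosis_only", "diagnosis_treatment", "treatment_only"), 2
    ),
    d_cost_total = c(
      110144690, 69380988, 67071454,
      235578120, 154964495, 148835236
    ),
    d_cost_pp = c(18.41, 11.59, 11.21, 19.68, 12.95, 12.44),
    d_daly_total = c(3253, 65277, 59330, 7487, 137698, 124300),
    d_daly_pp = c(0.000544, 0.0109, 0.00991, 0.000626, 0.0115, 0.0104),
    inmb = c(-16.77, 21.29, 18.68, -17.80, 21.74, 18.88),
    inmb_female = c(-24.76, 40.06, 34.87, -23.66, 36.23, 31.90),
    inmb_male = c(-19.79, 15.92, 14.26, -23.80, 21.22, 17.96),
    oop_averted = c(NA, 8715456, 3984548, NA, 19005489, 8475607),
    che_10_averted = c(NA, 104403, 34968, NA, 156682, 55213),
    che_25_averted = c(NA, 78080, 27812, NA, 84794, 30317),
    che_40_averted = c(NA, 60445, 22241, NA, 60738, 22246)
  )
}
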