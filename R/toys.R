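# Toy scenarios with analytically known behaviour. Each returns a complete
# parameter set (and where needed a cohort recipe) whose outcomes can be
# verified in closed form or against the deterministic cohort recursion, so
# every pipeline stage is testable without external data.

zero_strata <- function(params, bg = 0, dm_mort = 0, dm_inc = 0) {
  s <- params$strata
  s$bg_mortality <- bg
  s$dm_mortality <- dm_mort
  s$dm_incidence <- dm_inc
  s
}

#' Build a named toy scenario
#'
#' Available toys:
#' \describe{
#'   \item{null_effect}{Odds ratio 1 everywhere: every arm reproduces the
#'     comparator exactly under common random numbers.}
#'   \item{certain_death}{Background mortality 1: everyone dies in cycle 0 and
#'     total DALYs per person equal the closed-form discounted sum of the
#'     horizon, `sum((1+r)^-t)`.}
#'   \item{single_stratum}{A homogeneous cohort (one age, sex and quintile)
#'     whose state occupancies can be checked against the deterministic
#'     expected-value recursion.}
#'   \item{full_protection}{An arm parameter set with all OOP costs forced to
#'     zero: CHE cases averted equal the comparator's total CHE cases.}
#'   \item{deterministic_cascade}{All cascade probabilities 0 or 1, no deaths
#'     or complications: a single undiagnosed diabetic is diagnosed in cycle
#'     0 (one $13 transfer in diagnosis-covering arms) and accrues $51/year
#'     transfers on oral therapy thereafter in treatment-covering arms.}
#' }
#'
#' @param name One of the toy names above.
#' @param params Base parameters the toy modifies.
#' @return A list with elements `name`, `description`, `params` and (where
#'   applicable) `arm_params` and `cohort` (a ready-made cohort tibble).
#' @export
make_toy <- function(name, params = default_parameters()) {
  known <- c(
    "null_effect", "certain_death", "single_stratum", "full_protection",
    "deterministic_cascade"
  )
  if (!name %in% known) {
    abort(sprintf(
      "Unknown toy `%s` (available: %s)", name, paste(known, collapse = ", ")
    ))
  }
  switch(name,
    null_effect = {
      p <- params
      p$effect$odds_ratio <- 1
      p$effect$ci_low <- 1
      p$effect$ci_high <- 1
      p$effect$or_diagnosis <- NA_real_
      p$effect$or_treatment <- NA_real_
      list(
        name = name,
        description = "odds ratio 1: arms identical to comparator under CRN",
        params = validate_parameters(p)
      )
    },
    certain_death = {
      p <- params
      p$strata <- zero_strata(p, bg = 1)
      list(
        name = name,
        description = "all die in cycle 0; DALYs = sum of discount factors",
        params = validate_parameters(p)
      )
    },
    single_stratum = {
      p <- params
      p$female_share <- 1
      list(
        name = name,
        description = "homogeneous stratum for the cohort-recursion oracle",
        params = validate_parameters(p),
        cohort_args = list(quintiles = 1L, ages = 40L)
      )
    },
    full_protection = {
      arm <- params
      arm$states$oop_cost[] <- 0
      list(
        name = name,
        description = "arm with zero OOP: CHE averted equals base CHE cases",
        params = params,
        arm_params = validate_parameters(arm)
      )
    },
    deterministic_cascade = {
      p <- params
      p$cascade$p_dx <- 1
      p$cascade$p_dt <- 1
      p$cascade$p_tna <- 0
      p$cascade$p_reinit <- 0
      p$strata <- zero_strata(p)
      p$complications$untreated_incidence[] <- 0
      p$therapy_split <- c(oral = 1, insulin = 0, combination = 0)
      p$screening_transfers <- FALSE
      p <- validate_parameters(p)
      cohort <- tibble(
        id = 1L, age = 40L, sex = "female", quintile = 1L,
        income = 500, state = "UndiagnosedDM"
      )
      attr(cohort, "seed") <- 1L
      attr(cohort, "quintiles") <- 1L
      attr(cohort, "scale_factor") <- 1
      list(
        name = name,
        description = "hand-traceable: diagnose cycle 0, oral therapy after",
        params = p,
        cohort = cohort
      )
    }
  )
}
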