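# Shared fixtures, built once per test session.

PDEF <- default_parameters()

# Small parameter set with a short horizon for fast mechanical tests.
short_params <- function(horizon = 5L, params = PDEF) {
  params$horizon_years <- as.integer(horizon)
  validate_parameters(params)
}

# A tiny hand-built cohort (bypasses generate_population) for engine tests.
manual_cohort <- function(states, age = 40L, sex = "female", quintile = 1L,
                          income = 500, seed = 1L) {
  n <- length(states)
  cohort <- tibble::tibble(
    id = seq_len(n),
    age = rep(as.integer(age), length.out = n),
    sex = rep(sex, length.out = n),
    quintile = rep(as.integer(quintile), length.out = n),
    income = rep(income, length.out = n),
    state = states
  )
  attr(cohort, "seed") <- as.integer(seed)
  attr(cohort, "quintiles") <- sort(unique(cohort$quintile))
  attr(cohort, "scale_factor") <- 1
  cohort
}

# Parameters with all mortality/incidence set to given constants.
flat_rate_params <- function(params = PDEF, bg = 0, dm_mort = 0, dm_inc = 0,
                             comp_inc = NULL) {
  params$strata$bg_mortality <- bg
  params$strata$dm_mortality <- dm_mort
  params$strata$dm_incidence <- dm_inc
  if (!is.null(comp_inc)) params$complications$untreated_incidence <- comp_inc
  validate_parameters(params)
}
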