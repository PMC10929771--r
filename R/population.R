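# Synthetic eligible population: adults aged 25-69 in the eligible income
# quintiles, with banded-gamma incomes, baseline diabetes status drawn from the
# calibrated prevalence function and cascade position from the baseline split.

#' Sample annual incomes for one quintile
#'
#' Draws from the quintile's gamma distribution truncated to the quintile's
#' income band, via the inverse-CDF transform (exactly equivalent in
#' distribution to rejection sampling against the band).
#'
#' @param n Number of draws (ignored when `u` is supplied).
#' @param quintile Income quintile, 1-5.
#' @param income_model Tibble with columns `quintile`, `lower`, `upper`,
#'   `shape`, `scale` (see [default_parameters()]).
#' @param seed Optional seed for a self-contained draw.
#' @param u Optional uniforms in (0,1) to transform (used by the cohort
#'   generator so all randomness flows from one seeded stream).
#' @return Numeric vector of annual incomes (USD 2020), all within the band.
#' @export
sample_income <- function(n, quintile, income_model, seed = NULL, u = NULL) {
  row <- income_model[income_model$quintile == quintile, ]
  if (nrow(row) != 1) {
    abort(sprintf("Unknown income quintile %s", format(quintile)))
  }
  if (row$upper <= row$lower) {
    abort(sprintf("Income band for quintile %d has zero width", quintile))
  }
  if (is.null(u)) {
    u <- if (is.null(seed)) {
      runif(n)
    } else {
      withr::with_seed(seed, runif(n))
    }
  }
  plo <- pgamma(row$lower, shape = row$shape, scale = row$scale)
  phi <- pgamma(row$upper, shape = row$shape, scale = row$scale)
  qgamma(plo + u * (phi - plo), shape = row$shape, scale = row$scale)
}

#' Generate the synthetic eligible cohort
#'
#' Ages are drawn uniformly over `ages` (default 25-69; a custom pyramid can be
#' expressed by repeating ages in the vector), sex from the configured female
#' share, quintile uniformly over `quintiles`, income from the banded gamma
#' model, and baseline diabetes from the prevalence implied by the strata
#' incidence tables (so the cohort hits the calibrated quintile prevalence in
#' expectation). Baseline diabetics are split across cascade states by the
#' baseline cascade split (undiagnosed 0.600, diagnosed untreated 0.007, oral
#' 0.196, insulin 0.036, combination 0.160, renormalised).
#'
#' @param n Cohort size (>= 1).
#' @param quintiles Integer subset of 1:5; the study design uses `1` or `1:2`.
#' @param params An `ecea_params` list with strata tables.
#' @param seed Integer seed; the cohort is deterministic given all arguments.
#' @param ages Integer ages to sample from (default `25:69`).
#' @return A tibble with columns `id`, `age`, `sex`, `quintile`, `income`,
#'   `state` and attributes `seed`, `quintiles` and `scale_factor` (the number
#'   of represented people per simulated row, from `params$pop_per_quintile`).
#' @export
generate_population <- function(n, quintiles, params, seed, ages = 25:69) {
  if (!is.numeric(n) || n < 1) abort("`n` must be >= 1")
  n <- as.integer(n)
  if (!all(quintiles %in% 1:5)) {
    abort("`quintiles` must be a subset of 1:5")
  }
  if (is.null(params$strata)) {
    abort("`params$strata` is missing; synthesize or load strata tables first")
  }
  quintiles <- sort(unique(as.integer(quintiles)))
  cohort <- withr::with_seed(seed, {
    age <- ages[sample.int(length(ages), n, replace = TRUE)]
    sex <- ifelse(runif(n) < params$female_share, "female", "male")
    quintile <- if (length(quintiles) == 1) {
      rep(quintiles, n)
    } else {
      sample(quintiles, n, replace = TRUE)
    }
    income <- numeric(n)
    u_inc <- runif(n)
    for (q in quintiles) {
      sel <- quintile == q
      income[sel] <- sample_income(
        sum(sel), q, params$income,
        u = u_inc[sel]
      )
    }
    prev <- implied_prevalence(params$strata, age, sex, quintile)
    diabetic <- runif(n) < prev
    split <- params$baseline_cascade_split / sum(params$baseline_cascade_split)
    cuts <- cumsum(split)
    u_state <- runif(n)
    state_i <- rep(STATE[["Healthy"]], n)
    di <- which(diabetic)
    state_i[di] <- 2L + findInterval(u_state[di], cuts[-length(cuts)])
    tibble(
      id = seq_len(n),
      age = as.integer(age),
      sex = sex,
      quintile = as.integer(quintile),
      income = income,
      state = health_states()[state_i]
    )
  })
  attr(cohort, "seed") <- as.integer(seed)
  attr(cohort, "quintiles") <- quintiles
  attr(cohort, "scale_factor") <-
    params$pop_per_quintile * length(quintiles) / n
  cohort
}
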