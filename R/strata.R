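# Synthetic age/sex/income strata rate tables. The published analysis drew
# diabetes incidence and mortality and background mortality from national
# survey and burden-of-disease sources that are not reproduced here; this
# module synthesises smooth, age-increasing stand-in tables calibrated so that
# a generated cohort reproduces the printed baseline diabetes prevalence by
# quintile (17.5% / 18.4% for quintiles 1 and 2).

strata_age_lo <- function() seq(25L, 95L, by = 5L)

strata_band_index <- function(age) {
  pmin(pmax((age - 25L) %/% 5L, 0L), length(strata_age_lo()) - 1L) + 1L
}

#' Synthesize default strata rate tables
#'
#' Builds the (age band, sex, quintile) table of annual diabetes incidence and
#' diabetes-related mortality plus (age band, sex) background mortality. The
#' incidence curve is a smooth logistic ramp in age with a female:male ratio
#' (default 1.3:1) and a per-cell log-normal jitter emulating survey noise; a
#' per-quintile scale factor is then solved (bounded root search) so that the
#' baseline diabetes prevalence implied for a cohort with a uniform 25-69 age
#' pyramid equals the calibration target for that quintile. Background
#' mortality is a deterministic Gompertz-type curve, non-decreasing in age.
#'
#' @param params An `ecea_params` list (its `synthesis` block supplies curve
#'   constants; its `female_incidence_ratio` the sex ratio).
#' @param seed Integer; the table is deterministic given `(seed, calibration)`.
#' @param calibration List with `prevalence` (5 quintile targets) and
#'   `diagnosed_fraction`; defaults come from `params`.
#' @return A tibble with columns `age_band`, `age_lo`, `sex`, `quintile`,
#'   `dm_incidence`, `dm_mortality`, `bg_mortality`. Bands run 25-29 through
#'   95+; ages beyond the top band reuse its rates.
#' @export
synthesize_default_strata <- function(params, seed = params$synthesis$seed,
                                      calibration = NULL) {
  syn <- params$synthesis
  calibration <- calibration %||% list(
    prevalence = params$prevalence_targets,
    diagnosed_fraction = 1 - params$baseline_cascade_split[["undiagnosed"]] /
      sum(params$baseline_cascade_split)
  )
  prev_target <- calibration$prevalence
  if (length(prev_target) == 1) prev_target <- rep(prev_target, 5)
  age_lo <- strata_age_lo()
  nb <- length(age_lo)
  mid <- age_lo + 2
  grid <- tidyr::expand_grid(
    age_lo = age_lo, sex = c("female", "male"), quintile = 1:5
  )

  # Background mortality: smooth, sex-specific, non-decreasing in age.
  bg_curve <- function(m, sexv) {
    mult <- ifelse(sexv == "male", sqrt(syn$bg_sex_ratio),
      1 / sqrt(syn$bg_sex_ratio)
    )
    pmin(syn$bg_base * exp(syn$bg_growth * (m - 27)) * mult, 0.95)
  }
  grid$bg_mortality <- bg_curve(grid$age_lo + 2, grid$sex)

  # Diabetes-related (excess) mortality for people with diabetes, untreated.
  # Treated individuals face this rate times the therapy mortality effect.
  qmult <- syn$dm_mort_quintile_ratio^(3 - grid$quintile)
  grid$dm_mortality <- pmin(
    syn$dm_mort_base * exp(syn$dm_mort_growth * (grid$age_lo + 2 - 27)) * qmult,
    0.9
  )

  # Incidence: logistic age ramp, sex ratio, seeded log-normal jitter, then a
  # per-quintile scale solved against the prevalence target.
  fr <- params$female_incidence_ratio
  sex_mult <- ifelse(grid$sex == "female", 2 * fr / (1 + fr), 2 / (1 + fr))
  base_curve <- syn$inc_floor +
    (syn$inc_ceiling - syn$inc_floor) *
      plogis((grid$age_lo + 2 - syn$inc_midage) / syn$inc_age_scale)
  jitter <- withr::with_seed(
    derive_seed(seed, 0L, 99L),
    exp(rnorm(nrow(grid), mean = 0, sd = syn$jitter_sd))
  )
  shape0 <- base_curve * sex_mult * jitter

  # Prevalence implied for a uniform 25-69 pyramid with a 50/50 sex split:
  # cumulative-hazard mapping prev(a) = 1 - exp(-sum of annual incidence).
  implied_mean_prev <- function(rates_q) {
    # rates_q: named by sex, each length nb (band rates)
    sapply(c("female", "male"), function(s) {
      band_rates <- rates_q[[s]]
      ages <- 25:69
      cumhaz <- cumsum(band_rates[strata_band_index(ages)])
      prev <- 1 - exp(-c(0, cumhaz[-length(cumhaz)]))
      mean(prev)
    })
  }

  scale_q <- numeric(5)
  for (q in 1:5) {
    target <- prev_target[q]
    if (target == 0) {
      scale_q[q] <- 0
      next
    }
    rates_for <- function(s) {
      function(sc) {
        idx <- grid$quintile == q & grid$sex == s
        pmin(shape0[idx] * sc, 1)
      }
    }
    f <- function(sc) {
      r <- list(
        female = rates_for("female")(sc),
        male = rates_for("male")(sc)
      )
      mean(implied_mean_prev(r)) - target
    }
    lo <- 1e-6
    hi <- 200
    if (f(hi) < 0) {
      abort(sprintf(
        paste0(
          "Strata calibration infeasible for quintile %d: target prevalence ",
          "%.3f, closest achievable %.3f"
        ),
        q, target, f(hi) + target
      ))
    }
    scale_q[q] <- uniroot(f, c(lo, hi), tol = 1e-10)$root
  }

  grid$dm_incidence <- pmin(shape0 * scale_q[grid$quintile], 1)
  grid$age_band <- sprintf(
    "%d-%d", grid$age_lo,
    ifelse(grid$age_lo == max(age_lo), 120L, grid$age_lo + 4L)
  )
  out <- grid %>%
    select(
      "age_band", "age_lo", "sex", "quintile",
      "dm_incidence", "dm_mortality", "bg_mortality"
    ) %>%
    arrange(.data$quintile, .data$sex, .data$age_lo)
  as_tibble(out)
}

# Baseline diabetes prevalence implied by the strata incidence table for given
# individual ages. Used both by the calibration above and by the population
# generator, so the generated cohort matches the calibrated target in
# expectation by construction.
implied_prevalence <- function(strata, age, sex, quintile) {
  key <- paste(strata$sex, strata$quintile, sep = "|")
  prev_tab <- list()
  ages <- 25:max(70, max(age))
  for (k in unique(key)) {
    idx <- key == k
    band_rates <- strata$dm_incidence[idx][order(strata$age_lo[idx])]
    cumhaz <- cumsum(band_rates[strata_band_index(ages)])
    prev <- 1 - exp(-c(0, cumhaz[-length(cumhaz)]))
    prev_tab[[k]] <- prev
  }
  k_ind <- paste(sex, quintile, sep = "|")
  out <- numeric(length(age))
  for (k in unique(k_ind)) {
    sel <- k_ind == k
    out[sel] <- prev_tab[[k]][age[sel] - 25L + 1L]
  }
  out
}

# Fast lookup arrays for the engine: band x sex x quintile cubes.
strata_arrays <- function(strata) {
  nb <- length(strata_age_lo())
  dim3 <- c(nb, 2L, 5L)
  sex_i <- ifelse(strata$sex == "female", 1L, 2L)
  band_i <- strata_band_index(strata$age_lo)
  pos <- band_i + nb * (sex_i - 1L) + nb * 2L * (strata$quintile - 1L)
  mk <- function(col) {
    a <- rep(NA_real_, prod(dim3))
    a[pos] <- strata[[col]]
    a
  }
  list(
    nb = nb,
    dm_incidence = mk("dm_incidence"),
    dm_mortality = mk("dm_mortality"),
    bg_mortality = mk("bg_mortality")
  )
}

strata_pos <- function(arr, age, sex_i, quintile) {
  strata_band_index(age) + arr$nb * (sex_i - 1L) + arr$nb * 2L * (quintile - 1L)
}
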