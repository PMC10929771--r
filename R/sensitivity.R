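# Sensitivity machinery: probabilistic sensitivity analysis over parameter
# uncertainty, cost-effectiveness acceptability curves, one-way (tornado)
# analyses, and population-replicate variability at fixed parameters.

# Log-normal for the intervention odds ratio, matched to the reported 95% CI
# (geometric midpoint as median). The implied median, 1.313, is consistent
# with the reported 1.31 at printed precision.
or_distribution <- function(effect) {
  list(
    meanlog = (log(effect$ci_low) + log(effect$ci_high)) / 2,
    sdlog = log(effect$ci_high / effect$ci_low) / (2 * stats::qnorm(0.975))
  )
}

beta_moments <- function(p, cv, what) {
  if (p == 0 || cv == 0) {
    return(NULL)
  }
  v <- (cv * p)^2
  if (v >= p * (1 - p)) {
    abort(sprintf(
      "Beta moment matching infeasible for `%s` (p = %g, cv = %g)",
      what, p, cv
    ))
  }
  k <- p * (1 - p) / v - 1
  list(a = p * k, b = (1 - p) * k)
}

#' Sample parameter sets for probabilistic sensitivity analysis
#'
#' Cost parameters (state direct medical and OOP costs) are drawn from gamma
#' distributions with mean at the point estimate and coefficient of variation
#' `cv_cost`; the intervention odds ratio from a log-normal matched to its
#' 95% CI; utilisation probabilities and complication incidences from beta
#' distributions moment-matched around the point estimate with coefficient of
#' variation `cv_prob`. Therapy effect ratios are held at their point
#' estimates. With both CVs zero every draw equals the point estimate.
#'
#' @param params Base `ecea_params`.
#' @param n_draws Number of parameter sets (>= 1).
#' @param seed Integer seed; draws are deterministic given `(seed, n_draws)`.
#' @param cv_cost,cv_prob Coefficients of variation (defaults 0.2).
#' @param sample_or Draw the odds ratio from its CI-matched log-normal? Set
#'   `FALSE` (with both CVs zero) for fully degenerate draws.
#' @return List of `ecea_params`, one per draw, each carrying a `psa_draw`
#'   attribute with the sampled headline values.
#' @export
sample_psa_parameters <- function(params, n_draws, seed,
                                  cv_cost = 0.2, cv_prob = 0.2,
                                  sample_or = TRUE) {
  if (n_draws < 1) abort("`n_draws` must be >= 1")
  ord <- or_distribution(params$effect)
  lapply(seq_len(n_draws), function(d) {
    withr::with_seed(derive_seed(seed, d, 11L), {
      p <- params
      if (cv_cost > 0) {
        shape <- 1 / cv_cost^2
        for (col in c("direct_cost", "oop_cost")) {
          pe <- p$states[[col]]
          pos <- pe > 0
          p$states[[col]][pos] <-
            rgamma(sum(pos), shape = shape, scale = pe[pos] * cv_cost^2)
        }
      }
      or_draw <- if (sample_or) {
        rlnorm(1, ord$meanlog, ord$sdlog)
      } else {
        params$effect$odds_ratio
      }
      p$effect$odds_ratio <- or_draw
      p$effect$ci_low <- min(p$effect$ci_low, or_draw)
      p$effect$ci_high <- max(p$effect$ci_high, or_draw)
      if (cv_prob > 0) {
        for (k in c("p_dx", "p_dt", "p_tna", "p_reinit")) {
          m <- beta_moments(p$cascade[[k]], cv_prob, paste0("cascade.", k))
          if (!is.null(m)) p$cascade[[k]] <- rbeta(1, m$a, m$b)
        }
        inc <- p$complications$untreated_incidence
        for (j in seq_along(inc)) {
          m <- beta_moments(
            inc[j], cv_prob,
            paste0("complications.", p$complications$state[j])
          )
          if (!is.null(m)) inc[j] <- rbeta(1, m$a, m$b)
        }
        p$complications$untreated_incidence <- inc
      }
      p <- validate_parameters(p)
      attr(p, "psa_draw") <- tibble(
        draw = d, odds_ratio = or_draw,
        p_dx = p$cascade$p_dx, p_tna = p$cascade$p_tna
      )
      p
    })
  })
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_draws` parameter sets, then re-runs the no-programme comparator
#' and every arm on one common cohort per draw (common random numbers within
#' a draw), recording per-person incremental cost, incremental DALYs averted
#' and INMB.
#'
#' @param n Cohort size per draw.
#' @param quintiles Eligible quintiles for the cohort.
#' @param params Base `ecea_params`.
#' @param arms Named list of [strategy()] objects (default: the three CCT
#'   arms).
#' @param n_draws Number of parameter draws (>= 2; the study used 100).
#' @param seed Master seed for parameter draws and the cohort.
#' @param cv_cost,cv_prob,sample_or Passed to [sample_psa_parameters()].
#' @return An `ecea_psa` object: `draws` tibble (draw, arm, d_cost_pp,
#'   d_daly_pp, inmb), `parameters` tibble of sampled headline values, and
#'   metadata.
#' @export
run_psa <- function(n, quintiles, params, arms = NULL, n_draws = 100,
                    seed = 1, cv_cost = 0.2, cv_prob = 0.2,
                    sample_or = TRUE) {
  if (n_draws < 2) abort("`n_draws` must be >= 2")
  if (is.null(arms)) {
    arms <- cct_strategies(quintiles)[c(
      "diagnosis_only", "treatment_only", "diagnosis_treatment"
    )]
  }
  draws <- sample_psa_parameters(
    params, n_draws, seed, cv_cost, cv_prob,
    sample_or = sample_or
  )
  cohort_seed <- derive_seed(seed, 0L, 21L)
  rows <- purrr::map_dfr(seq_len(n_draws), function(d) {
    pd <- draws[[d]]
    cohort <- generate_population(n, quintiles, pd, seed = cohort_seed)
    base <- run_strategy(
      cohort, strategy(FALSE, FALSE, quintiles), pd
    )
    purrr::map_dfr(arms, function(s) {
      r <- run_strategy(cohort, s, pd)
      sm <- summarize_ecea(base, r, ce_threshold = params$econ$ce_threshold)
      tibble(
        draw = d, arm = s$name,
        d_cost_pp = sm$d_cost_pp, d_daly_pp = sm$d_daly_pp, inmb = sm$inmb
      )
    })
  })
  structure(
    list(
      draws = rows,
      parameters = purrr::map_dfr(draws, attr, "psa_draw"),
      n = n, quintiles = quintiles, n_draws = n_draws, seed = seed,
      ce_threshold = params$econ$ce_threshold
    ),
    class = "ecea_psa"
  )
}

#' @export
print.ecea_psa <- function(x, ...) {
  cat(sprintf(
    "<ecea_psa> %d draws x %d arms, cohort n = %d\n",
    x$n_draws, length(unique(x$draws$arm)), x$n
  ))
  invisible(x)
}

#' @export
tidy.ecea_psa <- function(x, ...) x$draws

#' @export
glance.ecea_psa <- function(x, ...) {
  x$draws %>%
    group_by(.data$arm) %>%
    summarise(
      mean_inmb = mean(.data$inmb),
      inmb_lo = quantile(.data$inmb, 0.025),
      inmb_hi = quantile(.data$inmb, 0.975),
      prob_ce = mean(.data$inmb > 0),
      .groups = "drop"
    )
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability that each arm has the
#' highest net monetary benefit among the compared arms (ties resolved to the
#' first arm in the PSA's arm order).
#'
#' @param psa An `ecea_psa` object (or its `draws` tibble).
#' @param wtp_grid Willingness-to-pay values (USD per DALY averted).
#' @param include_comparator Add the no-programme comparator as an arm with
#'   zero net benefit?
#' @return An `ecea_ceac` tibble with columns `wtp`, `arm`, `probability`;
#'   probabilities across arms sum to 1 at every grid point.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 6000, by = 250),
                 include_comparator = TRUE) {
  if (length(wtp_grid) < 1) abort("`wtp_grid` must be non-empty")
  draws <- if (inherits(psa, "ecea_psa")) psa$draws else as_tibble(psa)
  arms <- unique(draws$arm)
  out <- purrr::map_dfr(wtp_grid, function(w) {
    per_draw <- draws %>%
      mutate(nmb = w * .data$d_daly_pp - .data$d_cost_pp)
    if (include_comparator) {
      per_draw <- bind_rows(
        per_draw,
        tibble(
          draw = unique(draws$draw), arm = "no_programme",
          d_cost_pp = 0, d_daly_pp = 0, nmb = 0
        )
      )
    }
    winners <- per_draw %>%
      group_by(.data$draw) %>%
      summarise(
        winner = .data$arm[which.max(.data$nmb)], .groups = "drop"
      )
    all_arms <- if (include_comparator) c(arms, "no_programme") else arms
    tibble(
      wtp = w,
      arm = all_arms,
      probability = vapply(
        all_arms, function(a) mean(winners$winner == a), numeric(1),
        USE.NAMES = FALSE
      )
    )
  })
  class(out) <- c("ecea_ceac", class(out))
  out
}

#' One-way sensitivity analysis for a single parameter
#'
#' Re-runs all arms with the parameter set to `low` and to `high` (all other
#' parameters and all random streams held fixed) and reports the INMB at both
#' ends and the absolute swing.
#'
#' @param parameter Parameter identifier as accepted by [set_parameter()].
#' @param low,high Parameter values (`low <= high`).
#' @param cohort Cohort tibble.
#' @param params Base `ecea_params`.
#' @param arms Named list of strategies (default: the three CCT arms for the
#'   cohort's quintiles).
#' @param sim_seed Simulation seed shared by every run.
#' @return An `ecea_tornado` tibble: `parameter`, `arm`, `inmb_low`,
#'   `inmb_high`, `inmb_base`, `swing`.
#' @export
one_way <- function(parameter, low, high, cohort, params, arms = NULL,
                    sim_seed = attr(cohort, "seed")) {
  if (low > high) abort("`low` must be <= `high`")
  elig <- attr(cohort, "quintiles") %||% sort(unique(cohort$quintile))
  if (is.null(arms)) {
    arms <- cct_strategies(elig)[c(
      "diagnosis_only", "treatment_only", "diagnosis_treatment"
    )]
  }
  inmb_at <- function(value) {
    pv <- set_parameter(params, parameter, value)
    base <- run_strategy(
      cohort, strategy(FALSE, FALSE, elig, "no_programme"), pv,
      sim_seed = sim_seed
    )
    vapply(arms, function(s) {
      summarize_ecea(
        base, run_strategy(cohort, s, pv, sim_seed = sim_seed),
        ce_threshold = params$econ$ce_threshold
      )$inmb
    }, numeric(1), USE.NAMES = FALSE)
  }
  base_val <- get_parameter(params, parameter)
  lo <- inmb_at(low)
  hi <- if (identical(low, high)) lo else inmb_at(high)
  bs <- if (is.numeric(base_val) && length(base_val) == 1) {
    if (identical(base_val, low)) {
      lo
    } else if (identical(base_val, high)) {
      hi
    } else {
      inmb_at(base_val)
    }
  } else {
    rep(NA_real_, length(arms))
  }
  out <- tibble(
    parameter = parameter,
    arm = vapply(arms, `[[`, "", "name", USE.NAMES = FALSE),
    inmb_low = lo,
    inmb_high = hi,
    inmb_base = bs,
    swing = abs(hi - lo)
  )
  class(out) <- c("ecea_tornado", class(out))
  out
}

#' Built-in one-way scenarios
#'
#' The study's univariate analyses: the intervention odds ratio across its
#' 95% CI applied to both uptake channels, to diagnosis uptake only, and to
#' treatment uptake only; and administrative costs of 0 versus 50% of
#' transfer outlays.
#'
#' @inheritParams one_way
#' @return An `ecea_tornado` tibble stacking all scenarios.
#' @export
tornado_scenarios <- function(cohort, params, arms = NULL,
                              sim_seed = attr(cohort, "seed")) {
  lo <- params$effect$ci_low
  hi <- params$effect$ci_high
  scen <- list(
    list("effect.odds_ratio", lo, hi),
    list("effect.or_diagnosis", lo, hi),
    list("effect.or_treatment", lo, hi),
    list("econ.admin_cost_fraction", 0, 0.5)
  )
  out <- purrr::map_dfr(scen, function(s) {
    one_way(s[[1]], s[[2]], s[[3]], cohort, params, arms, sim_seed)
  })
  class(out) <- c("ecea_tornado", class(out))
  out
}

#' Variability across regenerated populations
#'
#' Re-generates the cohort `n_pops` times with different seeds at fixed
#' parameters (the study generated 1000) and summarises the spread of the
#' per-person incremental outcomes.
#'
#' @param n_pops Number of replicate populations (>= 2).
#' @param n Cohort size per replicate.
#' @param quintiles Eligible quintiles.
#' @param params `ecea_params`.
#' @param arms Named list of strategies (default: the three CCT arms).
#' @param seed Master seed; replicate `i` uses a seed derived from
#'   `(seed, i)`.
#' @return Tibble with one row per (replicate, arm): `pop`, `arm`,
#'   `d_cost_pp`, `d_daly_pp`, `inmb`.
#' @export
population_replicates <- function(n_pops, n, quintiles, params, arms = NULL,
                                  seed = 1) {
  if (n_pops < 2) abort("`n_pops` must be >= 2")
  if (is.null(arms)) {
    arms <- cct_strategies(quintiles)[c(
      "diagnosis_only", "treatment_only", "diagnosis_treatment"
    )]
  }
  purrr::map_dfr(seq_len(n_pops), function(i) {
    cs <- derive_seed(seed, i, 31L)
    cohort <- generate_population(n, quintiles, params, seed = cs)
    base <- run_strategy(cohort, strategy(FALSE, FALSE, quintiles), params)
    purrr::map_dfr(arms, function(s) {
      sm <- summarize_ecea(base, run_strategy(cohort, s, params))
      tibble(
        pop = i, arm = s$name,
        d_cost_pp = sm$d_cost_pp, d_daly_pp = sm$d_daly_pp, inmb = sm$inmb
      )
    })
  })
}
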