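test_that("odds-ratio transform is exact, monotone and boundary-preserving", {
  # oracle: odds 0.5/(1-0.5) = 1, times 1.31, back-transformed
  expect_equal(apply_odds_ratio(0.5, 1.31), 1.31 / 2.31, tolerance = 1e-12)
  expect_equal(apply_odds_ratio(0.5, 1.31), 0.56709957, tolerance = 1e-7)
  p <- seq(0, 1, by = 0.05)
  expect_equal(apply_odds_ratio(p, 1), p)
  expect_equal(apply_odds_ratio(0, 2.5), 0)
  expect_equal(apply_odds_ratio(1, 2.5), 1)
  ors <- c(0.5, 1, 1.31, 2, 5)
  vals <- vapply(ors, function(o) apply_odds_ratio(0.3, o), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(apply_odds_ratio(1.2, 1.3), "\\[0, 1\\]")
  expect_error(apply_odds_ratio(0.5, 0), "> 0")
})

test_that("transition bundles apply transfer effects to the right channels", {
  coh <- manual_cohort(
    c("UndiagnosedDM", "UndiagnosedDM", "OralTherapy", "Healthy"),
    quintile = c(1L, 3L, 1L, 1L)
  )
  p <- PDEF
  arm_d <- strategy(TRUE, FALSE, 1)
  arm_t <- strategy(FALSE, TRUE, 1)
  none <- strategy(FALSE, FALSE, 1)

  tb_none <- build_transitions(coh, none, p)
  expect_equal(tb_none$p_diagnosis[1], p$cascade$p_dx)
  expect_equal(tb_none$p_nonadherence[3], p$cascade$p_tna)

  tb_d <- build_transitions(coh, arm_d, p)
  boosted <- apply_odds_ratio(p$cascade$p_dx, p$effect$odds_ratio)
  expect_equal(tb_d$p_diagnosis[1], boosted)
  expect_gt(tb_d$p_diagnosis[1], p$cascade$p_dx)
  expect_equal(tb_d$p_diagnosis[2], p$cascade$p_dx) # quintile 3 not eligible
  expect_equal(tb_d$p_nonadherence[3], p$cascade$p_tna) # adherence untouched
  expect_equal(
    tb_d$p_screening[4],
    apply_odds_ratio(p$cascade$p_screen, p$effect$odds_ratio)
  )

  tb_t <- build_transitions(coh, arm_t, p)
  expect_equal(tb_t$p_diagnosis[1], p$cascade$p_dx)
  expect_equal(
    tb_t$p_nonadherence[3],
    1 - apply_odds_ratio(1 - p$cascade$p_tna, p$effect$odds_ratio)
  )
  expect_lt(tb_t$p_nonadherence[3], p$cascade$p_tna)

  # therapy effect multiplies complication risk for treated individuals only
  expect_equal(tb_none$p_nephropathy[1], 0.010)
  expect_equal(tb_none$p_nephropathy[3], 0.010 * 0.30)
  expect_true(is.na(tb_none$p_nephropathy[4]))
})

test_that("a missing strata cell is reported by name", {
  p <- PDEF
  p$strata <- p$strata[
    !(p$strata$age_lo == 40 & p$strata$sex == "female" & p$strata$quintile == 1),
  ]
  coh <- manual_cohort("Healthy", age = 41L)
  expect_error(
    build_transitions(coh, strategy(FALSE, FALSE, 1), p),
    "age=41, sex=female, quintile=1"
  )
})

test_that("null dynamics freeze the cohort; certain mortality absorbs it", {
  p0 <- flat_rate_params(short_params(3),
    comp_inc = rep(0, 10)
  )
  coh <- manual_cohort(c("Healthy", "OralTherapy"))
  p0$cascade$p_tna <- 0
  p0$cascade$p_dx <- 0
  p0 <- validate_parameters(p0)
  E <- engine_state(coh, strategy(FALSE, FALSE, 1), p0)
  step_cycle(E)
  snap <- as_cohort(E)
  expect_equal(snap$state, coh$state)
  expect_true(all(snap$alive))

  p1 <- flat_rate_params(short_params(4), bg = 1)
  run <- run_strategy(coh, strategy(FALSE, FALSE, 1), p1)
  expect_true(all(run$ledger$died_cycle == 0))
  expect_true(all(run$ledger$hs_cost == 0))
  expect_true(all(run$ledger$oop_undisc == 0))
  # all remaining horizon years are lost from cycle 0
  expect_equal(
    run$ledger$dalys,
    rep(sum(discount_factor(0:3, 0.05)), 2),
    tolerance = 1e-12
  )
})

test_that("complication event frequency matches the configured incidence", {
  # untreated diabetics, no deaths: hyperglycaemia must strike at its
  # published annual incidence of 0.18
  p <- flat_rate_params(short_params(1))
  p$cascade$p_dx <- 0
  p <- validate_parameters(p)
  n <- 20000
  coh <- manual_cohort(rep("UndiagnosedDM", n))
  E <- engine_state(coh, strategy(FALSE, FALSE, 1), p)
  step_cycle(E)
  frac <- mean(as_cohort(E)$state == "Hyperglycaemia")
  se <- sqrt(0.18 * 0.82 / n)
  expect_lt(abs(frac - 0.18), 3 * se)
})

test_that("common random numbers make identical configurations identical", {
  coh <- generate_population(3000, 1, PDEF, seed = 9)
  p <- short_params(10)
  r1 <- run_strategy(coh, strategy(FALSE, FALSE, 1), p)
  r2 <- run_strategy(coh, strategy(FALSE, FALSE, 1), p)
  expect_identical(r1$ledger, r2$ledger)

  # OR = 1: behaviour identical to no-programme, so health outcomes match
  # exactly and the cost increment is exactly the transfer outlay
  p1 <- make_toy("null_effect", p)$params
  base <- run_strategy(coh, strategy(FALSE, FALSE, 1), p1)
  arm <- run_strategy(coh, strategy(TRUE, TRUE, 1), p1)
  expect_equal(arm$ledger$dalys, base$ledger$dalys, tolerance = 1e-12)
  expect_equal(arm$ledger$oop_undisc, base$ledger$oop_undisc, tolerance = 1e-12)
  expect_equal(
    arm$ledger$hs_cost - base$ledger$hs_cost,
    arm$ledger$cct_disc,
    tolerance = 1e-9
  )
})

test_that("microsimulation occupancies match the cohort-recursion oracle", {
  # homogeneous stratum: one age, sex and quintile
  n <- 20000
  p <- short_params(20)
  split <- p$baseline_cascade_split
  counts <- round(n * 0.2 * split)
  states <- c(
    rep("Healthy", n - sum(counts)),
    rep(names(STATE)[2:6], times = counts)
  )
  coh <- manual_cohort(states, age = 40L, sex = "female", quintile = 1L)
  state0 <- c(n - sum(counts), counts) / n
  for (strat in list(strategy(FALSE, FALSE, 1), strategy(TRUE, TRUE, 1))) {
    run <- run_strategy(coh, strat, p)
    emp <- run$occupancy / n
    orc <- oracle_occupancy(40L, "female", 1L, state0, strat, p)
    se <- sqrt(pmax(orc * (1 - orc), 1e-6) / n)
    expect_true(all(abs(emp - orc) <= 3 * se + 2e-4))
  }
})

test_that("a stronger effect weakly increases treated time under CRN", {
  coh <- generate_population(8000, 1, PDEF, seed = 11)
  p <- short_params(15)
  arm <- strategy(TRUE, TRUE, 1)
  base <- run_strategy(coh, arm, p)
  p_hi <- set_parameter(p, "effect.ci_high", 2.0)
  p_hi <- set_parameter(p_hi, "effect.odds_ratio", 1.8)
  high <- run_strategy(coh, arm, p_hi)
  expect_gte(
    sum(high$ledger$treated_years),
    sum(base$ledger$treated_years)
  )
  # complication risk per person-year falls with more treatment
  rate <- function(r) {
    sum(r$ledger$n_complications) / sum(r$occupancy[, 2:16])
  }
  expect_lte(rate(high), rate(base))
})
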