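test_that("discount factors follow (1+r)^-t", {
  expect_equal(discount_factor(0, 0.05), 1)
  expect_equal(discount_factor(1, 0.05), 1 / 1.05, tolerance = 1e-12)
  expect_equal(discount_factor(10, 0), 1)
  expect_error(discount_factor(-1, 0.05), ">= 0")
  expect_error(discount_factor(1, -0.05), ">= 0")
})

test_that("transfer disbursement follows the programme rules", {
  p <- PDEF
  arm_d <- strategy(TRUE, FALSE, 1)
  arm_t <- strategy(FALSE, TRUE, 1)
  expect_equal(
    disburse_cct(arm_d, p, quintile = 1L, diagnosis_visit = TRUE), 13
  )
  expect_equal(
    disburse_cct(arm_t, p, quintile = 1L, treated_year = TRUE), 51
  )
  # ineligible quintile receives nothing under any arm
  expect_equal(
    disburse_cct(
      strategy(TRUE, TRUE, 1:2), p,
      quintile = 3L, diagnosis_visit = TRUE, treated_year = TRUE
    ), 0
  )
  # screening visits pay only when the switch is on
  expect_equal(
    disburse_cct(arm_d, p, quintile = 1L, screening_visit = TRUE), 13
  )
  p_off <- p
  p_off$screening_transfers <- FALSE
  expect_equal(
    disburse_cct(arm_d, p_off, quintile = 1L, screening_visit = TRUE), 0
  )
  # treatment transfers require the treatment arm
  expect_equal(
    disburse_cct(arm_d, p, quintile = 1L, treated_year = TRUE), 0
  )
})

test_that("state accruals match the published per-state amounts", {
  # frozen environment: no deaths, onsets or complications
  base_p <- flat_rate_params(short_params(1), comp_inc = rep(0, 10))
  base_p$cascade$p_dx <- 0
  base_p$cascade$p_tna <- 0
  base_p <- validate_parameters(base_p)

  healthy <- run_strategy(
    manual_cohort("Healthy"), strategy(FALSE, FALSE, 1), base_p
  )
  expect_equal(healthy$ledger$hs_cost, 0)
  expect_equal(healthy$ledger$dalys, 0)

  oral <- run_strategy(
    manual_cohort("OralTherapy"), strategy(FALSE, FALSE, 1), base_p
  )
  expect_equal(oral$ledger$hs_cost, 185)
  expect_equal(oral$ledger$oop_undisc, 51)
  expect_equal(oral$ledger$dalys, 0.049)

  # a stroke cycle accrues the published stroke amounts, discounted
  p_stroke <- base_p
  p_stroke$horizon_years <- 2L
  p_stroke$complications$untreated_incidence <-
    c(0, 0, 0, 0, 0, 0, 1, 0, 0, 0) # stroke certain for untreated
  p_stroke <- validate_parameters(p_stroke)
  run <- run_strategy(
    manual_cohort("UndiagnosedDM"), strategy(FALSE, FALSE, 1), p_stroke
  )
  df1 <- discount_factor(1, 0.05)
  expect_equal(run$ledger$hs_cost, 0 + 2168 * df1, tolerance = 1e-12)
  expect_equal(run$ledger$oop_disc, 0 + 90 * df1, tolerance = 1e-12)
  expect_equal(
    run$ledger$dalys, 0.049 + 0.588 * df1,
    tolerance = 1e-12
  )
})

test_that("transfer outlays are conserved between payer and recipients", {
  p <- short_params(12)
  coh <- generate_population(4000, 1:2, p, seed = 13)
  p0 <- p
  p0$states$direct_cost[] <- 0 # isolate transfers in the payer ledger
  p0 <- validate_parameters(p0)
  arm <- run_strategy(coh, strategy(TRUE, TRUE, 1:2), p0)
  expect_equal(
    sum(arm$ledger$hs_cost), sum(arm$ledger$cct_disc),
    tolerance = 1e-9
  )
  # 50% administrative loading lands on the payer only
  p5 <- set_parameter(p0, "econ.admin_cost_fraction", 0.5)
  arm5 <- run_strategy(coh, strategy(TRUE, TRUE, 1:2), p5)
  expect_equal(
    sum(arm5$ledger$hs_cost), 1.5 * sum(arm5$ledger$cct_disc),
    tolerance = 1e-9
  )
  expect_equal(arm5$ledger$cct_disc, arm$ledger$cct_disc)
})

test_that("zero discounting equates discounted and raw accruals", {
  p <- short_params(8)
  p$econ$discount_rate <- 0
  p <- validate_parameters(p)
  coh <- generate_population(2000, 1, p, seed = 17)
  run <- run_strategy(coh, strategy(TRUE, TRUE, 1), p)
  expect_equal(run$ledger$oop_disc, run$ledger$oop_undisc)
  expect_equal(run$ledger$cct_disc, run$ledger$cct_undisc)
  expect_equal(run$ledger$treated_years, run$ledger$treated_years_disc)
})

test_that("per-person DALYs never exceed the discounted horizon total", {
  p <- short_params(15)
  coh <- generate_population(3000, 1:2, p, seed = 19)
  run <- run_strategy(coh, strategy(FALSE, FALSE, 1), p)
  bound <- sum(discount_factor(0:14, p$econ$discount_rate))
  expect_true(all(run$ledger$dalys <= bound + 1e-9))
})
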