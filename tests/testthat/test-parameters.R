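test_that("default parameters encode the published state economics table", {
  p <- PDEF
  row <- function(state) p$states[p$states$state == state, ]
  expect_equal(row("DiagnosedUntreated")$direct_cost, 23)
  expect_equal(row("DiagnosedUntreated")$oop_cost, 13)
  expect_equal(row("OralTherapy")$direct_cost, 185)
  expect_equal(row("OralTherapy")$oop_cost, 51)
  expect_equal(row("InsulinTherapy")$direct_cost, 277)
  expect_equal(row("CombinationTherapy")$direct_cost, 301)
  expect_equal(row("UndiagnosedDM")$disability_weight, 0.049)
  expect_equal(row("Nephropathy")$direct_cost, 1207)
  expect_equal(row("Nephropathy")$disability_weight, 1)
  expect_equal(row("Retinopathy")$direct_cost, 56)
  expect_equal(row("Neuropathy")$direct_cost, 6340)
  expect_equal(row("Neuropathy")$disability_weight, 0.133)
  expect_equal(row("Angina")$direct_cost, 16)
  expect_equal(row("Angina")$disability_weight, 0.080)
  expect_equal(row("PeripheralVascular")$disability_weight, 0.014)
  expect_equal(row("MyocardialInfarction")$direct_cost, 1291)
  expect_equal(row("MyocardialInfarction")$disability_weight, 0.432)
  expect_equal(row("Stroke")$direct_cost, 2168)
  expect_equal(row("Stroke")$oop_cost, 90)
  expect_equal(row("Stroke")$disability_weight, 0.588)
  expect_equal(row("HeartFailure")$direct_cost, 2493)
  expect_equal(row("HeartFailure")$disability_weight, 0.179)
  expect_equal(row("Hyperglycaemia")$direct_cost, 83)
  expect_equal(row("Hypoglycaemia")$direct_cost, 76)
  expect_equal(row("Healthy")$disability_weight, 0)
  expect_equal(row("DiabetesDeath")$disability_weight, 1)

  comp <- function(state) p$complications[p$complications$state == state, ]
  expect_equal(comp("Nephropathy")$untreated_incidence, 0.010)
  expect_equal(comp("Nephropathy")$therapy_effect, 0.30)
  expect_equal(comp("Retinopathy")$untreated_incidence, 0.021)
  expect_equal(comp("Retinopathy")$therapy_effect, 0.68)
  expect_equal(comp("Neuropathy")$untreated_incidence, 0.047)
  expect_equal(comp("Neuropathy")$therapy_effect, 0.94)
  expect_equal(comp("Angina")$untreated_incidence, 0.0067)
  expect_equal(comp("PeripheralVascular")$untreated_incidence, 0.0085)
  expect_equal(comp("PeripheralVascular")$therapy_effect, 0.74)
  expect_equal(comp("MyocardialInfarction")$untreated_incidence, 0.017)
  expect_equal(comp("MyocardialInfarction")$therapy_effect, 0.61)
  expect_equal(comp("Stroke")$untreated_incidence, 0.0053)
  expect_equal(comp("Stroke")$therapy_effect, 0.59)
  expect_equal(comp("HeartFailure")$untreated_incidence, 0.0033)
  expect_equal(comp("Hyperglycaemia")$untreated_incidence, 0.18)
  expect_equal(comp("Hyperglycaemia")$therapy_effect, 1)
  expect_equal(comp("Hypoglycaemia")$untreated_incidence, 0.18)
  expect_equal(comp("Hypoglycaemia")$therapy_effect, 0.68)

  expect_equal(p$econ$discount_rate, 0.05)
  expect_equal(p$econ$ce_threshold, 3015)
  expect_equal(p$econ$che_thresholds, c(0.10, 0.25, 0.40))
  expect_equal(p$econ$cct_diagnosis_amount, 13)
  expect_equal(p$econ$cct_treatment_amount, 51)
  expect_equal(p$effect$odds_ratio, 1.31)
  expect_equal(p$effect$ci_low, 1.12)
  expect_equal(p$effect$ci_high, 1.54)
  expect_equal(p$horizon_years, 45L)

  # Printed split sums to 0.999 and is renormalised on validation
  raw <- c(0.600, 0.007, 0.196, 0.036, 0.160)
  expect_equal(sum(raw), 0.999)
  expect_equal(unname(p$baseline_cascade_split), raw / 0.999)
  expect_equal(sum(p$baseline_cascade_split), 1)
})

test_that("packaged default config loads with the study constants", {
  p <- load_parameters(default_config_path())
  expect_equal(p$econ$ce_threshold, 3015)
  expect_equal(p$econ$discount_rate, 0.05)
  expect_s3_class(p$strata, "tbl_df")
})

test_that("partial configs fall back to defaults; invalid values abort", {
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(econ = list(ce_threshold = 2000)), f)
  p <- load_parameters(f)
  expect_equal(p$econ$ce_threshold, 2000)
  expect_equal(p$econ$che_thresholds, c(0.10, 0.25, 0.40))

  yaml::write_yaml(list(econ = list(discount_rate = -0.01)), f)
  expect_error(load_parameters(f), "econ.discount_rate")
  yaml::write_yaml(list(cascade = list(p_dx = 1.7)), f)
  expect_error(load_parameters(f), "cascade.p_dx")
  yaml::write_yaml(list(nonsense_key = 1), f)
  expect_error(load_parameters(f), "nonsense_key")
  expect_error(load_parameters("/nonexistent/file.yaml"), "not found")
})

test_that("parameter sets round-trip through YAML", {
  p <- load_parameters(default_config_path())
  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, f)
  p2 <- load_parameters(f)
  expect_equal(
    p2[setdiff(names(p2), "strata")],
    p[setdiff(names(p), "strata")],
    tolerance = 1e-9, ignore_attr = TRUE
  )
  expect_equal(as.data.frame(p2$strata), as.data.frame(p$strata),
    tolerance = 1e-9
  )
})

test_that("set_parameter and get_parameter address dotted identifiers", {
  p <- set_parameter(PDEF, "econ.admin_cost_fraction", 0.5)
  expect_equal(p$econ$admin_cost_fraction, 0.5)
  p <- set_parameter(PDEF, "states.direct_cost.Stroke", 999)
  expect_equal(get_parameter(p, "states.direct_cost.Stroke"), 999)
  expect_error(set_parameter(PDEF, "no.such.parameter", 1), "Valid identifiers")
})

test_that("strata synthesis is deterministic, calibrated and validated", {
  s1 <- synthesize_default_strata(PDEF, seed = 11)
  s2 <- synthesize_default_strata(PDEF, seed = 11)
  s3 <- synthesize_default_strata(PDEF, seed = 12)
  expect_identical(s1, s2)
  expect_false(isTRUE(all.equal(s1$dm_incidence, s3$dm_incidence)))

  # zero prevalence target -> zero incidence everywhere
  s0 <- synthesize_default_strata(
    PDEF,
    calibration = list(prevalence = rep(0, 5), diagnosed_fraction = 0.4)
  )
  expect_true(all(s0$dm_incidence == 0))

  # infeasible target reports the closest achievable prevalence
  expect_error(
    synthesize_default_strata(
      PDEF,
      calibration = list(prevalence = rep(0.9999, 5), diagnosed_fraction = 0.4)
    ),
    "infeasible"
  )

  # background mortality non-decreasing in age within (sex, quintile)
  mono <- s1 %>%
    dplyr::arrange(sex, quintile, age_lo) %>%
    dplyr::group_by(sex, quintile) %>%
    dplyr::summarise(ok = all(diff(bg_mortality) >= 0), .groups = "drop")
  expect_true(all(mono$ok))

  # a missing cell is rejected with the cell named
  p_bad <- PDEF
  p_bad$strata <- p_bad$strata[
    !(p_bad$strata$age_lo == 40 & p_bad$strata$sex == "female" &
      p_bad$strata$quintile == 1),
  ]
  expect_error(validate_parameters(p_bad), "age_lo=40")
})
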