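test_that("degenerate uncertainty reproduces the point estimate", {
  draws <- sample_psa_parameters(PDEF, 2, seed = 1,
    cv_cost = 0, cv_prob = 0, sample_or = FALSE
  )
  for (d in draws) {
    expect_equal(d$states, PDEF$states)
    expect_equal(d$cascade, PDEF$cascade)
    expect_equal(d$effect$odds_ratio, PDEF$effect$odds_ratio)
  }
  p <- short_params(6)
  psa <- run_psa(500, 1, p,
    n_draws = 2, seed = 3,
    cv_cost = 0, cv_prob = 0, sample_or = FALSE
  )
  wide <- tidyr::pivot_wider(psa$draws,
    names_from = "draw", values_from = c("d_cost_pp", "d_daly_pp", "inmb")
  )
  expect_equal(wide$inmb_1, wide$inmb_2)
  expect_equal(wide$d_cost_pp_1, wide$d_cost_pp_2)
})

test_that("sampled odds ratios reproduce the published 95% interval", {
  draws <- sample_psa_parameters(PDEF, 4000, seed = 5, cv_cost = 0, cv_prob = 0)
  ors <- vapply(draws, function(d) d$effect$odds_ratio, numeric(1))
  qs <- quantile(ors, c(0.025, 0.975))
  expect_lt(abs(qs[[1]] - 1.12), 0.02)
  expect_lt(abs(qs[[2]] - 1.54), 0.03)
  expect_true(all(ors > 0))
})

test_that("PSA is deterministic given its seed", {
  p <- short_params(5)
  a <- run_psa(300, 1, p, n_draws = 3, seed = 11)
  b <- run_psa(300, 1, p, n_draws = 3, seed = 11)
  expect_equal(a$draws, b$draws)
})

test_that("beta moment matching rejects infeasible dispersion", {
  expect_error(
    sample_psa_parameters(PDEF, 1, seed = 1, cv_prob = 3),
    "infeasible"
  )
})

test_that("acceptability curves partition probability across arms", {
  draws <- tibble::tibble(
    draw = rep(1:50, each = 2),
    arm = rep(c("a", "b"), 50),
    d_cost_pp = rep(c(10, 20), 50),
    d_daly_pp = rep(c(0.001, 0.01), 50)
  )
  cc <- ceac(draws, wtp_grid = c(0, 2000, 5000), include_comparator = FALSE)
  sums <- tapply(cc$probability, cc$wtp, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # arm a dominates at wtp 0 (cheaper), b at high wtp
  expect_equal(cc$probability[cc$wtp == 0 & cc$arm == "a"], 1)
  expect_equal(cc$probability[cc$wtp == 5000 & cc$arm == "b"], 1)
  # with the comparator, nobody beats zero net benefit at wtp 0
  cc2 <- ceac(draws, wtp_grid = c(0), include_comparator = TRUE)
  expect_equal(cc2$probability[cc2$arm == "no_programme"], 1)
  expect_error(ceac(draws, wtp_grid = numeric(0)), "non-empty")
})

test_that("one-way analysis: zero swing at equal bounds, admin closed form", {
  p <- short_params(10)
  coh <- generate_population(1500, 1, p, seed = 47)
  tor <- one_way("effect.odds_ratio", 1.31, 1.31, coh, p)
  expect_equal(tor$swing, rep(0, 3))
  expect_equal(tor$inmb_low, tor$inmb_high)
  expect_error(one_way("bogus.param", 0, 1, coh, p), "Valid identifiers")

  # administrative loading reduces INMB by exactly admin x transfer outlay pp
  arm <- strategy(TRUE, TRUE, 1)
  base0 <- run_strategy(coh, strategy(FALSE, FALSE, 1), p)
  arm0 <- run_strategy(coh, arm, p)
  p5 <- set_parameter(p, "econ.admin_cost_fraction", 0.5)
  base5 <- run_strategy(coh, strategy(FALSE, FALSE, 1), p5)
  arm5 <- run_strategy(coh, arm, p5)
  inmb0 <- summarize_ecea(base0, arm0)$inmb
  inmb5 <- summarize_ecea(base5, arm5)$inmb
  expect_equal(
    inmb0 - inmb5, 0.5 * mean(arm0$ledger$cct_disc),
    tolerance = 1e-9
  )
})

test_that("built-in tornado scenarios cover effect and admin uncertainty", {
  p <- short_params(6)
  coh <- generate_population(800, 1, p, seed = 53)
  tor <- tornado_scenarios(coh, p)
  expect_setequal(
    unique(tor$parameter),
    c(
      "effect.odds_ratio", "effect.or_diagnosis", "effect.or_treatment",
      "econ.admin_cost_fraction"
    )
  )
  # adding administrative cost can only lower the net benefit of CCT arms
  adm <- tor[tor$parameter == "econ.admin_cost_fraction", ]
  expect_true(all(adm$inmb_high <= adm$inmb_low + 1e-9))
})

test_that("population replicates are deterministic and tighten with size", {
  p <- short_params(15)
  arms <- list(dt = strategy(TRUE, TRUE, 1))
  a <- population_replicates(2, 400, 1, p, arms = arms, seed = 59)
  b <- population_replicates(2, 400, 1, p, arms = arms, seed = 59)
  expect_equal(a, b)

  reps_small <- population_replicates(12, 800, 1, p, arms = arms, seed = 61)
  reps_large <- population_replicates(12, 6400, 1, p, arms = arms, seed = 61)
  expect_gt(sd(reps_small$d_cost_pp), sd(reps_large$d_cost_pp))
})
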