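test_that("tornado ranks swings and zero-width ranges sort last", {
  inp <- default_inputs()
  inp$sensitivity_ranges$cost_ed <- c(low = 691, high = 691)  # degenerate
  tor <- tornado("epit", inp,
                 params = c("cost_ed", "cost_hosp", "d_food_allergy",
                            "epit.p_tx_anaphylaxis", "cost_ofc"),
                 outcome = "icer")
  expect_equal(nrow(tor), 5)
  expect_true(all(diff(tor$swing) <= 0))        # widest first
  expect_equal(tor$swing[tor$param == "cost_ed"], 0)
  expect_identical(tor$param[nrow(tor)] %in% c("cost_ed", "cost_ofc"), TRUE)
  # cost_ofc is never charged under the biomarker assessment: zero swing
  expect_equal(tor$swing[tor$param == "cost_ofc"], 0)
  # the utility decrement is a dominant lever
  expect_gt(tor$swing[tor$param == "d_food_allergy"], 0)
  expect_error(tornado("epit", inp, params = "not_a_param"),
               "no declared sensitivity range")
})

test_that("treated-utility axes sweep through the scenario layer", {
  inp <- default_inputs()
  tor <- tornado("epit", inp, params = "epit.d_treated", outcome = "icer")
  # a smaller treated decrement (better treated state) lowers the ICER;
  # the high end of the published range coincides with the base value
  expect_lt(tor$outcome_low, tor$outcome_base)
  expect_gte(tor$outcome_high, tor$outcome_base)
  expect_gt(tor$swing, 0)
})

test_that("removing discounting raises undiscounted lifetime QALYs", {
  inp <- default_inputs()
  q_disc <- run_cohort(build_strategy("none", inp))$mean_qaly
  q_undisc <- run_cohort(build_strategy("none",
    set_input(inp, "discount_rate", 0)))$mean_qaly
  expect_gt(q_undisc, q_disc)
})

test_that("ceiling price rises monotonically with treated utility", {
  inp <- default_inputs()
  surf <- utility_cost_surface("epit", inp,
                               utility_grid = c(0.92, 0.94, 0.96, 0.98))
  expect_true(all(surf$flag == "ok"))
  expect_true(all(diff(surf$ceiling_price) > 0))
  # treated state no better than untreated: nothing to pay for
  flat <- utility_cost_surface("epit", inp, utility_grid = 0.91)
  expect_identical(flat$flag, "no_positive_ceiling")
  expect_true(is.na(flat$ceiling_price))
})

test_that("risk-reduction grid is consistent with the base case", {
  inp <- default_inputs()
  sw <- risk_reduction_sweep(inp, base_rate_axis = c(0.01, 0.04, 0.07),
                             rr_epit_axis = c(1.0, 0.5))
  expect_equal(nrow(sw), 3 * 3)  # (2 EPIT rr + 1 POIT row) per base rate
  # rr = 1 at the base 1%/yr rate reproduces the base-case EPIT ICER
  base <- scenario_report("base", inp, engine = "cohort")
  cell <- sw[sw$arm == "epit" & sw$rr == 1 & sw$base_rate == 0.01, ]
  expect_equal(cell$icer, base$comparisons$epit$icer, tolerance = 1e-9)
  # with protection (rr < 1), more baseline risk means more averted harm
  epit_rr05 <- sw[sw$arm == "epit" & sw$rr == 0.5, ]
  expect_true(all(diff(epit_rr05$icer[order(epit_rr05$base_rate)]) < 0))
})

test_that("degenerate PSA distributions collapse to the base case", {
  inp <- default_inputs()
  params <- c("cost_hosp", "p_ed_anaphylaxis", "d_food_allergy")
  for (p in params) {
    point <- get_input(inp, p)
    inp$sensitivity_ranges[[p]] <- c(low = point, high = point)
  }
  res <- run_psa(inp, psa_spec(n_iter = 4, seed = 9, params = params))
  base <- run_cohort(build_strategy("none", inp))
  expect_true(all(abs(res$iterations$cost_none - base$mean_cost) < 1e-9))
  expect_true(all(abs(res$iterations$qaly_none - base$mean_qaly) < 1e-9))
})

test_that("PSA draws respect their declared ranges and CEAC is monotone", {
  inp <- default_inputs()
  res <- run_psa(inp, psa_spec(n_iter = 40, seed = 11))
  for (p in res$params) {
    rg <- inp$sensitivity_ranges[[p]]
    expect_true(all(res$iterations[[p]] >= rg[["low"]] &
                      res$iterations[[p]] <= rg[["high"]]), label = p)
  }
  # cost-effectiveness acceptability is non-decreasing in willingness-to-pay
  it <- res$iterations
  frac_ce <- vapply(c(0, 5e4, 1e5, 5e5, 2e6), function(lambda) {
    mean((lambda * it$qaly_epit - it$cost_epit >=
            lambda * it$qaly_none - it$cost_none) |
           (lambda * it$qaly_poit - it$cost_poit >=
              lambda * it$qaly_none - it$cost_none))
  }, 0)
  expect_true(all(diff(frac_ce) >= 0))
})

test_that("beta-family PSA stays in range too", {
  inp <- default_inputs()
  res <- run_psa(inp, psa_spec(n_iter = 25, seed = 2, family = "beta",
                               params = c("p_ed_anaphylaxis",
                                          "p_hosp_given_ed", "cost_hosp")))
  for (p in res$params) {
    rg <- inp$sensitivity_ranges[[p]]
    expect_true(all(res$iterations[[p]] >= rg[["low"]] &
                      res$iterations[[p]] <= rg[["high"]]), label = p)
  }
})

test_that("the base preset is the identity scenario", {
  inp <- default_inputs()
  rep_base <- scenario_report("base", inp, engine = "cohort")
  direct <- run_cohort(build_strategy("none", inp))
  expect_equal(rep_base$results$none$mean_cost, direct$mean_cost)
  expect_equal(rep_base$results$none$mean_qaly, direct$mean_qaly)
  expect_error(scenario_report("utopia", inp), "unknown preset")
  # every shipped preset runs on the cohort engine
  for (p in names(scenario_presets())) {
    r <- scenario_report(p, inp, engine = "cohort")
    expect_s3_class(r, "ce_report")
    expect_equal(nrow(r$table), 3)
  }
})
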