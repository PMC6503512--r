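test_that("arms compile to the expected state machines", {
  inp <- default_inputs()
  none <- build_strategy("none", inp)
  expect_setequal(none$states, c("Allergic", "Tolerant", "Dead"))
  expect_false(none$on_therapy)

  ep <- build_strategy("epit", inp)
  expect_equal(ep$p_tx, 0.034)
  expect_equal(ep$d_treated, 0.07)
  expect_equal(ep$price, rep(3839, 80))
  expect_equal(ep$assess_cost, 17)  # biomarker assessment by default

  po_ofc <- build_strategy("poit", inp, scenario_spec(responder_method = "ofc"))
  expect_equal(po_ofc$p_resp, 0.672)
  expect_equal(po_ofc$assess_cost, 121)
  ep_ofc <- build_strategy("epit", inp, scenario_spec(responder_method = "ofc"))
  expect_equal(ep_ofc$p_resp, 0.353)

  expect_error(build_strategy("sublingual", inp), "arg")
})

test_that("price schedules and treated-utility overrides apply", {
  inp <- default_inputs()
  fl <- build_strategy("poit", inp, scenario_spec(
    price_overrides = list(poit = list(year1 = 5000, subsequent = 1000))))
  expect_equal(fl$price[1:3], c(5000, 1000, 1000))
  ann <- build_strategy("epit", inp, scenario_spec(
    price_overrides = list(epit = list(annual = 1500))))
  expect_equal(ann$price, rep(1500, 80))
  tu <- build_strategy("epit", inp, scenario_spec(
    treated_utility = c(epit = 0.98, poit = NA)))
  expect_equal(tu$d_treated, 0.02)
})

test_that("per-cycle costs reproduce the published components", {
  inp <- default_inputs()
  none <- build_strategy("none", inp)
  ep <- build_strategy("epit", inp)
  expect_equal(cycle_cost("Allergic", list(), none), 3913)
  expect_equal(cycle_cost("OnTherapyMaint", list(), ep, cycle_index = 2),
               3913 + 3839)
  expect_equal(cycle_cost("OnTherapyY1", list(), ep, cycle_index = 1),
               3913 + 3839 + 17)
  expect_equal(cycle_cost("Tolerant", list(), none), 0)
  expect_equal(cycle_cost("Dead", list(), none), 0)
  expect_equal(cycle_cost("Allergic",
                          list(ed_anaphylaxis = 1, hospitalized = 1), none),
               3913 + 691 + 5899)
  expect_equal(cycle_cost("OnTherapyMaint",
                          list(tx_anaphylaxis = 1, tx_hospitalized = 1),
                          ep, cycle_index = 3),
               3913 + 3839 + 691 + 5899)
})

test_that("expectation-mode transition masses always sum to one", {
  inp <- default_inputs()
  scenarios <- list(
    scenario_spec(),
    scenario_spec(su_4yr_prob = 0.5),
    scenario_spec(responder_method = "ofc", ofc_reactive_disutility = TRUE),
    scenario_spec(spontaneous_tolerance_cum_by_20 = 0.22),
    scenario_spec(spontaneous_tolerance_cum_by_20 = 0.22,
                  spontaneous_tolerance_on_therapy = TRUE),
    scenario_spec(max_therapy_years = 10)
  )
  for (sc in scenarios) {
    for (arm in c("none", "epit", "poit")) {
      st <- build_strategy(arm, inp, sc)
      for (state in st$states) {
        for (t in c(1L, 2L, 4L, 5L)) {
          age <- inp$start_age + t - 1L
          k <- cycle_transition(state, age, t, st, mode = "expectation")
          expect_equal(sum(k$next_state), 1, tolerance = 1e-12,
                       info = paste(arm, state, t))
          expect_true(all(k$next_state >= 0))
        }
      }
    }
  }
})

test_that("expectation-mode event rates match the published probabilities", {
  inp <- degenerate_inputs()           # no mortality: isolates event rates
  inp$p_ed_anaphylaxis <- 0.01
  inp$p_accidental_reaction <- 0.07
  none <- build_strategy("none", inp)
  k <- cycle_transition("Allergic", 10, 3, none, mode = "expectation")
  expect_equal(k$events$ed_anaphylaxis, 0.01)
  expect_equal(k$events$hospitalized, 0.01 * 0.35)
  expect_equal(k$events$accidental_reaction, 0.07)

  # year-1 continuation mass = responder fraction x (1 - discontinuation)
  inp2 <- default_inputs()
  inp2$life_table <- immortal_life_table()
  inp2$fa_fatality_5_19 <- 0
  ep <- build_strategy("epit", inp2)
  k1 <- cycle_transition("OnTherapyY1", 4, 1, ep, mode = "expectation")
  expect_equal(k1$next_state[["OnTherapyMaint"]], 0.495 * (1 - 0.017))
  expect_equal(k1$next_state[["Allergic"]], 1 - 0.495 * (1 - 0.017))

  # 75% of maintenance occupancy reaches tolerance at the year-4 SU draw
  ep75 <- build_strategy("epit", inp2, scenario_spec(su_4yr_prob = 0.75))
  k4 <- cycle_transition("OnTherapyMaint", 7, 4, ep75, mode = "expectation")
  expect_equal(k4$next_state[["Tolerant"]], 0.75)
})

test_that("Dead is absorbing and stochastic mode returns valid states", {
  inp <- default_inputs()
  st <- build_strategy("epit", inp, scenario_spec(su_4yr_prob = 0.3))
  k <- cycle_transition("Dead", 50, 10, st, mode = "stochastic")
  expect_identical(k$next_state, "Dead")
  ke <- cycle_transition("Dead", 50, 10, st, mode = "expectation")
  expect_equal(ke$next_state[["Dead"]], 1)
  set.seed(99)
  states <- c("Allergic", "OnTherapyY1", "OnTherapyMaint", "Tolerant")
  for (i in 1:100) {
    s <- sample(states, 1)
    t <- sample(c(1L, 4L, 20L), 1)
    k <- cycle_transition(s, inp$start_age + t - 1L, t, st,
                          mode = "stochastic")
    expect_true(k$next_state %in% c(states, "Dead"))
    # hospitalization implies the matching anaphylaxis event
    expect_true(k$events$hospitalized <= k$events$ed_anaphylaxis)
    expect_true(k$events$tx_hospitalized <= k$events$tx_anaphylaxis)
    expect_true(k$events$died_all_cause + k$events$died_food_allergy <= 1)
  }
})
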