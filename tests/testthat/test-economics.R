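arm_res <- function(cost, qaly, arm = "x") {
  structure(list(arm = arm, mean_cost = cost, mean_qaly = qaly),
            class = "arm_result")
}

test_that("ICER arithmetic and dominance flags", {
  cmp <- icer(arm_res(101000, 25.01, "a"), arm_res(100000, 25.00, "b"))
  expect_equal(cmp$icer, 100000)
  expect_equal(cmp$status, "cost_effective_at_wtp")

  # published incrementals (rounded): 30,094 / 0.139
  cmp2 <- icer(arm_res(124568 + 30094, 26.792 + 0.139, "epit"),
               arm_res(124568, 26.792, "none"))
  expect_equal(cmp2$icer, 30094 / 0.139)
  expect_equal(round(cmp2$icer), 216504)
  expect_equal(cmp2$status, "not_cost_effective")

  dom <- icer(arm_res(2000, 10, "a"), arm_res(1000, 11, "b"))
  expect_equal(dom$status, "dominated")
  expect_true(is.na(dom$icer))
  zero <- icer(arm_res(2000, 10, "a"), arm_res(1000, 10, "b"))
  expect_true(is.na(zero$icer))
})

test_that("net monetary benefit identities", {
  expect_equal(nmb(arm_res(124568, 26.792), wtp = 100000),
               100000 * 26.792 - 124568)  # 2,554,632
  expect_equal(nmb(arm_res(5000, 10), wtp = 0), -5000)
  expect_equal(nmb(arm_res(0, 0), wtp = 100000), 0)
})

test_that("NMB ranking and dominance mapping hold on random results", {
  set.seed(20)
  for (i in 1:200) {
    a <- random_arm_result("a"); b <- random_arm_result("b")
    wtp <- stats::runif(1, 0, 3e5)
    cmp <- icer(a, b, wtp)
    # cost-effective (incl. dominant) iff NMB(a) >= NMB(b), algebraically
    expect_identical(cmp$nmb_a >= cmp$nmb_b,
                     cmp$status %in% c("cost_effective_at_wtp", "dominant"))
    # antisymmetry: swapping arms negates deltas, maps dominated<->dominant
    rev <- icer(b, a, wtp)
    expect_equal(rev$delta_cost, -cmp$delta_cost)
    expect_equal(rev$delta_qaly, -cmp$delta_qaly)
    if (cmp$status == "dominated") expect_identical(rev$status, "dominant")
    if (cmp$status == "dominant") expect_identical(rev$status, "dominated")
  }
})

test_that("ceiling price equals the flat-benefit closed form", {
  # no events, no mortality, everyone responds and continues: price and
  # QALY gain share the same annuity, so ceiling = wtp x annual utility gain
  inp <- degenerate_inputs()
  sc <- scenario_spec(responder_method = "none",
                      treated_utility = c(epit = 0.93, poit = NA))
  p <- ceiling_price("epit", inp, sc, wtp = 100000, engine = "cohort",
                     bracket = c(0, 20000), tol = 1)
  expect_equal(as.numeric(p), 0.02 * 100000, tolerance = 1)
  # halving the tolerance tightens, not moves, the answer
  p2 <- ceiling_price("epit", inp, sc, wtp = 100000, tol = 0.5)
  expect_lt(abs(as.numeric(p2) - 2000), 0.5)
  expect_equal(attr(p2, "iterations"), attr(p, "iterations") + 1L)
})

test_that("non-straddling brackets are rejected with both endpoint ICERs", {
  inp <- degenerate_inputs()
  sc <- scenario_spec(treated_utility = c(epit = 0.93, poit = NA))
  # wtp = 0 with a positive assessment cost: ICER(0) > 0 already
  expect_error(
    ceiling_price("epit", inp, sc, wtp = 0, engine = "cohort"),
    "do not straddle")
  # bracket entirely below the solution
  expect_error(
    ceiling_price("epit", inp, sc, wtp = 100000, bracket = c(0, 100)),
    "do not straddle")
})

test_that("frontier sorts, flags dominance, and finds the NMB-maximal arm", {
  # identical QALYs: the cheaper arm wins, the dearer is dominated
  f1 <- frontier(list(a = arm_res(1000, 10, "a"), b = arm_res(2000, 10, "b")),
                 wtp = 1e5)
  expect_identical(attr(f1, "nmb_max"), "a")
  expect_identical(f1$status[f1$arm == "b"], "dominated")

  # strictly increasing cost and QALY: no dominance, two frontier ICERs
  f2 <- frontier(list(a = arm_res(1000, 10, "a"),
                      b = arm_res(2000, 11, "b"),
                      c = arm_res(5000, 12, "c")), wtp = 1e5)
  expect_true(all(f2$status == "on_frontier"))
  expect_equal(sum(!is.na(f2$icer_vs_previous)), 2)
  expect_equal(f2$icer_vs_previous[f2$arm == "b"], 1000)
  expect_equal(f2$icer_vs_previous[f2$arm == "c"], 3000)

  # extended dominance: the middle arm's ICER exceeds the next one's
  f3 <- frontier(list(a = arm_res(1000, 10, "a"),
                      b = arm_res(3000, 10.1, "b"),
                      c = arm_res(3500, 12, "c")), wtp = 1e5)
  expect_identical(f3$status[f3$arm == "b"], "extended_dominated")
})
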