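#' End-of-cycle discount factor
#'
#' `(1 + rate)^(-cycle_index)`: costs and QALYs accrued during cycle `t`
#' are discounted as if booked at the end of the year.
#'
#' @param cycle_index 1-based cycle index (vectorized).
#' @param rate Annual discount rate, >= 0.
#' @return Discount factor(s).
#' @examples
#' discount_factor(1, 0.03)            # 0.9708738
#' sum(discount_factor(1:80, 0.03))    # 30.20076, the 80-year annuity
#' @export
discount_factor <- function(cycle_index, rate) {
  stopifnot(all(cycle_index >= 1), rate >= 0)
  (1 + rate)^(-cycle_index)
}

new_arm_result <- function(arm, mode, n, seed = NULL, means, sds = NULL,
                           fa_mean, fa_sd = NA_real_) {
  sdv <- function(f) if (is.null(sds)) NA_real_ else sds[[f]]
  structure(list(
    arm = arm,
    mean_cost = means$cost, sd_cost = sdv("cost"),
    mean_qaly = means$qaly, sd_qaly = sdv("qaly"),
    mean_all_anaphylaxis = means$all_ana, sd_all_anaphylaxis = sdv("all_ana"),
    mean_tx_anaphylaxis = means$tx_ana, sd_tx_anaphylaxis = sdv("tx_ana"),
    mean_mild_reactions = means$mild,
    fa_fatality_mean = fa_mean, fa_fatality_sd = fa_sd,
    n = n, seed = seed, mode = mode
  ), class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("Arm %s [%s, n=%s]: cost %.0f, QALY %.3f, anaphylaxis %.3f (therapy %.3f), FA fatality %.2g\n",
              x$arm, x$mode, format(x$n, big.mark = ""), x$mean_cost,
              x$mean_qaly, x$mean_all_anaphylaxis, x$mean_tx_anaphylaxis,
              x$fa_fatality_mean))
  invisible(x)
}

# Per-cycle state utilities for a strategy (before event tolls).
.state_u <- function(strategy, t) {
  c(Allergic = strategy$u_perfect - strategy$d_allergic,
    OnTherapyY1 = strategy$u_perfect - .treated_decrement(strategy, t),
    OnTherapyMaint = strategy$u_perfect - .treated_decrement(strategy, t),
    Tolerant = strategy$u_perfect,
    Dead = 0)
}

#' Deterministic cohort expectation engine
#'
#' Propagates exact state-occupancy masses through
#' [cycle_transition()] in expectation mode, accruing discounted expected
#' costs and QALYs and undiscounted expected event counts. This is the
#' mean-value oracle for [run_microsim()]: for any strategy, microsim means
#' converge to these values as the number of simulated persons grows.
#'
#' @param strategy A [build_strategy()] result.
#' @param init_state Optional starting state name (default: `OnTherapyY1`
#'   for therapy arms, `Allergic` otherwise).
#' @return An `arm_result` with `mode = "cohort"` (SDs are `NA`).
#' @export
run_cohort <- function(strategy, init_state = NULL) {
  sc <- strategy$scenario
  if (is.null(init_state)) {
    init_state <- if (strategy$on_therapy) "OnTherapyY1" else "Allergic"
  }
  occ <- stats::setNames(numeric(5), .ST_NAMES)
  occ[init_state] <- 1
  r <- strategy$discount_rate
  tot <- list(cost = 0, qaly = 0, all_ana = 0, tx_ana = 0, mild = 0, fa = 0)
  for (t in seq_len(strategy$horizon)) {
    age <- strategy$start_age + t - 1L
    v <- discount_factor(t, r)
    u_state <- .state_u(strategy, t)
    new_occ <- stats::setNames(numeric(5), .ST_NAMES)
    new_occ["Dead"] <- occ["Dead"]
    for (s in .ST_NAMES[.ST_NAMES != "Dead"]) {
      m <- occ[[s]]
      if (m <= 0) next
      k <- cycle_transition(s, age, t, strategy, mode = "expectation")
      ev <- k$events
      af <- 1 - ev$died_all_cause - ev$died_food_allergy
      e_ed <- ev$tx_anaphylaxis + ev$ed_anaphylaxis
      e_hosp <- ev$tx_hospitalized + ev$hospitalized
      recurring <- if (s %in% c("Allergic", "OnTherapyY1", "OnTherapyMaint")) {
        strategy$annual_cost
      } else 0
      price <- if (s %in% c("OnTherapyY1", "OnTherapyMaint")) {
        strategy$price[t]
      } else 0
      cost_pp <- af * (recurring + price) + ev$assessment_cost_incurred +
        e_ed * strategy$cost_ed + e_hosp * strategy$cost_hosp
      util_pp <- af * u_state[[s]] - e_ed * strategy$toll
      if (sc$ofc_reactive_disutility && t == 1 && s == "OnTherapyY1") {
        util_pp <- util_pp - af * (1 - strategy$p_resp) * strategy$toll
      }
      tot$cost <- tot$cost + v * m * cost_pp
      tot$qaly <- tot$qaly + v * m * util_pp
      tot$all_ana <- tot$all_ana + m * e_ed
      tot$tx_ana <- tot$tx_ana + m * ev$tx_anaphylaxis
      tot$mild <- tot$mild + m * ev$accidental_reaction
      tot$fa <- tot$fa + m * ev$died_food_allergy
      new_occ <- new_occ + m * k$next_state
    }
    occ <- new_occ
    total_mass <- sum(occ)
    if (abs(total_mass - 1) > 1e-9 || any(occ < -1e-12)) {
      stop(sprintf("cohort occupancy mass left [0,1] at cycle %d (total %.12f)",
                   t, total_mass), call. = FALSE)
    }
  }
  new_arm_result(strategy$arm, "cohort", n = 1, seed = NULL,
                 means = list(cost = tot$cost, qaly = tot$qaly,
                              all_ana = tot$all_ana, tx_ana = tot$tx_ana,
                              mild = tot$mild),
                 fa_mean = tot$fa)
}

#' Individual-level microsimulation engine
#'
#' Simulates `n` independent life courses through the strategy's annual
#' state machine, accruing per-person discounted costs and QALYs and raw
#' event counts (all ED-level anaphylaxis, therapy-associated anaphylaxis,
#' food-allergy fatality). All Bernoulli draws are independent within a
#' cycle; identical `(seed, n, strategy)` give a bit-identical result.
#' SDs use the n-1 denominator.
#'
#' @param strategy A [build_strategy()] result.
#' @param n Number of simulated persons.
#' @param seed Integer seed.
#' @param init_state Optional starting state name.
#' @return An `arm_result` with `mode = "microsim"`.
#' @export
run_microsim <- function(strategy, n = 10000, seed = 1, init_state = NULL) {
  stopifnot(n >= 1)
  set.seed(seed)
  sc <- strategy$scenario
  ST_A <- .ST[["Allergic"]]; ST_Y1 <- .ST[["OnTherapyY1"]]
  ST_M <- .ST[["OnTherapyMaint"]]; ST_T <- .ST[["Tolerant"]]
  ST_D <- .ST[["Dead"]]
  if (is.null(init_state)) {
    init_state <- if (strategy$on_therapy) "OnTherapyY1" else "Allergic"
  }
  st <- rep(.ST[[init_state]], n)
  cost <- numeric(n); qaly <- numeric(n)
  all_ana <- integer(n); tx_ana <- integer(n); mild <- integer(n)
  fa_dead <- logical(n)
  r <- strategy$discount_rate
  p_hosp <- strategy$p_hosp
  for (t in seq_len(strategy$horizon)) {
    age <- strategy$start_age + t - 1L
    v <- discount_factor(t, r)
    qa <- strategy$q[min(age, strategy$max_age) + 1L]
    mu <- .fa_rate(strategy, age)
    alive <- st != ST_D
    if (!any(alive)) break
    # (1) all-cause death
    die1 <- alive & (stats::runif(n) < qa)
    st[die1] <- ST_D
    alive <- alive & !die1
    # (2) food-allergy fatality (not Tolerant)
    risk <- alive & st != ST_T
    die2 <- risk & (stats::runif(n) < mu)
    st[die2] <- ST_D; fa_dead <- fa_dead | die2
    alive <- alive & !die2
    on_t <- alive & (st == ST_Y1 | st == ST_M)
    allerg <- alive & st == ST_A
    tol <- alive & st == ST_T
    # (3) therapy anaphylaxis, (4) accidental ED anaphylaxis, hospitalization
    txe <- on_t & (stats::runif(n) < strategy$p_tx)
    u_acc <- stats::runif(n)
    acc <- (allerg & u_acc < strategy$p_ed) |
      (on_t & u_acc < strategy$p_ed * strategy$rr)
    hosp_tx <- txe & (stats::runif(n) < p_hosp)
    hosp_acc <- acc & (stats::runif(n) < p_hosp)
    # (5) mild accidental reaction (tracked only)
    mildt <- (allerg | on_t) & (stats::runif(n) < strategy$p_mild)
    # year-1 responder/discontinuation draws (before accrual, for the
    # reactive-OFC disutility). Drawn in every arm so that runs sharing a
    # seed share their whole uniform stream (common random numbers).
    if (t == 1) {
      u_resp <- stats::runif(n)
      u_disc <- stats::runif(n)
      resp <- u_resp < strategy$p_resp
      disc <- u_disc < strategy$p_disc
    }
    # accrual
    cyc_cost <- numeric(n)
    cyc_cost[allerg | on_t] <- strategy$annual_cost
    if (strategy$on_therapy) {
      cyc_cost[on_t] <- cyc_cost[on_t] + strategy$price[t] +
        if (t == 1) strategy$assess_cost else 0
    }
    n_ed <- txe + acc
    cyc_cost <- cyc_cost + n_ed * strategy$cost_ed +
      (hosp_tx + hosp_acc) * strategy$cost_hosp
    u_state <- .state_u(strategy, t)
    uvec <- numeric(n)
    uvec[allerg] <- u_state[["Allergic"]]
    uvec[on_t] <- u_state[["OnTherapyMaint"]]
    uvec[tol] <- u_state[["Tolerant"]]
    uvec <- uvec - n_ed * strategy$toll
    if (t == 1 && strategy$on_therapy && sc$ofc_reactive_disutility) {
      uvec[on_t & !resp] <- uvec[on_t & !resp] - strategy$toll
    }
    cost <- cost + v * cyc_cost
    qaly <- qaly + v * pmax(uvec, 0)
    all_ana <- all_ana + n_ed
    tx_ana <- tx_ana + txe
    mild <- mild + mildt
    # (6) responder assessment + year-1 discontinuation
    if (t == 1 && strategy$on_therapy) {
      go_on <- on_t & resp & !disc
      if (is.finite(sc$max_therapy_years) && sc$max_therapy_years <= 1) {
        st[on_t] <- ST_A
      } else {
        st[go_on] <- ST_M
        st[on_t & !go_on] <- ST_A
      }
    }
    # (7) sustained unresponsiveness at end of therapy year 4 (the draw is
    # taken in every arm, again to keep seeded streams aligned across arms)
    if (t == sc$su_after_years) {
      u_su <- stats::runif(n)
      if (strategy$on_therapy && sc$su_4yr_prob > 0) {
        su <- (st == ST_M) & alive & (u_su < sc$su_4yr_prob)
        st[su] <- ST_T
      }
    }
    # therapy-duration cap
    if (strategy$on_therapy && is.finite(sc$max_therapy_years) &&
        t >= sc$max_therapy_years && t > 1) {
      st[alive & (st == ST_Y1 | st == ST_M)] <- ST_A
    }
    # (8) spontaneous tolerance while untreated, through age 20
    if (strategy$sp_hazard > 0 && age < strategy$sp_until_age) {
      sp <- allerg & (stats::runif(n) < strategy$sp_hazard)
      st[sp] <- ST_T
      if (sc$spontaneous_tolerance_on_therapy) {
        sp2 <- alive & st == ST_M & (stats::runif(n) < strategy$sp_hazard)
        st[sp2] <- ST_T
      }
    }
  }
  means <- list(cost = mean(cost), qaly = mean(qaly),
                all_ana = mean(all_ana), tx_ana = mean(tx_ana),
                mild = mean(mild))
  sds <- list(cost = stats::sd(cost), qaly = stats::sd(qaly),
              all_ana = stats::sd(all_ana), tx_ana = stats::sd(tx_ana))
  new_arm_result(strategy$arm, "microsim", n = n, seed = seed,
                 means = means, sds = sds,
                 fa_mean = mean(fa_dead), fa_sd = stats::sd(fa_dead))
}
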