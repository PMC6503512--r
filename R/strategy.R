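# Integer state codes shared by both engines.
.ST <- c(Allergic = 1L, OnTherapyY1 = 2L, OnTherapyMaint = 3L,
         Tolerant = 4L, Dead = 5L)
.ST_NAMES <- names(.ST)

#' Scenario specification
#'
#' A scenario bundles every structural deviation from the base case:
#' sustained unresponsiveness (SU) after year 4, the year-1 responder
#' assessment method, reactive-OFC disutility, on-therapy relative risk of
#' accidental anaphylaxis, an override of the annual ED-level anaphylaxis
#' rate, spontaneous tolerance through age 20, delayed utility benefit, a
#' cap on therapy duration, a horizon override, treated-utility overrides,
#' and per-arm price-schedule overrides.
#'
#' @param su_4yr_prob Probability of SU at the end of therapy year 4
#'   (0 = base case; the published grid is 0.25/0.50/0.75). Persons
#'   reaching SU become Tolerant: ad libitum peanut, no further allergy
#'   costs or reaction risk.
#' @param responder_method `"biomarker"` (default; year-1 continuation uses
#'   the biomarker responder fraction and charges the biomarker cost),
#'   `"ofc"` (OFC responder fraction, OFC cost), or `"none"` (all who do
#'   not discontinue continue; no assessment cost).
#' @param ofc_reactive_disutility Apply a one-cycle anaphylaxis toll to the
#'   year-1 non-responder fraction (reactive food challenge).
#' @param accidental_rr_on_therapy Relative risk of accidental ED-level
#'   anaphylaxis while on therapy; scalar or named `c(epit=, poit=)`.
#' @param base_p_ed_anaphylaxis_override Override of the annual ED-level
#'   anaphylaxis probability in all arms, or `NULL`.
#' @param spontaneous_tolerance_cum_by_20 Cumulative probability of natural
#'   tolerance by age 20, converted to a constant annual hazard applied to
#'   untreated (Allergic) persons below age 20. 0 disables.
#' @param spontaneous_tolerance_on_therapy Extend the natural-tolerance
#'   hazard to persons still on therapy at cycle end (outgrowing the
#'   allergy is a host process; they stop therapy and eat peanut ad
#'   libitum). Default `FALSE`: only untreated persons are eligible.
#' @param benefit_delay_years Therapy years before the treated utility
#'   applies (the untreated decrement is used meanwhile).
#' @param max_therapy_years Therapy stops (reverting to Allergic) after
#'   this many years; `Inf` = treat until death (default).
#' @param horizon_override Cycle-count override, or `NULL`.
#' @param treated_utility Named `c(epit=, poit=)` treated health-state
#'   utility overriding the buffer-derived value; `NA` entries keep the
#'   derived utility.
#' @param price_overrides Named list per arm, e.g.
#'   `list(poit = list(year1 = 5000, subsequent = 1000))` or
#'   `list(epit = list(annual = 1500))`.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(su_4yr_prob = 0,
                          responder_method = c("biomarker", "ofc", "none"),
                          ofc_reactive_disutility = FALSE,
                          accidental_rr_on_therapy = 1.0,
                          base_p_ed_anaphylaxis_override = NULL,
                          spontaneous_tolerance_cum_by_20 = 0,
                          spontaneous_tolerance_on_therapy = FALSE,
                          benefit_delay_years = 0,
                          max_therapy_years = Inf,
                          horizon_override = NULL,
                          treated_utility = c(epit = NA_real_, poit = NA_real_),
                          price_overrides = list()) {
  responder_method <- match.arg(responder_method)
  stopifnot(su_4yr_prob >= 0, su_4yr_prob <= 1,
            all(accidental_rr_on_therapy >= 0),
            spontaneous_tolerance_cum_by_20 >= 0,
            spontaneous_tolerance_cum_by_20 <= 1,
            benefit_delay_years >= 0, max_therapy_years >= 1)
  structure(list(
    su_4yr_prob = su_4yr_prob,
    su_after_years = 4,
    responder_method = responder_method,
    ofc_reactive_disutility = ofc_reactive_disutility,
    accidental_rr_on_therapy = accidental_rr_on_therapy,
    base_p_ed_anaphylaxis_override = base_p_ed_anaphylaxis_override,
    spontaneous_tolerance_cum_by_20 = spontaneous_tolerance_cum_by_20,
    spontaneous_tolerance_on_therapy = spontaneous_tolerance_on_therapy,
    benefit_delay_years = benefit_delay_years,
    max_therapy_years = max_therapy_years,
    horizon_override = horizon_override,
    treated_utility = treated_utility,
    price_overrides = price_overrides
  ), class = "scenario_spec")
}

#' Build a treatment-arm strategy
#'
#' Compiles an arm (`"none"`, `"epit"`, or `"poit"`) plus inputs and
#' scenario into the per-cycle state machine the engines execute: state
#' set, event probabilities, year-1 responder rule, SU and spontaneous
#' tolerance hazards, treated utility, and the price schedule.
#'
#' @param arm `"none"`, `"epit"`, or `"poit"`.
#' @param inputs A [default_inputs()]-style `peanut_inputs`.
#' @param scenario A [scenario_spec()].
#' @return A `strategy` object.
#' @export
build_strategy <- function(arm = c("none", "epit", "poit"),
                           inputs = default_inputs(),
                           scenario = scenario_spec()) {
  arm <- match.arg(arm)
  um <- utility_model(d_food_allergy = inputs$d_food_allergy,
                      kappa = inputs$kappa,
                      d_anaphylaxis_toll = inputs$d_anaphylaxis_toll)
  on_therapy <- arm != "none"
  horizon <- if (!is.null(scenario$horizon_override)) {
    scenario$horizon_override
  } else inputs$horizon_cycles
  p_ed <- if (!is.null(scenario$base_p_ed_anaphylaxis_override)) {
    scenario$base_p_ed_anaphylaxis_override
  } else inputs$p_ed_anaphylaxis

  st <- list(
    arm = arm,
    on_therapy = on_therapy,
    states = if (on_therapy) .ST_NAMES else .ST_NAMES[c(1L, 4L, 5L)],
    start_age = inputs$start_age,
    horizon = horizon,
    discount_rate = inputs$discount_rate,
    q = inputs$life_table$q,
    max_age = inputs$life_table$max_age,
    fa_fatality_5_19 = inputs$fa_fatality_5_19,
    fa_fatality_20plus = inputs$fa_fatality_20plus,
    p_ed = p_ed,
    p_mild = inputs$p_accidental_reaction,
    p_hosp = inputs$p_hosp_given_ed,
    annual_cost = sum(unlist(inputs$annual_costs)),
    cost_ed = inputs$cost_ed,
    cost_hosp = inputs$cost_hosp,
    d_allergic = inputs$d_food_allergy,
    toll = inputs$d_anaphylaxis_toll,
    u_perfect = um$u_perfect,
    um = um,
    scenario = scenario,
    rr = 1.0, p_tx = 0, p_resp = 0, p_disc = 0, assess_cost = 0,
    d_treated = inputs$d_food_allergy, price = numeric(horizon),
    sp_hazard = 0, sp_until_age = 20
  )

  if (scenario$spontaneous_tolerance_cum_by_20 > 0) {
    yrs <- max(1, st$sp_until_age - inputs$start_age)
    st$sp_hazard <- 1 - (1 - scenario$spontaneous_tolerance_cum_by_20)^(1 / yrs)
  }

  if (on_therapy) {
    tp <- inputs[[arm]]
    st$p_tx <- tp$p_tx_anaphylaxis
    st$p_disc <- tp$p_discontinue_y1
    st$p_resp <- switch(scenario$responder_method,
                        biomarker = tp$p_responder_biomarker,
                        ofc = tp$p_responder_ofc,
                        none = 1.0)
    st$assess_cost <- switch(scenario$responder_method,
                             biomarker = inputs$cost_biomarker,
                             ofc = inputs$cost_ofc,
                             none = 0)
    rr <- scenario$accidental_rr_on_therapy
    st$rr <- if (length(rr) > 1 || !is.null(names(rr))) {
      if (!arm %in% names(rr)) 1.0 else unname(rr[[arm]])
    } else unname(rr)
    tu <- scenario$treated_utility
    st$d_treated <- if (!is.null(names(tu)) && arm %in% names(tu) &&
                        !is.na(tu[[arm]])) {
      um$u_perfect - unname(tu[[arm]])
    } else protection_disutility(tp$protection_mg, um)

    po <- scenario$price_overrides[[arm]]
    y1 <- tp$price_year1; sub <- tp$price_subsequent; flat <- tp$annual_price
    if (!is.null(po)) {
      if (!is.null(po$annual)) flat <- po$annual
      if (!is.null(po$year1)) { y1 <- po$year1; sub <- po$subsequent }
    }
    st$price <- if (!is.null(y1) && !is.null(sub)) {
      c(y1, rep(sub, max(0, horizon - 1)))
    } else rep(flat, horizon)
  }
  structure(st, class = "strategy")
}

#' @export
print.strategy <- function(x, ...) {
  cat("Strategy:", x$arm, "| states:", paste(x$states, collapse = ", "),
      "| horizon", x$horizon, "cycles\n")
  invisible(x)
}

# Utility of an on-therapy person in therapy year ty (benefit delay aware).
.treated_decrement <- function(strategy, ty) {
  if (ty <= strategy$scenario$benefit_delay_years) {
    strategy$d_allergic
  } else strategy$d_treated
}

# Food-allergy fatality rate at integer age (ages <5 use the 5-19 band).
.fa_rate <- function(strategy, age) {
  if (age < 20) strategy$fa_fatality_5_19 else strategy$fa_fatality_20plus
}

#' Per-cycle cost of a state plus its events
#'
#' Dead and Tolerant states accrue nothing. Allergic and on-therapy states
#' accrue the seven annual food-allergy cost components; on-therapy states
#' add the therapy price for that therapy year, plus the year-1 responder
#' assessment cost. Each ED-level anaphylaxis event (accidental or
#' therapy-associated) adds an ED visit; each hospitalization adds the
#' hospitalization cost.
#'
#' @param state Health-state name.
#' @param events A list of event flags/counts as produced by
#'   [cycle_transition()]: uses `ed_anaphylaxis`, `tx_anaphylaxis`,
#'   `hospitalized`, `tx_hospitalized`.
#' @param strategy A [build_strategy()] result.
#' @param cycle_index 1-based cycle (therapy year for on-therapy states).
#' @return Cost in USD for the cycle (undiscounted).
#' @export
cycle_cost <- function(state, events = list(), strategy,
                       cycle_index = 1) {
  ev <- function(f) {
    x <- events[[f]]
    if (is.null(x)) 0 else as.numeric(x)
  }
  cost <- 0
  if (state %in% c("Allergic", "OnTherapyY1", "OnTherapyMaint")) {
    cost <- cost + strategy$annual_cost
  }
  if (state %in% c("OnTherapyY1", "OnTherapyMaint") && strategy$on_therapy) {
    cost <- cost + strategy$price[min(cycle_index, length(strategy$price))]
    if (cycle_index == 1) cost <- cost + strategy$assess_cost
  }
  n_ed <- ev("ed_anaphylaxis") + ev("tx_anaphylaxis")
  n_hosp <- ev("hospitalized") + ev("tx_hospitalized")
  cost + n_ed * strategy$cost_ed + n_hosp * strategy$cost_hosp
}

#' One annual cycle of the state machine
#'
#' Applies, in order: all-cause death; food-allergy fatality;
#' therapy-associated anaphylaxis; accidental ED-level anaphylaxis (35%
#' hospitalization after either); mild accidental reaction (tracked only);
#' the end-of-year-1 responder/discontinuation rule; the end-of-year-4 SU
#' draw; the therapy-duration cap; and the spontaneous-tolerance hazard.
#'
#' In `"expectation"` mode, returns the exact outgoing transition mass over
#' states plus expected per-person event counts (the cohort engine's
#' single-step kernel). In `"stochastic"` mode, draws each Bernoulli
#' independently and returns the realized next state and events.
#'
#' @param state Current health-state name.
#' @param age Integer age during the cycle.
#' @param cycle_index 1-based cycle index.
#' @param strategy A [build_strategy()] result.
#' @param mode `"expectation"` or `"stochastic"`.
#' @return A list with `next_state` (named mass vector in expectation mode,
#'   a state name in stochastic mode) and `events` (expected counts or
#'   realized flags: `died_all_cause`, `died_food_allergy`,
#'   `tx_anaphylaxis`, `tx_hospitalized`, `ed_anaphylaxis`, `hospitalized`,
#'   `accidental_reaction`, `became_tolerant`, `discontinued`,
#'   `assessment_cost_incurred`).
#' @export
cycle_transition <- function(state, age, cycle_index, strategy,
                             mode = c("expectation", "stochastic")) {
  mode <- match.arg(mode)
  if (!state %in% .ST_NAMES) stop("unknown health state: ", state, call. = FALSE)
  sc <- strategy$scenario
  zero_events <- list(died_all_cause = 0, died_food_allergy = 0,
                      tx_anaphylaxis = 0, tx_hospitalized = 0,
                      ed_anaphylaxis = 0, hospitalized = 0,
                      accidental_reaction = 0, became_tolerant = 0,
                      discontinued = 0, assessment_cost_incurred = 0)
  if (state == "Dead") {
    out <- if (mode == "expectation") {
      mass <- stats::setNames(numeric(5), .ST_NAMES); mass["Dead"] <- 1
      mass
    } else "Dead"
    return(list(next_state = out, events = zero_events))
  }

  qa <- strategy$q[min(age, strategy$max_age) + 1L]
  at_risk <- state != "Tolerant"
  mu <- if (at_risk) .fa_rate(strategy, age) else 0
  on_t <- state %in% c("OnTherapyY1", "OnTherapyMaint")
  p_acc <- if (state == "Allergic") strategy$p_ed else
    if (on_t) strategy$p_ed * strategy$rr else 0
  p_tx <- if (on_t) strategy$p_tx else 0
  p_mild <- if (at_risk) strategy$p_mild else 0

  if (mode == "expectation") {
    surv <- 1 - qa
    alive <- surv * (1 - mu)
    ev <- zero_events
    ev$died_all_cause <- qa
    ev$died_food_allergy <- surv * mu
    ev$tx_anaphylaxis <- alive * p_tx
    ev$ed_anaphylaxis <- alive * p_acc
    ev$tx_hospitalized <- ev$tx_anaphylaxis * strategy$p_hosp
    ev$hospitalized <- ev$ed_anaphylaxis * strategy$p_hosp
    ev$accidental_reaction <- alive * p_mild
    if (on_t && cycle_index == 1) ev$assessment_cost_incurred <-
        alive * strategy$assess_cost
    mass <- stats::setNames(numeric(5), .ST_NAMES)
    mass["Dead"] <- qa + surv * mu
    dest <- alive
    if (state == "OnTherapyY1" && cycle_index == 1) {
      p_cont <- strategy$p_resp * (1 - strategy$p_disc)
      if (is.finite(sc$max_therapy_years) && sc$max_therapy_years <= 1) {
        p_cont <- 0
      }
      ev$discontinued <- alive * (1 - p_cont)
      mass["OnTherapyMaint"] <- dest * p_cont
      mass["Allergic"] <- dest * (1 - p_cont)
    } else if (on_t) {
      stay <- if (on_t && cycle_index == sc$su_after_years) {
        ev$became_tolerant <- alive * sc$su_4yr_prob
        mass["Tolerant"] <- dest * sc$su_4yr_prob
        1 - sc$su_4yr_prob
      } else 1
      if (is.finite(sc$max_therapy_years) &&
          cycle_index >= sc$max_therapy_years) {
        mass["Allergic"] <- dest * stay
      } else {
        mass["OnTherapyMaint"] <- dest * stay
      }
    } else if (state == "Allergic") {
      h <- if (strategy$sp_hazard > 0 && age < strategy$sp_until_age) {
        strategy$sp_hazard
      } else 0
      ev$became_tolerant <- alive * h
      mass["Tolerant"] <- dest * h
      mass["Allergic"] <- dest * (1 - h)
    } else {
      mass["Tolerant"] <- dest
    }
    if (sc$spontaneous_tolerance_on_therapy && strategy$sp_hazard > 0 &&
        age < strategy$sp_until_age && mass[["OnTherapyMaint"]] > 0) {
      moved <- mass[["OnTherapyMaint"]] * strategy$sp_hazard
      mass["OnTherapyMaint"] <- mass[["OnTherapyMaint"]] - moved
      mass["Tolerant"] <- mass[["Tolerant"]] + moved
      ev$became_tolerant <- ev$became_tolerant + moved
    }
    return(list(next_state = mass, events = ev))
  }

  # stochastic single-person draw
  ev <- zero_events
  if (stats::runif(1) < qa) {
    ev$died_all_cause <- 1
    return(list(next_state = "Dead", events = ev))
  }
  if (at_risk && stats::runif(1) < mu) {
    ev$died_food_allergy <- 1
    return(list(next_state = "Dead", events = ev))
  }
  if (on_t && stats::runif(1) < p_tx) {
    ev$tx_anaphylaxis <- 1
    ev$tx_hospitalized <- as.numeric(stats::runif(1) < strategy$p_hosp)
  }
  if (p_acc > 0 && stats::runif(1) < p_acc) {
    ev$ed_anaphylaxis <- 1
    ev$hospitalized <- as.numeric(stats::runif(1) < strategy$p_hosp)
  }
  if (p_mild > 0 && stats::runif(1) < p_mild) ev$accidental_reaction <- 1
  nxt <- state
  if (state == "OnTherapyY1" && cycle_index == 1) {
    ev$assessment_cost_incurred <- strategy$assess_cost
    resp <- stats::runif(1) < strategy$p_resp
    disc <- stats::runif(1) < strategy$p_disc
    capped <- is.finite(sc$max_therapy_years) && sc$max_therapy_years <= 1
    if (resp && !disc && !capped) nxt <- "OnTherapyMaint" else {
      nxt <- "Allergic"; ev$discontinued <- 1
    }
  } else if (on_t) {
    if (cycle_index == sc$su_after_years &&
        stats::runif(1) < sc$su_4yr_prob) {
      nxt <- "Tolerant"; ev$became_tolerant <- 1
    } else if (is.finite(sc$max_therapy_years) &&
               cycle_index >= sc$max_therapy_years) {
      nxt <- "Allergic"
    } else nxt <- "OnTherapyMaint"
  } else if (state == "Allergic") {
    if (strategy$sp_hazard > 0 && age < strategy$sp_until_age &&
        stats::runif(1) < strategy$sp_hazard) {
      nxt <- "Tolerant"; ev$became_tolerant <- 1
    }
  }
  if (nxt == "OnTherapyMaint" && sc$spontaneous_tolerance_on_therapy &&
      strategy$sp_hazard > 0 && age < strategy$sp_until_age &&
      stats::runif(1) < strategy$sp_hazard) {
    nxt <- "Tolerant"; ev$became_tolerant <- 1
  }
  list(next_state = nxt, events = ev)
}
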