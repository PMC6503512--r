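#' Health-state utility model
#'
#' Utility constants for the model's health states. Living with untreated
#' peanut allergy carries a decrement `d_food_allergy` (0.09) below perfect
#' health; each ED-level anaphylaxis event carries an additional one-cycle
#' toll `d_anaphylaxis_toll` (0.09 per occurrence). Successful
#' immunotherapy shrinks the food-allergy decrement in proportion to the
#' protection buffer: each 100 mg of peanut protein a treated patient can
#' tolerate removes a fraction `kappa` (0.057) of the decrement. This
#' mapping was derived from the 1.61-point FAQLQ improvement observed in
#' patients able to consume 800 mg of peanut protein, scaled against
#' FAQLQ impairment in untreated food allergy. Derived treated decrements
#' are rounded to `round_treated_to` decimals (default 2) so the treated
#' health states are 0.93 (300 mg) and 0.94 (600 mg) exactly; set
#' `round_treated_to = NA` to disable rounding.
#'
#' @param u_perfect Utility of perfect health (1.0).
#' @param d_food_allergy Utility decrement of untreated peanut allergy.
#' @param kappa Fractional disutility reduction per 100 mg of protection.
#' @param d_anaphylaxis_toll One-cycle decrement per anaphylaxis event.
#' @param round_treated_to Decimal places for derived treated decrements,
#'   or `NA` for no rounding.
#' @return A `utility_model` object.
#' @export
utility_model <- function(u_perfect = 1.0, d_food_allergy = 0.09,
                          kappa = 0.057, d_anaphylaxis_toll = 0.09,
                          round_treated_to = 2) {
  stopifnot(d_food_allergy >= 0, d_food_allergy <= 1,
            kappa >= 0, kappa <= 1, d_anaphylaxis_toll >= 0)
  structure(list(u_perfect = u_perfect,
                 d_food_allergy = d_food_allergy,
                 kappa = kappa,
                 d_anaphylaxis_toll = d_anaphylaxis_toll,
                 round_treated_to = round_treated_to),
            class = "utility_model")
}

#' Utility decrement under a protection buffer
#'
#' `d = d_food_allergy * max(0, 1 - kappa * buffer_mg / 100)`, rounded per
#' the model, so a 0 mg buffer returns the full food-allergy decrement,
#' 300 mg gives 0.07, 600 mg gives 0.06, and large buffers clamp to 0.
#' Non-increasing in `buffer_mg`; vectorized over `buffer_mg`.
#'
#' @param buffer_mg Protection buffer in mg of peanut protein, >= 0.
#' @param model A [utility_model()].
#' @return Utility decrement(s) in `[0, d_food_allergy]`.
#' @examples
#' protection_disutility(c(0, 300, 600, 1800), utility_model())
#' @export
protection_disutility <- function(buffer_mg, model = utility_model()) {
  if (any(buffer_mg < 0)) stop("buffer_mg must be >= 0", call. = FALSE)
  d <- model$d_food_allergy * pmax(0, 1 - model$kappa * buffer_mg / 100)
  if (!is.na(model$round_treated_to)) d <- round(d, model$round_treated_to)
  d
}

#' Per-cycle utility of a health state
#'
#' Dead contributes 0; Tolerant, perfect health; Allergic, perfect health
#' minus the food-allergy decrement; OnTherapy, perfect health minus the
#' buffer-reduced decrement. Each anaphylaxis event this cycle subtracts one
#' toll; the result is floored at 0.
#'
#' @param state One of `"Allergic"`, `"OnTherapyY1"`, `"OnTherapyMaint"`,
#'   `"Tolerant"`, `"Dead"`.
#' @param on_therapy_buffer_mg Protection buffer for on-therapy states
#'   (ignored otherwise).
#' @param anaphylaxis_events Number of ED-level anaphylaxis events this
#'   cycle (therapy-associated plus accidental).
#' @param model A [utility_model()].
#' @return Utility in `[0, 1]`.
#' @export
state_utility <- function(state, on_therapy_buffer_mg = NULL,
                          anaphylaxis_events = 0, model = utility_model()) {
  stopifnot(anaphylaxis_events >= 0)
  u <- switch(state,
    Dead = 0,
    Tolerant = model$u_perfect,
    Allergic = model$u_perfect - model$d_food_allergy,
    OnTherapyY1 = ,
    OnTherapyMaint = model$u_perfect -
      protection_disutility(on_therapy_buffer_mg, model),
    stop("unknown health state: ", state, call. = FALSE)
  )
  if (state != "Dead") u <- u - anaphylaxis_events * model$d_anaphylaxis_toll
  max(0, u)
}
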