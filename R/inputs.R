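#' Therapy-arm parameter set
#'
#' Per-therapy clinical and pricing parameters: annual probability of
#' therapy-associated anaphylaxis, overall adverse-event rate (informational;
#' carries no cost or utility by default), first-year discontinuation,
#' year-1 responder fractions under the serologic-biomarker and oral food
#' challenge (OFC) assessments, the protection buffer in mg of peanut
#' protein that drives the utility mapping, and the annual price (optionally
#' a front-loaded year-1 / subsequent-year schedule).
#'
#' @param p_tx_anaphylaxis Annual probability of therapy-associated
#'   anaphylaxis while on therapy.
#' @param p_all_ae Probability of any treatment-emergent adverse event
#'   (tracked as data only).
#' @param p_discontinue_y1 First-year discontinuation probability.
#' @param p_responder_biomarker Year-1 responder fraction by predictive
#'   biomarker.
#' @param p_responder_ofc Year-1 responder fraction by supervised OFC.
#' @param protection_mg Protection buffer in mg of peanut protein.
#' @param annual_price Annual therapy price, USD/yr (2018 USD).
#' @param price_year1,price_subsequent Optional front-loaded price schedule;
#'   when both are given they override `annual_price`.
#' @return A `therapy_params` object.
#' @export
therapy_params <- function(p_tx_anaphylaxis, p_all_ae, p_discontinue_y1,
                           p_responder_biomarker, p_responder_ofc,
                           protection_mg, annual_price = 3839,
                           price_year1 = NULL, price_subsequent = NULL) {
  structure(list(
    p_tx_anaphylaxis = as.numeric(p_tx_anaphylaxis),
    p_all_ae = as.numeric(p_all_ae),
    p_discontinue_y1 = as.numeric(p_discontinue_y1),
    p_responder_biomarker = as.numeric(p_responder_biomarker),
    p_responder_ofc = as.numeric(p_responder_ofc),
    protection_mg = as.numeric(protection_mg),
    annual_price = as.numeric(annual_price),
    price_year1 = if (is.null(price_year1)) NULL else as.numeric(price_year1),
    price_subsequent = if (is.null(price_subsequent)) NULL else as.numeric(price_subsequent)
  ), class = "therapy_params")
}

#' Full published model input set
#'
#' Returns every model input at its published point estimate together with
#' its deterministic-sensitivity range: simulation settings (start age 4,
#' 80 annual cycles, 3%/yr discounting, willingness-to-pay $100,000/QALY,
#' 10,000 persons per arm), clinical event probabilities, food-allergy
#' fatality rates by age band, the seven annual societal cost components of
#' living with peanut allergy, acute-care and assessment costs, the utility
#' constants, EPIT/POIT therapy parameters, and the synthetic life table.
#' All monetary values are 2018 USD.
#'
#' @return A `peanut_inputs` object; `validate_inputs()` on it returns no
#'   violations.
#' @examples
#' inp <- default_inputs()
#' inp$cost_hosp                 # 5899
#' inp$epit$p_tx_anaphylaxis     # 0.034
#' sum(unlist(inp$annual_costs)) # 3913
#' @export
default_inputs <- function() {
  inputs <- list(
    start_age = 4,
    horizon_cycles = 80,
    discount_rate = 0.03,
    wtp = 100000,
    n_microsim = 10000,
    p_accidental_reaction = 0.07,
    p_ed_anaphylaxis = 0.01,
    p_hosp_given_ed = 0.35,
    fa_fatality_5_19 = 3.25e-6,
    fa_fatality_20plus = 1.81e-6,
    epit = therapy_params(
      p_tx_anaphylaxis = 0.034, p_all_ae = 0.597, p_discontinue_y1 = 0.017,
      p_responder_biomarker = 0.495, p_responder_ofc = 0.353,
      protection_mg = 300),
    poit = therapy_params(
      p_tx_anaphylaxis = 0.142, p_all_ae = 0.987, p_discontinue_y1 = 0.204,
      p_responder_biomarker = 0.672, p_responder_ofc = 0.672,
      protection_mg = 600),
    annual_costs = list(
      pediatrician = 100, allergist = 149, nutritionist = 17, alt_care = 25,
      groceries = 310, job_opportunity = 2597, epinephrine = 715),
    cost_ed = 691,
    cost_hosp = 5899,
    cost_biomarker = 17,
    cost_ofc = 121,
    d_food_allergy = 0.09,
    d_anaphylaxis_toll = 0.09,
    kappa = 0.057,
    life_table = make_life_table(),
    sensitivity_ranges = default_sensitivity_ranges()
  )
  inputs$annual_costs <- lapply(inputs$annual_costs, as.numeric)
  for (f in c("start_age", "horizon_cycles", "discount_rate", "wtp",
              "n_microsim", "p_accidental_reaction", "p_ed_anaphylaxis",
              "p_hosp_given_ed", "fa_fatality_5_19", "fa_fatality_20plus",
              "cost_ed", "cost_hosp", "cost_biomarker", "cost_ofc",
              "d_food_allergy", "d_anaphylaxis_toll", "kappa")) {
    inputs[[f]] <- as.numeric(inputs[[f]])
  }
  structure(inputs, class = "peanut_inputs")
}

# Deterministic sensitivity ranges (low, high) keyed by dotted field path.
# epit.d_treated / poit.d_treated are virtual axes: the treated utility
# decrement is derived from kappa at base but carries its own published range.
default_sensitivity_ranges <- function() {
  r <- list(
    fa_fatality_5_19 = c(3.25e-6, 33e-6),
    fa_fatality_20plus = c(1.81e-6, 18.1e-6),
    p_accidental_reaction = c(0.05, 0.45),
    p_ed_anaphylaxis = c(0.005, 0.035),
    p_hosp_given_ed = c(0.05, 0.45),
    "epit.p_tx_anaphylaxis" = c(0.01, 0.10),
    "epit.p_all_ae" = c(0.20, 0.85),
    "poit.p_tx_anaphylaxis" = c(0.05, 0.25),
    "poit.p_all_ae" = c(0.45, 0.99),
    "annual_costs.pediatrician" = c(94, 105),
    "annual_costs.allergist" = c(140, 152),
    "annual_costs.nutritionist" = c(15, 18),
    "annual_costs.alt_care" = c(22, 27),
    "annual_costs.groceries" = c(290, 330),
    "annual_costs.job_opportunity" = c(0, 2697),
    "annual_costs.epinephrine" = c(50, 1000),
    cost_biomarker = c(10, 234),
    cost_ofc = c(115, 250),
    cost_hosp = c(5000, 20000),
    cost_ed = c(689, 693),
    "epit.annual_price" = c(1200, 8000),
    "poit.annual_price" = c(1200, 8000),
    start_age = c(2, 8),
    discount_rate = c(0, 0.03),
    d_food_allergy = c(0.02, 0.11),
    "epit.d_treated" = c(0.02, 0.07),
    "poit.d_treated" = c(0.02, 0.06)
  )
  lapply(r, function(x) c(low = as.numeric(x[1]), high = as.numeric(x[2])))
}

#' Get / set a model input by dotted path
#'
#' `get_input(inputs, "epit.annual_price")` reads and
#' `set_input(inputs, "epit.annual_price", 1500)` returns a modified copy.
#' The virtual paths `epit.d_treated` / `poit.d_treated` read the derived
#' treated utility decrement; setting them is handled at the scenario layer
#' (see [scenario_spec()]), not here.
#'
#' @param inputs A `peanut_inputs`.
#' @param path Dotted field path.
#' @param value Replacement value (for `set_input`).
#' @return The value, or the modified inputs.
#' @export
get_input <- function(inputs, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (identical(parts[2], "d_treated")) {
    um <- utility_model(d_food_allergy = inputs$d_food_allergy,
                        kappa = inputs$kappa,
                        d_anaphylaxis_toll = inputs$d_anaphylaxis_toll)
    return(protection_disutility(inputs[[parts[1]]]$protection_mg, um))
  }
  x <- inputs
  for (p in parts) {
    if (is.null(x[[p]])) stop("unknown input path: ", path, call. = FALSE)
    x <- x[[p]]
  }
  x
}

#' @rdname get_input
#' @export
set_input <- function(inputs, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (identical(parts[2], "d_treated")) {
    stop("treated decrement is derived; override it via scenario_spec(treated_utility=)",
         call. = FALSE)
  }
  if (length(parts) == 1) {
    if (is.null(inputs[[parts]])) stop("unknown input path: ", path, call. = FALSE)
    inputs[[parts]] <- as.numeric(value)
  } else if (length(parts) == 2) {
    if (is.null(inputs[[parts[1]]][[parts[2]]])) {
      stop("unknown input path: ", path, call. = FALSE)
    }
    inputs[[parts[1]]][[parts[2]]] <- as.numeric(value)
  } else stop("unsupported path depth: ", path, call. = FALSE)
  inputs
}

#' Validate a model input set
#'
#' Checks every structural invariant: probabilities in `[0, 1]`, costs and
#' rates non-negative, utility decrements in `[0, 1]`, horizon at least one
#' cycle, a valid life table, and `low <= point <= high` for every declared
#' sensitivity range.
#'
#' @param inputs A `peanut_inputs`.
#' @return Character vector of violations, empty when valid. Each entry
#'   names the offending field and the rule it breaks.
#' @export
validate_inputs <- function(inputs) {
  v <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  probs <- c("p_accidental_reaction", "p_ed_anaphylaxis", "p_hosp_given_ed",
             "fa_fatality_5_19", "fa_fatality_20plus")
  for (f in probs) {
    chk(inputs[[f]] >= 0 && inputs[[f]] <= 1,
        paste0(f, ": probability must lie in [0, 1]"))
  }
  for (arm in c("epit", "poit")) {
    tp <- inputs[[arm]]
    for (f in c("p_tx_anaphylaxis", "p_all_ae", "p_discontinue_y1",
                "p_responder_biomarker", "p_responder_ofc")) {
      chk(tp[[f]] >= 0 && tp[[f]] <= 1,
          paste0(arm, ".", f, ": probability must lie in [0, 1]"))
    }
    chk(tp$protection_mg >= 0, paste0(arm, ".protection_mg: must be >= 0"))
    chk(tp$annual_price >= 0, paste0(arm, ".annual_price: must be >= 0"))
    if (!is.null(tp$price_year1)) {
      chk(tp$price_year1 >= 0 && tp$price_subsequent >= 0,
          paste0(arm, ".price_schedule: prices must be >= 0"))
    }
  }
  for (f in names(inputs$annual_costs)) {
    chk(inputs$annual_costs[[f]] >= 0,
        paste0("annual_costs.", f, ": cost must be >= 0"))
  }
  for (f in c("cost_ed", "cost_hosp", "cost_biomarker", "cost_ofc")) {
    chk(inputs[[f]] >= 0, paste0(f, ": cost must be >= 0"))
  }
  for (f in c("d_food_allergy", "d_anaphylaxis_toll", "kappa")) {
    chk(inputs[[f]] >= 0 && inputs[[f]] <= 1,
        paste0(f, ": must lie in [0, 1]"))
  }
  chk(inputs$horizon_cycles >= 1, "horizon_cycles: must be >= 1")
  chk(inputs$discount_rate >= 0, "discount_rate: must be >= 0")
  chk(inputs$wtp >= 0, "wtp: must be >= 0")
  chk(inputs$n_microsim >= 1, "n_microsim: must be >= 1")
  chk(inputs$start_age >= 0 && inputs$start_age <= inputs$life_table$max_age,
      "start_age: must lie within the life table")
  v <- c(v, validate_life_table(inputs$life_table))
  for (key in names(inputs$sensitivity_ranges)) {
    rg <- inputs$sensitivity_ranges[[key]]
    point <- tryCatch(get_input(inputs, key), error = function(e) NA_real_)
    if (!is.na(point) && !(rg[["low"]] <= point && point <= rg[["high"]])) {
      v <- c(v, paste0("sensitivity_ranges.", key,
                       ": requires low <= point <= high"))
    }
    if (rg[["low"]] > rg[["high"]]) {
      v <- c(v, paste0("sensitivity_ranges.", key, ": low > high"))
    }
  }
  v
}

#' Save / load a model input set as a config file
#'
#' The config dialect is a flat JSON object keyed by dotted field paths
#' (`"epit.annual_price": 3839`), diff-able and easy to edit for sweeps.
#' Vector-valued fields (the life-table `q`, sensitivity ranges) are stored
#' as JSON arrays. `load_config()` reconstructs a canonical
#' `peanut_inputs`; a save/load round trip is exact.
#'
#' @param inputs A `peanut_inputs`.
#' @param path File path.
#' @return `save_config` returns `path` invisibly; `load_config` a
#'   `peanut_inputs`.
#' @export
save_config <- function(inputs, path) {
  flat <- list()
  scalars <- c("start_age", "horizon_cycles", "discount_rate", "wtp",
               "n_microsim", "p_accidental_reaction", "p_ed_anaphylaxis",
               "p_hosp_given_ed", "fa_fatality_5_19", "fa_fatality_20plus",
               "cost_ed", "cost_hosp", "cost_biomarker", "cost_ofc",
               "d_food_allergy", "d_anaphylaxis_toll", "kappa")
  for (f in scalars) flat[[f]] <- inputs[[f]]
  for (arm in c("epit", "poit")) {
    tp <- inputs[[arm]]
    for (f in names(tp)) {
      if (!is.null(tp[[f]])) flat[[paste0(arm, ".", f)]] <- tp[[f]]
    }
  }
  for (f in names(inputs$annual_costs)) {
    flat[[paste0("annual_costs.", f)]] <- inputs$annual_costs[[f]]
  }
  flat[["life_table.q"]] <- inputs$life_table$q
  for (key in names(inputs$sensitivity_ranges)) {
    flat[[paste0("sensitivity.", key)]] <-
      unname(inputs$sensitivity_ranges[[key]])
  }
  # I(17) = 17 significant digits, enough for an exact double round trip
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  flat <- jsonlite::read_json(path, simplifyVector = TRUE)
  inputs <- default_inputs()
  keys <- names(flat)
  for (key in keys) {
    if (key == "life_table.q") {
      inputs$life_table <- new_life_table(as.numeric(flat[[key]]))
    } else if (startsWith(key, "sensitivity.")) {
      rk <- sub("^sensitivity\\.", "", key)
      x <- as.numeric(flat[[key]])
      inputs$sensitivity_ranges[[rk]] <- c(low = x[1], high = x[2])
    } else if (grepl("^(epit|poit)\\.", key)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      inputs[[parts[1]]][[parts[2]]] <- as.numeric(flat[[key]])
    } else if (startsWith(key, "annual_costs.")) {
      inputs$annual_costs[[sub("^annual_costs\\.", "", key)]] <-
        as.numeric(flat[[key]])
    } else {
      inputs[[key]] <- as.numeric(flat[[key]])
    }
  }
  inputs
}

#' @export
print.peanut_inputs <- function(x, ...) {
  cat("Peanut immunotherapy CEA inputs (2018 USD)\n")
  cat("  start age", x$start_age, "| horizon", x$horizon_cycles,
      "cycles | discount", x$discount_rate, "| WTP", x$wtp, "/QALY\n")
  cat("  annual allergy costs:", sum(unlist(x$annual_costs)), "USD/yr\n")
  cat("  EPIT price", x$epit$annual_price, "| POIT price",
      x$poit$annual_price, "USD/yr\n")
  invisible(x)
}
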