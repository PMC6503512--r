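# Apply a swept parameter (a dotted input path or a virtual treated-utility
# axis) to an (inputs, scenario) pair; returns the modified pair.
.apply_param <- function(inputs, scenario, name, value) {
  if (name %in% c("epit.d_treated", "poit.d_treated")) {
    arm <- sub("\\..*$", "", name)
    scenario$treated_utility[[arm]] <- 1 - value
  } else {
    inputs <- set_input(inputs, name, value)
  }
  list(inputs = inputs, scenario = scenario)
}

#' Named scenario presets
#'
#' Registry of the analysis scenarios: `base`; sustained unresponsiveness
#' grids `su25`/`su50`/`su75`; `ofc` and `ofc_disutility` (oral food
#' challenge responder assessment, without/with reactive-challenge
#' disutility); `no_responder` (all who do not discontinue continue, no
#' assessment); `frontload_poit` (POIT priced $5000 in year 1, $1000/yr
#' thereafter); `risk_reduction_50` (7%/yr ED-level anaphylaxis with a 50%
#' on-therapy risk reduction in both arms); `spontaneous_tolerance` (20%
#' cumulative natural tolerance by age 20); `benefit_delay` (treated
#' utility starts after therapy year 1); `horizon_age12` (model stops at
#' age 12).
#'
#' @return Named list of [scenario_spec()] objects.
#' @export
scenario_presets <- function() {
  list(
    base = scenario_spec(),
    su25 = scenario_spec(su_4yr_prob = 0.25),
    su50 = scenario_spec(su_4yr_prob = 0.50),
    su75 = scenario_spec(su_4yr_prob = 0.75),
    ofc = scenario_spec(responder_method = "ofc"),
    ofc_disutility = scenario_spec(responder_method = "ofc",
                                   ofc_reactive_disutility = TRUE),
    no_responder = scenario_spec(responder_method = "none"),
    frontload_poit = scenario_spec(
      price_overrides = list(poit = list(year1 = 5000, subsequent = 1000))),
    risk_reduction_50 = scenario_spec(
      base_p_ed_anaphylaxis_override = 0.07,
      accidental_rr_on_therapy = c(epit = 0.5, poit = 0.5)),
    spontaneous_tolerance = scenario_spec(
      spontaneous_tolerance_cum_by_20 = 0.20,
      spontaneous_tolerance_on_therapy = TRUE),
    benefit_delay = scenario_spec(benefit_delay_years = 1),
    horizon_age12 = scenario_spec(horizon_override = 8)
  )
}

#' Three-arm cost-effectiveness report for a scenario
#'
#' Runs all three arms under a preset (or an explicit [scenario_spec()])
#' and returns the per-arm results plus pairwise comparisons against the
#' no-immunotherapy baseline, shaped like the published summary table.
#'
#' @param preset Preset name from [scenario_presets()], or a
#'   `scenario_spec`.
#' @param inputs A `peanut_inputs`.
#' @param engine `"microsim"` or `"cohort"`.
#' @param n,seed Microsim size and seed. Arms use seeds
#'   `seed`, `seed + 1`, `seed + 2` (independent streams) unless
#'   `crn = TRUE`.
#' @param crn Common random numbers: run every arm with the same seed so
#'   the arms share mortality and accidental-event draws. Leaves each
#'   arm's marginal distribution unchanged but removes most of the
#'   between-arm noise from incremental contrasts (paired simulation),
#'   giving much sharper ICERs at the same `n`. Off by default.
#' @return A `ce_report`: list with `scenario`, `results` (named
#'   `arm_result` list), `comparisons` (named `ce_comparison` list vs
#'   no-therapy), and `table` (a [table2_df()] data.frame).
#' @export
scenario_report <- function(preset = "base", inputs = default_inputs(),
                            engine = c("microsim", "cohort"),
                            n = inputs$n_microsim, seed = 1, crn = FALSE) {
  engine <- match.arg(engine)
  if (is.character(preset)) {
    presets <- scenario_presets()
    if (!preset %in% names(presets)) {
      stop("unknown preset: ", preset, "; known: ",
           paste(names(presets), collapse = ", "), call. = FALSE)
    }
    name <- preset
    scenario <- presets[[preset]]
  } else {
    stopifnot(inherits(preset, "scenario_spec"))
    name <- "custom"
    scenario <- preset
  }
  arms <- c("none", "epit", "poit")
  results <- stats::setNames(vector("list", 3), arms)
  for (i in seq_along(arms)) {
    strat <- build_strategy(arms[i], inputs, scenario)
    results[[i]] <- if (engine == "cohort") {
      run_cohort(strat)
    } else {
      run_microsim(strat, n = n,
                   seed = if (crn) seed else seed + i - 1L)
    }
  }
  comparisons <- list(
    epit = icer(results$epit, results$none, wtp = inputs$wtp),
    poit = icer(results$poit, results$none, wtp = inputs$wtp)
  )
  structure(list(scenario_name = name, scenario = scenario,
                 engine = engine, results = results,
                 comparisons = comparisons,
                 table = table2_df(results, comparisons, wtp = inputs$wtp)),
            class = "ce_report")
}

#' @export
print.ce_report <- function(x, ...) {
  cat("Scenario:", x$scenario_name, "| engine:", x$engine, "\n")
  print(x$table, digits = 6)
  invisible(x)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' For each parameter with a declared sensitivity range, evaluates the
#' outcome (ICER of `arm` versus no immunotherapy, or the arm's NMB) at
#' the range's low and high ends with all other parameters at base, on the
#' cohort engine. Bars are sorted by swing width (widest first);
#' zero-width ranges sort last with zero swing.
#'
#' @param arm `"epit"` or `"poit"`.
#' @param inputs A `peanut_inputs`.
#' @param params Parameter names (dotted paths present in
#'   `inputs$sensitivity_ranges`); default all declared ranges.
#' @param outcome `"icer"` or `"nmb"`.
#' @param scenario A [scenario_spec()].
#' @param wtp Willingness-to-pay threshold.
#' @return A data.frame (`tornado` class) with one row per parameter:
#'   `param`, `low`, `high`, `outcome_low`, `outcome_high`,
#'   `outcome_base`, `swing`.
#' @export
tornado <- function(arm = c("epit", "poit"), inputs = default_inputs(),
                    params = names(inputs$sensitivity_ranges),
                    outcome = c("icer", "nmb"),
                    scenario = scenario_spec(), wtp = inputs$wtp) {
  arm <- match.arg(arm)
  outcome <- match.arg(outcome)
  missing_rg <- setdiff(params, names(inputs$sensitivity_ranges))
  if (length(missing_rg)) {
    stop("no declared sensitivity range for: ",
         paste(missing_rg, collapse = ", "), call. = FALSE)
  }
  eval_outcome <- function(inp, sc) {
    a <- run_cohort(build_strategy(arm, inp, sc))
    b <- run_cohort(build_strategy("none", inp, sc))
    if (outcome == "nmb") {
      nmb(a, wtp)
    } else {
      (a$mean_cost - b$mean_cost) / (a$mean_qaly - b$mean_qaly)
    }
  }
  base_val <- eval_outcome(inputs, scenario)
  rows <- lapply(params, function(p) {
    rg <- inputs$sensitivity_ranges[[p]]
    at <- function(v) {
      mod <- .apply_param(inputs, scenario, p, v)
      eval_outcome(mod$inputs, mod$scenario)
    }
    lo <- at(rg[["low"]]); hi <- at(rg[["high"]])
    data.frame(param = p, low = rg[["low"]], high = rg[["high"]],
               outcome_low = lo, outcome_high = hi,
               outcome_base = base_val, swing = abs(hi - lo),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(-df$swing), ]
  rownames(df) <- NULL
  class(df) <- c("tornado", class(df))
  df
}

#' Ceiling price as a function of treated health-state utility
#'
#' For each treated utility value on the grid, overrides the arm's treated
#' health state and solves for the value-based ceiling annual price at
#' `wtp` (cohort engine). Utilities at or below the untreated state (0.91
#' at base) have no QALY gain to pay for and are flagged `NA`.
#'
#' @param arm `"epit"` or `"poit"`.
#' @param inputs A `peanut_inputs`.
#' @param utility_grid Treated utility axis, values in `[0.90, 1.0]`.
#' @param price_grid Bracket for the price search (its range is used).
#' @param wtp Willingness-to-pay threshold.
#' @param scenario A [scenario_spec()].
#' @return A `sweep_result` data.frame: `utility`, `ceiling_price` (NA
#'   when flagged), `flag`.
#' @export
utility_cost_surface <- function(arm = c("epit", "poit"),
                                 inputs = default_inputs(),
                                 utility_grid = seq(0.92, 0.98, by = 0.01),
                                 price_grid = c(0, 20000),
                                 wtp = inputs$wtp,
                                 scenario = scenario_spec()) {
  arm <- match.arg(arm)
  stopifnot(all(utility_grid >= 0.90), all(utility_grid <= 1.0))
  rows <- lapply(utility_grid, function(u) {
    sc <- scenario
    sc$treated_utility[[arm]] <- u
    price <- tryCatch(
      as.numeric(ceiling_price(arm, inputs, sc, wtp = wtp,
                               engine = "cohort",
                               bracket = range(price_grid), tol = 1)),
      error = function(e) NA_real_)
    data.frame(utility = u, ceiling_price = price,
               flag = if (is.na(price)) "no_positive_ceiling" else "ok",
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  attr(df, "metadata") <- list(arm = arm, wtp = wtp, engine = "cohort")
  class(df) <- c("sweep_result", class(df))
  df
}

#' ICER grid over baseline anaphylaxis rate and on-therapy risk reduction
#'
#' Evaluates the ICER of each therapy versus no immunotherapy over a grid
#' of annual ED-level anaphylaxis rates and EPIT on-therapy relative
#' risks, holding the POIT relative risk fixed (cohort engine). Treated
#' health-state utilities are retained, so benefit accrues both through
#' utility and through averted reactions.
#'
#' @param inputs A `peanut_inputs`.
#' @param base_rate_axis Annual ED-level anaphylaxis probabilities.
#' @param rr_epit_axis EPIT on-therapy relative risks.
#' @param rr_poit POIT on-therapy relative risk (fixed).
#' @param wtp Willingness-to-pay threshold.
#' @return A `sweep_result` data.frame: `base_rate`, `arm`, `rr`, `icer`,
#'   `nmb`, `status` (one EPIT row per grid cell, one POIT row per base
#'   rate).
#' @export
risk_reduction_sweep <- function(inputs = default_inputs(),
                                 base_rate_axis = c(0.01, 0.03, 0.05, 0.07),
                                 rr_epit_axis = c(1.0, 0.75, 0.5, 0.325),
                                 rr_poit = 0.325, wtp = inputs$wtp) {
  stopifnot(all(base_rate_axis >= 0), all(base_rate_axis <= 1),
            all(rr_epit_axis >= 0))
  rows <- list()
  for (rate in base_rate_axis) {
    cells <- c(lapply(rr_epit_axis, function(rr) list(arm = "epit", rr = rr)),
               list(list(arm = "poit", rr = rr_poit)))
    sc0 <- scenario_spec(base_p_ed_anaphylaxis_override = rate)
    base <- run_cohort(build_strategy("none", inputs, sc0))
    for (cell in cells) {
      sc <- sc0
      sc$accidental_rr_on_therapy <-
        stats::setNames(cell$rr, cell$arm)
      res <- run_cohort(build_strategy(cell$arm, inputs, sc))
      cmp <- icer(res, base, wtp = wtp)
      rows[[length(rows) + 1L]] <- data.frame(
        base_rate = rate, arm = cell$arm, rr = cell$rr,
        icer = cmp$icer, nmb = cmp$nmb_a, status = cmp$status,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  attr(df, "metadata") <- list(rr_poit = rr_poit, wtp = wtp,
                               engine = "cohort")
  class(df) <- c("sweep_result", class(df))
  df
}

#' Probabilistic sensitivity analysis specification
#'
#' @param n_iter Number of PSA iterations.
#' @param seed Integer seed.
#' @param params Parameters to sample (dotted paths with declared
#'   ranges). The default samples every declared range except the therapy
#'   annual prices and start age, which are held at base, and the treated
#'   utility decrements, which are derived from the sampled base
#'   food-allergy decrement through the protection mapping so the sampled
#'   health states stay internally coherent.
#' @param family `"triangular"` (low, mode = base, high) or `"beta"`
#'   (for probabilities only: a beta distribution moment-matched to mode =
#'   base with the range as support; other parameters fall back to
#'   triangular).
#' @return A `psa_spec` object.
#' @export
psa_spec <- function(n_iter = 1000, seed = 1, params = NULL,
                     family = c("triangular", "beta")) {
  family <- match.arg(family)
  stopifnot(n_iter >= 1)
  structure(list(n_iter = as.integer(n_iter), seed = as.integer(seed),
                 params = params, family = family),
            class = "psa_spec")
}

# Triangular(low, mode, high) sampler by inverse CDF.
rtriangular <- function(n, low, mode, high) {
  stopifnot(low <= mode, mode <= high)
  if (high == low) return(rep(low, n))
  u <- stats::runif(n)
  f <- (mode - low) / (high - low)
  ifelse(u < f,
         low + sqrt(u * (high - low) * (mode - low)),
         high - sqrt((1 - u) * (high - low) * (high - mode)))
}

.default_psa_params <- function(inputs) {
  setdiff(names(inputs$sensitivity_ranges),
          c("epit.annual_price", "poit.annual_price", "start_age",
            "epit.d_treated", "poit.d_treated"))
}

#' Probabilistic sensitivity analysis
#'
#' Samples the model parameters from their sensitivity ranges, evaluates
#' all three arms on the cohort engine per iteration, and records costs,
#' QALYs, NMB, and the NMB-maximal arm. Treated utility decrements are
#' derived each iteration from the sampled base decrement via the
#' protection mapping; therapy prices stay at base (see [psa_spec()]).
#' Every sampled value is asserted to lie inside its declared range.
#'
#' @param inputs A `peanut_inputs`.
#' @param spec A [psa_spec()].
#' @param wtp Willingness-to-pay threshold.
#' @param scenario A [scenario_spec()].
#' @return A `psa_result`: list with `iterations` (one row per iteration:
#'   sampled parameters, per-arm cost/QALY, NMB winner, cost-effectiveness
#'   of each therapy vs no-therapy at `wtp`), `acceptability` (fraction of
#'   iterations each arm maximizes NMB), `prop_therapy_cost_effective`
#'   (fraction in which EPIT or POIT beats no-therapy NMB), and metadata.
#' @export
run_psa <- function(inputs = default_inputs(), spec = psa_spec(),
                    wtp = inputs$wtp, scenario = scenario_spec()) {
  params <- if (is.null(spec$params)) .default_psa_params(inputs) else spec$params
  missing_rg <- setdiff(params, names(inputs$sensitivity_ranges))
  if (length(missing_rg)) {
    stop("no declared sensitivity range for: ",
         paste(missing_rg, collapse = ", "), call. = FALSE)
  }
  set.seed(spec$seed)
  prob_like <- function(p) {
    grepl("^p_|\\.p_", p) || p %in% c("p_hosp_given_ed", "d_food_allergy")
  }
  draws <- matrix(NA_real_, nrow = spec$n_iter, ncol = length(params),
                  dimnames = list(NULL, params))
  for (p in params) {
    rg <- inputs$sensitivity_ranges[[p]]
    point <- get_input(inputs, p)
    x <- if (spec$family == "beta" && prob_like(p) &&
             rg[["high"]] > rg[["low"]]) {
      # beta on [low, high] with mode at the base point
      m <- (point - rg[["low"]]) / (rg[["high"]] - rg[["low"]])
      k <- 8  # concentration
      a <- 1 + m * k; b <- 1 + (1 - m) * k
      rg[["low"]] + stats::rbeta(spec$n_iter, a, b) * (rg[["high"]] - rg[["low"]])
    } else {
      rtriangular(spec$n_iter, rg[["low"]], point, rg[["high"]])
    }
    stopifnot(all(x >= rg[["low"]] - 1e-12), all(x <= rg[["high"]] + 1e-12))
    draws[, p] <- pmin(pmax(x, rg[["low"]]), rg[["high"]])
  }
  arms <- c("none", "epit", "poit")
  it <- vector("list", spec$n_iter)
  for (i in seq_len(spec$n_iter)) {
    inp <- inputs
    for (p in params) inp <- set_input(inp, p, draws[i, p])
    res <- lapply(arms, function(a) {
      run_cohort(build_strategy(a, inp, scenario))
    })
    names(res) <- arms
    nmbs <- vapply(res, nmb, 0, wtp = wtp)
    it[[i]] <- data.frame(
      iteration = i,
      cost_none = res$none$mean_cost, qaly_none = res$none$mean_qaly,
      cost_epit = res$epit$mean_cost, qaly_epit = res$epit$mean_qaly,
      cost_poit = res$poit$mean_cost, qaly_poit = res$poit$mean_qaly,
      nmb_none = nmbs[["none"]], nmb_epit = nmbs[["epit"]],
      nmb_poit = nmbs[["poit"]],
      winner = arms[which.max(nmbs)],
      epit_ce = nmbs[["epit"]] >= nmbs[["none"]],
      poit_ce = nmbs[["poit"]] >= nmbs[["none"]],
      stringsAsFactors = FALSE)
  }
  iterations <- do.call(rbind, it)
  iterations <- cbind(iterations, as.data.frame(draws))
  acceptability <- vapply(arms, function(a) mean(iterations$winner == a), 0)
  structure(list(
    iterations = iterations,
    acceptability = acceptability,
    prop_therapy_cost_effective = mean(iterations$epit_ce | iterations$poit_ce),
    params = params,
    family = spec$family, seed = spec$seed, n_iter = spec$n_iter,
    wtp = wtp, engine = "cohort"
  ), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("PSA (", x$n_iter, " iterations, ", x$family,
      " distributions, seed ", x$seed, ")\n", sep = "")
  cat("  NMB-maximal arm frequency:\n")
  print(round(x$acceptability, 4))
  cat("  therapy cost-effective vs no-therapy in ",
      100 * x$prop_therapy_cost_effective, "% of iterations\n", sep = "")
  invisible(x)
}
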