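#' Net monetary benefit
#'
#' `wtp * mean_qaly - mean_cost` for an arm result at willingness-to-pay
#' `wtp` (USD per QALY).
#'
#' @param result An `arm_result` (or any list with `mean_qaly`,
#'   `mean_cost`).
#' @param wtp Willingness-to-pay threshold, USD/QALY, >= 0.
#' @return NMB in USD.
#' @export
nmb <- function(result, wtp = 100000) {
  stopifnot(wtp >= 0)
  wtp * result$mean_qaly - result$mean_cost
}

#' Pairwise incremental cost-effectiveness comparison
#'
#' Computes incremental cost and effectiveness of `intervention` over
#' `comparator` from unrounded means, the ICER, net monetary benefit of
#' both arms, and a dominance/cost-effectiveness status:
#' `dominated` (costs more, yields less), `dominant` (costs less, yields
#' more), otherwise `cost_effective_at_wtp` when NMB(intervention) >=
#' NMB(comparator), else `not_cost_effective`. The ICER is `NA` (flagged)
#' when the QALY difference is zero or under dominance.
#'
#' @param intervention,comparator `arm_result` objects from the same
#'   inputs and horizon.
#' @param wtp Willingness-to-pay threshold, USD/QALY.
#' @return A `ce_comparison` object.
#' @export
icer <- function(intervention, comparator, wtp = 100000) {
  dc <- intervention$mean_cost - comparator$mean_cost
  de <- intervention$mean_qaly - comparator$mean_qaly
  nmb_a <- nmb(intervention, wtp)
  nmb_b <- nmb(comparator, wtp)
  status <- if (dc > 0 && de < 0) {
    "dominated"
  } else if (dc < 0 && de > 0) {
    "dominant"
  } else if (nmb_a >= nmb_b) {
    "cost_effective_at_wtp"
  } else {
    "not_cost_effective"
  }
  ratio <- if (de == 0 || status %in% c("dominated", "dominant")) {
    NA_real_
  } else dc / de
  structure(list(intervention = intervention$arm,
                 comparator = comparator$arm,
                 delta_cost = dc, delta_qaly = de, icer = ratio,
                 nmb_a = nmb_a, nmb_b = nmb_b, status = status,
                 wtp = wtp),
            class = "ce_comparison")
}

#' @export
print.ce_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: dCost %.0f, dQALY %.4f, ICER %s, status %s\n",
              x$intervention, x$comparator, x$delta_cost, x$delta_qaly,
              if (is.na(x$icer)) "NA" else sprintf("%.0f", x$icer),
              x$status))
  invisible(x)
}

#' Value-based ceiling annual price
#'
#' Bisection on the therapy's annual price until the ICER versus no
#' immunotherapy equals the willingness-to-pay threshold. The ICER is
#' monotone increasing in price (the price enters only the cost side),
#' which is verified at the bracket endpoints before searching; endpoints
#' that do not straddle the threshold are an error reporting both endpoint
#' ICERs. With the microsim engine, the same seed is reused at every price
#' evaluation (common random numbers), so trajectories are identical
#' across prices and the bisection stays monotone.
#'
#' @param arm `"epit"` or `"poit"`.
#' @param inputs A `peanut_inputs`.
#' @param scenario A [scenario_spec()].
#' @param wtp Willingness-to-pay threshold, USD/QALY.
#' @param engine `"cohort"` (default; smooth and deterministic) or
#'   `"microsim"`.
#' @param n,seed Microsim size and seed (microsim engine only).
#' @param bracket Price bracket in USD/yr.
#' @param tol Price tolerance in USD.
#' @return The ceiling annual price in USD, with attributes `icer` (ICER
#'   at the returned price) and `iterations`.
#' @export
ceiling_price <- function(arm = c("epit", "poit"), inputs = default_inputs(),
                          scenario = scenario_spec(), wtp = 100000,
                          engine = c("cohort", "microsim"),
                          n = 10000, seed = 1,
                          bracket = c(0, 20000), tol = 1) {
  arm <- match.arg(arm)
  engine <- match.arg(engine)
  stopifnot(length(bracket) == 2, bracket[1] < bracket[2], tol > 0)
  run <- function(strategy) {
    if (engine == "cohort") run_cohort(strategy)
    else run_microsim(strategy, n = n, seed = seed)
  }
  base <- run(build_strategy("none", inputs, scenario))
  eval_icer <- function(price) {
    sc <- scenario
    sc$price_overrides[[arm]] <- list(annual = price)
    res <- run(build_strategy(arm, inputs, sc))
    de <- res$mean_qaly - base$mean_qaly
    if (de <= 0) {
      stop("no QALY gain over no-therapy at price ", price,
           "; ceiling price undefined", call. = FALSE)
    }
    (res$mean_cost - base$mean_cost) / de
  }
  lo <- bracket[1]; hi <- bracket[2]
  icer_lo <- eval_icer(lo); icer_hi <- eval_icer(hi)
  if (!(icer_lo <= wtp && icer_hi >= wtp)) {
    stop(sprintf(paste0("bracket endpoints do not straddle the threshold: ",
                        "ICER(%.0f)=%.0f, ICER(%.0f)=%.0f, wtp=%.0f"),
                 lo, icer_lo, hi, icer_hi, wtp), call. = FALSE)
  }
  iter <- 0L
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (eval_icer(mid) <= wtp) lo <- mid else hi <- mid
    iter <- iter + 1L
  }
  price <- (lo + hi) / 2
  structure(price, icer = eval_icer(price), iterations = iter)
}

#' Cost-effectiveness frontier over several arms
#'
#' Sorts arms by mean cost, flags strictly dominated and
#' extended-dominated arms, reports pairwise ICERs along the efficient
#' frontier, and identifies the NMB-maximal arm.
#'
#' @param arms Named list of `arm_result` objects (>= 2).
#' @param wtp Willingness-to-pay threshold, USD/QALY.
#' @return A data.frame with one row per arm (cost, QALY, NMB, status,
#'   ICER versus the previous frontier arm) and attribute `nmb_max`, the
#'   name of the NMB-maximal arm.
#' @export
frontier <- function(arms, wtp = 100000) {
  stopifnot(length(arms) >= 2)
  if (is.null(names(arms))) names(arms) <- vapply(arms, `[[`, "", "arm")
  df <- data.frame(
    arm = names(arms),
    cost = vapply(arms, `[[`, 0, "mean_cost"),
    qaly = vapply(arms, `[[`, 0, "mean_qaly"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  df$nmb <- wtp * df$qaly - df$cost
  df <- df[order(df$cost, -df$qaly), ]
  df$status <- "on_frontier"
  # strict dominance: some other arm is no worse on both axes, better on one
  for (i in seq_len(nrow(df))) {
    others <- df[-i, ]
    dom <- others$cost <= df$cost[i] & others$qaly >= df$qaly[i] &
      (others$cost < df$cost[i] | others$qaly > df$qaly[i])
    if (any(dom)) df$status[i] <- "dominated"
  }
  # extended dominance along the remaining frontier: ICERs must increase
  repeat {
    idx <- which(df$status == "on_frontier")
    if (length(idx) < 3) break
    ic <- diff(df$cost[idx]) / diff(df$qaly[idx])
    bad <- which(diff(ic) < 0)
    if (!length(bad)) break
    df$status[idx[bad[1] + 1L]] <- "extended_dominated"
  }
  df$icer_vs_previous <- NA_real_
  idx <- which(df$status == "on_frontier")
  if (length(idx) > 1) {
    df$icer_vs_previous[idx[-1]] <-
      diff(df$cost[idx]) / diff(df$qaly[idx])
  }
  attr(df, "nmb_max") <- df$arm[which.max(df$nmb)]
  rownames(df) <- NULL
  df
}
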