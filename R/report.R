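#' Summary table of per-arm results and incremental comparisons
#'
#' Builds the three-row report mirroring the published summary layout:
#' per-arm discounted mean (SD) cost and QALYs, net monetary benefit,
#' anaphylaxis trackers, food-allergy fatality, simulation size, and
#' incremental cost / effectiveness / ICER versus the no-immunotherapy
#' comparator (comparator row fields are `NA`).
#'
#' @param results Named list of `arm_result` objects; must include
#'   `"none"`.
#' @param comparisons Named list of `ce_comparison` objects keyed by arm
#'   (versus `none`); built with [icer()] when `NULL`.
#' @param wtp Willingness-to-pay used for the NMB column.
#' @return A data.frame with columns `strategy`, `mean_cost`, `sd_cost`,
#'   `mean_qaly`, `sd_qaly`, `nmb`, `all_anaphylaxis_mean`,
#'   `all_anaphylaxis_sd`, `tx_anaphylaxis_mean`, `tx_anaphylaxis_sd`,
#'   `fa_fatality`, `n`, `incremental_cost`, `incremental_effectiveness`,
#'   `icer`.
#' @export
table2_df <- function(results, comparisons = NULL, wtp = 100000) {
  stopifnot("none" %in% names(results))
  if (is.null(comparisons)) {
    comparisons <- lapply(results[setdiff(names(results), "none")],
                          icer, comparator = results$none, wtp = wtp)
  }
  row_of <- function(name) {
    x <- results[[name]]
    cmp <- comparisons[[name]]
    data.frame(
      strategy = name,
      mean_cost = x$mean_cost, sd_cost = x$sd_cost,
      mean_qaly = x$mean_qaly, sd_qaly = x$sd_qaly,
      nmb = nmb(x, wtp),
      all_anaphylaxis_mean = x$mean_all_anaphylaxis,
      all_anaphylaxis_sd = x$sd_all_anaphylaxis,
      tx_anaphylaxis_mean = x$mean_tx_anaphylaxis,
      tx_anaphylaxis_sd = x$sd_tx_anaphylaxis,
      fa_fatality = x$fa_fatality_mean,
      n = x$n,
      incremental_cost = if (is.null(cmp)) NA_real_ else cmp$delta_cost,
      incremental_effectiveness = if (is.null(cmp)) NA_real_ else cmp$delta_qaly,
      icer = if (is.null(cmp)) NA_real_ else cmp$icer,
      stringsAsFactors = FALSE)
  }
  ord <- c("none", setdiff(names(results), "none"))
  df <- do.call(rbind, lapply(ord, row_of))
  rownames(df) <- NULL
  df
}

#' Write the summary table to CSV
#'
#' Plain CSV with period decimal separator, no thousands separators, and
#' enough digits that a re-read reproduces the in-memory values to 12+
#' significant digits.
#'
#' @param results Named list of `arm_result` objects (with `"none"`), or
#'   a prebuilt [table2_df()] data.frame.
#' @param path Output CSV path.
#' @param comparisons Optional named `ce_comparison` list.
#' @param wtp Willingness-to-pay for the NMB column.
#' @return `path`, invisibly.
#' @export
write_table2 <- function(results, path, comparisons = NULL, wtp = 100000) {
  df <- if (is.data.frame(results)) results else {
    need <- c("mean_cost", "mean_qaly")
    ok <- vapply(results, function(x) all(need %in% names(x)), TRUE)
    if (!all(ok)) stop("partial results: every arm needs cost and QALY means",
                       call. = FALSE)
    table2_df(results, comparisons, wtp)
  }
  out <- df
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), "", sprintf("%.15g", x))
  })
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# Rolling 31-bit hash of a character scalar (djb2 variant); all
# intermediates stay below 2^53 so the result is exact in doubles. Enough
# to fingerprint a config.
.config_hash <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run manifest
#'
#' Fingerprint of a run: config hash, seed(s), package version, scenario
#' preset, engine, and timestamp. Two runs with the same manifest (modulo
#' timestamp) produce byte-identical outputs.
#'
#' @param inputs A `peanut_inputs`.
#' @param seed Seed(s) used.
#' @param preset Scenario preset name.
#' @param engine Engine name.
#' @return A named list.
#' @export
run_manifest <- function(inputs, seed = NA, preset = "base",
                         engine = "microsim") {
  cfg <- tempfile(fileext = ".json")
  on.exit(unlink(cfg))
  save_config(inputs, cfg)
  list(config_hash = .config_hash(paste(readLines(cfg, warn = FALSE),
                                  collapse = "\n")),
       seed = seed,
       package_version = as.character(utils::packageVersion("peanutCEA")),
       preset = preset, engine = engine,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

.cli_log <- function(...) cat(..., "\n", file = stderr())

#' Command-line entry point
#'
#' Thin subcommand dispatcher over the package's functions, usable from a
#' shell via the shim script shipped at `inst/cli/peanutcea` (or
#' `Rscript -e 'peanutCEA::cea_cli()' ...`). Subcommands:
#'
#' * `run` - three-arm report (`--preset`, `--engine cohort|microsim`,
#'   `--seed`, `--n`); writes `table2.csv`, `comparisons.json`,
#'   `manifest.json`.
#' * `ceiling` - value-based ceiling price (`--arm`, `--wtp`); writes
#'   `ceiling.json` + manifest.
#' * `tornado` - one-way sensitivity table (`--arm`, `--outcome`);
#'   writes `tornado.csv` + manifest.
#' * `psa` - probabilistic sensitivity analysis (`--iters`, `--seed`);
#'   writes `psa_iterations.csv`, `psa_summary.json` + manifest.
#' * `surface` - treated-utility / ceiling-price curve (`--arm`);
#'   writes `surface.csv` + manifest.
#'
#' Common flags: `--config FILE` (flat dotted-path JSON,
#' see [save_config()]), `--life-table FILE` (age,qx CSV), `--out DIR`.
#' Logs go to stderr; data only to files. When no `--seed` is given one
#' is drawn and logged.
#'
#' @param args Character vector of CLI arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
cea_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    .cea_cli_impl(args)
    0L
  }, error = function(e) {
    .cli_log("error:", conditionMessage(e))
    1L
  })
  invisible(status)
}

.cli_opts <- function(args) {
  opts <- list(positional = character())
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(args) || startsWith(args[i + 1L], "--")) {
        opts[[key]] <- TRUE
        i <- i + 1L
      } else {
        opts[[key]] <- args[i + 1L]
        i <- i + 2L
      }
    } else {
      opts$positional <- c(opts$positional, a)
      i <- i + 1L
    }
  }
  opts
}

.cea_cli_impl <- function(args) {
  opts <- .cli_opts(args)
  cmd <- if (length(opts$positional)) opts$positional[1] else "help"
  if (cmd %in% c("help", "--help")) {
    .cli_log("usage: peanutcea <run|ceiling|tornado|psa|surface> [flags]")
    return(invisible(NULL))
  }
  inputs <- if (!is.null(opts$config)) load_config(opts$config) else
    default_inputs()
  if (!is.null(opts[["life-table"]])) {
    inputs$life_table <- load_life_table(opts[["life-table"]])
  }
  viol <- validate_inputs(inputs)
  if (length(viol)) stop("invalid config: ", paste(viol, collapse = "; "))
  out_dir <- if (!is.null(opts$out)) opts$out else "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- if (!is.null(opts$seed)) as.integer(opts$seed) else {
    s <- sample.int(1e6, 1)
    .cli_log("no --seed given; using seed", s)
    s
  }
  engine <- if (!is.null(opts$engine)) opts$engine else "microsim"
  preset <- if (!is.null(opts$preset)) opts$preset else "base"
  n <- if (!is.null(opts$n)) as.integer(opts$n) else inputs$n_microsim
  wtp <- if (!is.null(opts$wtp)) as.numeric(opts$wtp) else inputs$wtp
  arm <- if (!is.null(opts$arm)) opts$arm else "epit"
  write_json <- function(x, file) {
    jsonlite::write_json(x, file.path(out_dir, file), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  manifest <- run_manifest(inputs, seed = seed, preset = preset,
                           engine = engine)

  if (cmd == "run") {
    t0 <- proc.time()[["elapsed"]]
    rep <- scenario_report(preset, inputs, engine = engine, n = n,
                           seed = seed)
    write_table2(rep$table, file.path(out_dir, "table2.csv"))
    write_json(lapply(rep$comparisons, unclass), "comparisons.json")
    write_json(manifest, "manifest.json")
    .cli_log(sprintf("run %s [%s, n=%d, seed=%d] in %.1fs -> %s",
                     preset, engine, n, seed,
                     proc.time()[["elapsed"]] - t0, out_dir))
  } else if (cmd == "ceiling") {
    presets <- scenario_presets()
    sc <- if (preset %in% names(presets)) presets[[preset]] else
      stop("unknown preset: ", preset)
    price <- ceiling_price(arm, inputs, sc, wtp = wtp,
                           engine = if (engine == "cohort") "cohort" else "microsim",
                           n = n, seed = seed)
    write_json(list(arm = arm, wtp = wtp,
                    ceiling_annual_price = as.numeric(price),
                    icer_at_price = attr(price, "icer")), "ceiling.json")
    write_json(manifest, "manifest.json")
    .cli_log(sprintf("ceiling %s at wtp %.0f: %.0f USD/yr", arm, wtp,
                     as.numeric(price)))
  } else if (cmd == "tornado") {
    outcome <- if (!is.null(opts$outcome)) opts$outcome else "icer"
    df <- tornado(arm, inputs, outcome = outcome, wtp = wtp)
    utils::write.csv(df, file.path(out_dir, "tornado.csv"),
                     row.names = FALSE)
    write_json(manifest, "manifest.json")
    .cli_log("tornado for", arm, "->", out_dir)
  } else if (cmd == "psa") {
    iters <- if (!is.null(opts$iters)) as.integer(opts$iters) else 1000L
    res <- run_psa(inputs, psa_spec(n_iter = iters, seed = seed), wtp = wtp)
    utils::write.csv(res$iterations,
                     file.path(out_dir, "psa_iterations.csv"),
                     row.names = FALSE)
    write_json(list(acceptability = as.list(res$acceptability),
                    prop_therapy_cost_effective =
                      res$prop_therapy_cost_effective,
                    n_iter = res$n_iter, family = res$family,
                    seed = res$seed), "psa_summary.json")
    write_json(manifest, "manifest.json")
    .cli_log("psa with", iters, "iterations ->", out_dir)
  } else if (cmd == "surface") {
    df <- utility_cost_surface(arm, inputs, wtp = wtp)
    utils::write.csv(df, file.path(out_dir, "surface.csv"),
                     row.names = FALSE)
    write_json(manifest, "manifest.json")
    .cli_log("surface for", arm, "->", out_dir)
  } else {
    stop("unknown subcommand: ", cmd)
  }
  invisible(NULL)
}
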