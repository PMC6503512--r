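test_that("summary table has the fixed column contract", {
  inp <- default_inputs()
  results <- lapply(c(none = "none", epit = "epit", poit = "poit"),
                    function(a) run_cohort(build_strategy(a, inp)))
  df <- table2_df(results, wtp = inp$wtp)
  expect_identical(names(df), c(
    "strategy", "mean_cost", "sd_cost", "mean_qaly", "sd_qaly", "nmb",
    "all_anaphylaxis_mean", "all_anaphylaxis_sd", "tx_anaphylaxis_mean",
    "tx_anaphylaxis_sd", "fa_fatality", "n",
    "incremental_cost", "incremental_effectiveness", "icer"))
  expect_equal(nrow(df), 3)
  expect_identical(df$strategy[1], "none")
  # comparator row mirrors the published "NA" convention
  expect_true(is.na(df$incremental_cost[1]))
  expect_true(is.na(df$icer[1]))
  expect_false(anyNA(df$incremental_cost[-1]))
})

test_that("CSV writer round-trips values to 12 significant digits", {
  inp <- default_inputs()
  results <- lapply(c(none = "none", epit = "epit", poit = "poit"),
                    function(a) run_cohort(build_strategy(a, inp)))
  df <- table2_df(results, wtp = inp$wtp)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_table2(results, f, wtp = inp$wtp)
  back <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_identical(names(back), names(df))
  for (col in names(df)[-1]) {
    ok <- is.na(df[[col]]) | abs(back[[col]] - df[[col]]) <=
      1e-12 * pmax(1, abs(df[[col]]))
    expect_true(all(ok), label = col)
  }
  expect_error(write_table2(list(none = list(mean_cost = 1)), f),
               "partial results")
})

test_that("CLI runs are deterministic and log to stderr only", {
  d1 <- file.path(tempdir(), "cli1"); d2 <- file.path(tempdir(), "cli2")
  unlink(c(d1, d2), recursive = TRUE)
  args <- c("run", "--preset", "base", "--engine", "microsim",
            "--n", "300", "--seed", "7")
  s1 <- cea_cli(c(args, "--out", d1))
  s2 <- cea_cli(c(args, "--out", d2))
  expect_identical(s1, 0L)
  expect_identical(s2, 0L)
  expect_identical(readLines(file.path(d1, "table2.csv")),
                   readLines(file.path(d2, "table2.csv")))
  expect_identical(readLines(file.path(d1, "comparisons.json")),
                   readLines(file.path(d2, "comparisons.json")))
  # manifests may differ only in the timestamp
  m1 <- jsonlite::read_json(file.path(d1, "manifest.json"))
  m2 <- jsonlite::read_json(file.path(d2, "manifest.json"))
  m1$timestamp <- m2$timestamp <- NULL
  expect_identical(m1, m2)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("CLI ceiling subcommand and failure modes", {
  d <- file.path(tempdir(), "cli3")
  unlink(d, recursive = TRUE)
  s <- cea_cli(c("ceiling", "--arm", "epit", "--wtp", "100000",
                 "--engine", "cohort", "--out", d))
  expect_identical(s, 0L)
  out <- jsonlite::read_json(file.path(d, "ceiling.json"))
  expect_equal(out$arm, "epit")
  expect_gt(out$ceiling_annual_price, 0)
  expect_true(file.exists(file.path(d, "manifest.json")))
  unlink(d, recursive = TRUE)

  expect_identical(cea_cli(c("run", "--preset", "not_a_preset")), 1L)
  expect_identical(cea_cli("frobnicate"), 1L)
  bad_cfg <- tempfile(fileext = ".json")
  writeLines('{"p_ed_anaphylaxis": 1.5}', bad_cfg)
  expect_identical(cea_cli(c("run", "--config", bad_cfg)), 1L)
  unlink(bad_cfg)
})

test_that("config and life-table flags feed the CLI", {
  d <- file.path(tempdir(), "cli4")
  unlink(d, recursive = TRUE)
  cfg <- tempfile(fileext = ".json")
  inp <- default_inputs()
  save_config(set_input(inp, "epit.annual_price", 1500), cfg)
  lt <- tempfile(fileext = ".csv")
  write_life_table(make_life_table(), lt)
  s <- cea_cli(c("run", "--preset", "base", "--engine", "cohort",
                 "--config", cfg, "--life-table", lt, "--out", d,
                 "--seed", "1"))
  expect_identical(s, 0L)
  df <- utils::read.csv(file.path(d, "table2.csv"))
  # cheaper EPIT price must lower the EPIT arm's mean cost
  base_cost <- run_cohort(build_strategy("epit", inp))$mean_cost
  expect_lt(df$mean_cost[df$strategy == "epit"], base_cost)
  unlink(c(d, cfg, lt), recursive = TRUE)
})
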