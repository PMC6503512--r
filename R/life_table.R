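#' Synthetic Gompertz-Makeham life table
#'
#' Builds an age-indexed vector of annual all-cause death probabilities
#' `q(a)` from a Gompertz-Makeham hazard, `h(a) = A + B * exp(c * a)`, with
#' `q(a) = 1 - exp(-h(a))`. The table is deterministic and closed at the
#' terminal age (`q(max_age) = 1`). Defaults are tuned so that survival from
#' age 4 to age 84 falls in the band typical of recent US period life tables
#' (roughly 0.45-0.70); users with a real life table can load it with
#' [load_life_table()] instead.
#'
#' @param makeham_a Age-independent background hazard (per year), > 0.
#' @param gompertz_b Gompertz scale (per year), > 0.
#' @param gompertz_c Gompertz shape (1/years), > 0.
#' @param max_age Terminal table age; `q` is forced to 1 there.
#' @return A `life_table` object: numeric vector `q` of length `max_age + 1`
#'   (ages `0:max_age`), each entry in `[0, 1]`, terminal entry 1.
#' @examples
#' lt <- make_life_table()
#' lt$q[85]   # annual death probability at age 84
#' @export
make_life_table <- function(makeham_a = 5e-4, gompertz_b = 2e-5,
                            gompertz_c = 0.095, max_age = 110L) {
  if (!is.numeric(makeham_a) || makeham_a <= 0 ||
      !is.numeric(gompertz_b) || gompertz_b <= 0 ||
      !is.numeric(gompertz_c) || gompertz_c <= 0) {
    stop("life-table parameters must all be positive", call. = FALSE)
  }
  if (max_age < 1) stop("max_age must be >= 1", call. = FALSE)
  ages <- 0:max_age
  q <- 1 - exp(-(makeham_a + gompertz_b * exp(gompertz_c * ages)))
  q <- pmin(pmax(q, 0), 1)
  q[length(q)] <- 1
  new_life_table(q)
}

new_life_table <- function(q) {
  structure(list(q = as.numeric(q), max_age = length(q) - 1L),
            class = "life_table")
}

#' Validate a life table
#'
#' @param lt A `life_table`.
#' @return Character vector of violations (empty when valid).
#' @export
validate_life_table <- function(lt) {
  v <- character()
  if (!inherits(lt, "life_table")) return("not a life_table object")
  if (any(!is.finite(lt$q)) || any(lt$q < 0) || any(lt$q > 1)) {
    v <- c(v, "q: all annual death probabilities must lie in [0, 1]")
  }
  if (lt$q[length(lt$q)] != 1) {
    v <- c(v, "q: terminal-age death probability must be 1")
  }
  v
}

#' Load a life table from a two-column CSV
#'
#' The file must have a header `age,qx`, ages contiguous from 0, and
#' `qx` in `[0, 1]`. If the terminal `qx` is not 1 it is forced to 1 with a
#' message (the model requires a closed table).
#'
#' @param path CSV file path.
#' @return A `life_table`.
#' @export
load_life_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age", "qx") %in% names(df))) {
    stop("life-table file must have columns 'age' and 'qx': ", path,
         call. = FALSE)
  }
  if (nrow(df) < 2) stop("life-table file has too few rows: ", path, call. = FALSE)
  if (any(!is.finite(df$age)) || any(!is.finite(df$qx))) {
    bad <- which(!is.finite(df$age) | !is.finite(df$qx))[1]
    stop("malformed life-table row at line ", bad + 1L, " of ", path,
         call. = FALSE)
  }
  expected <- 0:(nrow(df) - 1L)
  if (!identical(as.integer(df$age), expected)) {
    miss <- setdiff(expected, df$age)
    stop("life-table ages must be contiguous from 0; problem near age ",
         if (length(miss)) miss[1] else df$age[which(df$age != expected)[1]],
         call. = FALSE)
  }
  bad <- which(df$qx < 0 | df$qx > 1)
  if (length(bad)) {
    stop("life-table qx outside [0, 1] at age ", df$age[bad[1]], call. = FALSE)
  }
  q <- as.numeric(df$qx)
  if (q[length(q)] != 1) {
    message("life table: forcing terminal q(", df$age[nrow(df)], ") to 1")
    q[length(q)] <- 1
  }
  new_life_table(q)
}

#' Write a life table to CSV (age,qx)
#'
#' @param lt A `life_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path) {
  stopifnot(inherits(lt, "life_table"))
  df <- data.frame(age = 0:lt$max_age, qx = lt$q)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.life_table <- function(x, ...) {
  cat("Life table: ages 0-", x$max_age, ", q(0)=", signif(x$q[1], 3),
      ", q(", x$max_age, ")=", x$q[length(x$q)], "\n", sep = "")
  invisible(x)
}
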