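# Reading and writing the tabular inputs and outputs.

#' Construct a child table
#'
#' One row per child: wealth quintile (1 = poorest, 5 = wealthiest), one
#' integer severity-level column per risk factor (0 = reference level) and a
#' positive survey weight. Counts everywhere downstream are weight sums.
#'
#' @param df Data frame with columns `quintile`, one column per factor name
#'   (integer level indices) and optionally `weight`.
#' @param factors List of [risk_factor()] objects naming the level columns.
#' @param dropped Number of incomplete rows removed before construction
#'   (bookkeeping, stored as an attribute).
#' @return A `child_table` (a data frame).
#' @export
child_table <- function(df, factors, dropped = 0L) {
  fnames <- vapply(factors, `[[`, "", "name")
  missing_cols <- setdiff(c("quintile", fnames), names(df))
  if (length(missing_cols))
    stop("child table is missing column(s): ", paste(missing_cols, collapse = ", "))
  q <- df$quintile
  if (any(is.na(q)) || any(q != round(q)) || any(q < 1) || any(q > 5))
    stop("quintile out of range: quintiles must be integers 1..5")
  if (is.null(df$weight)) df$weight <- 1
  if (any(is.na(df$weight)) || any(df$weight <= 0))
    stop("weights must be positive")
  for (f in factors) {
    lev <- df[[f$name]]
    if (any(is.na(lev)))
      stop("column '", f$name, "' contains missing levels; apply the ",
           "complete-case rule first (see load_microdata)")
    if (any(lev != round(lev)) || any(lev < 0) || any(lev >= length(f$levels)))
      stop("column '", f$name, "' has level indices outside 0..",
           length(f$levels) - 1L)
    df[[f$name]] <- as.integer(lev)
  }
  out <- df[, c("quintile", fnames, "weight"), drop = FALSE]
  out$quintile <- as.integer(out$quintile)
  rownames(out) <- NULL
  structure(out, factors = fnames, dropped = as.integer(dropped),
            class = c("child_table", "data.frame"))
}

#' @export
print.child_table <- function(x, ...) {
  cat("child table: ", nrow(x), " children (total weight ",
      format(sum(x$weight)), "), factors: ",
      paste(attr(x, "factors"), collapse = ", "), "\n", sep = "")
  if (attr(x, "dropped") > 0L)
    cat("  (", attr(x, "dropped"), " incomplete rows dropped)\n", sep = "")
  NextMethod()
}

#' Load child-level microdata
#'
#' Reads a CSV with a `quintile` column, one column per risk factor of the
#' chosen outcome (either integer level indices 0-based or level labels
#' matching the factor definition) and an optional `weight` column. Rows
#' with a missing level for any of the outcome's factors are dropped
#' (complete-case rule) and the count of dropped rows is reported via
#' `message()` and stored in the `dropped` attribute.
#'
#' @param path CSV file path.
#' @param spec A [disease_spec()].
#' @param outcome `"case"` or `"death"`: which factor set must be complete.
#' @return A [child_table()] restricted to complete cases.
#' @export
load_microdata <- function(path, spec, outcome = c("case", "death")) {
  outcome <- match.arg(outcome)
  if (!file.exists(path)) stop("microdata file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"quintile" %in% names(df)) stop("microdata must have a 'quintile' column")
  factors <- spec_factors(spec, outcome)
  for (f in factors) {
    if (!f$name %in% names(df))
      stop("microdata is missing the factor column '", f$name, "'")
    col <- df[[f$name]]
    if (is.character(col)) {
      col[!nzchar(trimws(col))] <- NA_character_
      idx <- match(col, f$levels) - 1L
      bad <- which(!is.na(col) & is.na(idx))
      if (length(bad))
        stop("unknown factor level label '", col[bad[1L]], "' in row ",
             bad[1L], ", column '", f$name, "'")
      df[[f$name]] <- idx
    } else {
      bad <- which(!is.na(col) & (col != round(col) | col < 0 |
                                    col >= length(f$levels)))
      if (length(bad))
        stop("unknown factor level label '", col[bad[1L]], "' in row ",
             bad[1L], ", column '", f$name, "'")
    }
  }
  fnames <- vapply(factors, `[[`, "", "name")
  complete <- stats::complete.cases(df[, fnames, drop = FALSE])
  n_drop <- sum(!complete)
  if (n_drop > 0L)
    message("dropped ", n_drop, " of ", nrow(df),
            " rows with incomplete ", outcome, " risk-factor data")
  df <- df[complete, , drop = FALSE]
  if (nrow(df) == 0L)
    stop("no complete-case rows remain for the ", outcome, " factor set")
  child_table(df, factors, dropped = n_drop)
}

#' Load a per-quintile coverage table
#'
#' CSV with one row per quintile 1..5 and columns `<vaccine>_coverage`
#' (proportions), plus care-seeking proportions `careseek_diarrhoea`,
#' `careseek_ari` and `careseek_fever` (each optionally missing). A country
#' without a vaccine in its national programme is represented by zero
#' coverage, not a missing column.
#'
#' @param path CSV file path.
#' @return A `coverage_table` data frame ordered by quintile.
#' @export
load_coverage <- function(path) {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"quintile" %in% names(df)) stop("coverage table must have a 'quintile' column")
  if (!setequal(df$quintile, 1:5) || nrow(df) != 5L)
    stop("coverage table must have exactly one row per quintile 1..5")
  df <- df[order(df$quintile), , drop = FALSE]
  num_cols <- setdiff(names(df), "quintile")
  for (cl in num_cols) {
    v <- df[[cl]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop("coverage column '", cl, "' must contain proportions in [0, 1]")
  }
  rownames(df) <- NULL
  structure(df, class = c("coverage_table", "data.frame"))
}

#' Load a per-quintile under-5 mortality table
#'
#' CSV with columns `quintile` (1..5) and `u5mr_per_1000` (deaths per 1000
#' live births, positive).
#'
#' @param path CSV file path.
#' @return Numeric vector of length 5 (quintiles I..V).
#' @export
load_u5mr <- function(path) {
  if (!file.exists(path)) stop("u5mr file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("quintile", "u5mr_per_1000") %in% names(df)))
    stop("u5mr table must have columns 'quintile' and 'u5mr_per_1000'")
  if (!setequal(df$quintile, 1:5) || nrow(df) != 5L)
    stop("u5mr table must have exactly one row per quintile 1..5")
  df <- df[order(df$quintile), ]
  u5mr <- df$u5mr_per_1000
  if (any(is.na(u5mr)) || any(u5mr <= 0)) stop("u5mr values must be positive")
  setNames(u5mr, paste0("Q", 1:5))
}

#' Resolve per-quintile treatment coverage for a disease
#'
#' Care-seeking percentages proxy effective treatment coverage. Diarrhoea
#' uses the diarrhoea care-seeking column. Pneumonia care-seeking is not
#' reported in the surveys, so acute respiratory infection (ARI)
#' care-seeking stands in, with fever care-seeking as fallback. Measles uses
#' the per-quintile average of the diarrhoea and respiratory (ARI, else
#' fever) care-seeking proportions.
#'
#' @param coverage A [load_coverage()] table.
#' @param disease Disease name.
#' @return Numeric vector of length 5: treatment coverage per quintile.
#' @export
resolve_treatment_coverage <- function(coverage, disease) {
  disease <- match.arg(disease, DISEASES)
  pick <- function(col) {
    v <- coverage[[col]]
    if (is.null(v) || all(is.na(v))) NULL else v
  }
  fail <- function(chain)
    stop("no care-seeking data for ", disease,
         ": tried columns ", paste(chain, collapse = " -> "))
  resp <- function() {
    v <- pick("careseek_ari")
    if (is.null(v)) v <- pick("careseek_fever")
    v
  }
  out <- switch(disease,
    diarrhoea = pick("careseek_diarrhoea") %||% fail("careseek_diarrhoea"),
    pneumonia = resp() %||% fail(c("careseek_ari", "careseek_fever")),
    measles = {
      d <- pick("careseek_diarrhoea") %||%
        fail(c("careseek_diarrhoea", "careseek_ari"))
      r <- resp() %||% fail(c("careseek_diarrhoea", "careseek_ari",
                              "careseek_fever"))
      (d + r) / 2
    })
  if (any(is.na(out)))
    stop("care-seeking column for ", disease, " has missing quintile values")
  setNames(as.numeric(out), paste0("Q", 1:5))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a quintile gradient to CSV
#'
#' Columns: `quintile`, `mean`, `median`, `ui_low`, `ui_high`, `reference`
#' (logical, TRUE for the reference quintile). Values round-trip losslessly
#' well beyond 6 decimals.
#'
#' @param gradient A [quintile_gradient] (see [normalize_gradient()]).
#' @param path Output CSV path.
#' @export
write_gradients <- function(gradient, path) {
  stopifnot(inherits(gradient, "quintile_gradient"))
  num <- as.matrix(gradient[, c("mean", "median", "ui_low", "ui_high")])
  if (!all(is.finite(num)))
    stop("gradient contains non-finite values; refusing to write")
  ok <- tryCatch({
    write.csv(as.data.frame(gradient), path, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write gradient to ", path)
  invisible(path)
}

#' Read a quintile gradient written by [write_gradients()]
#' @param path CSV path.
#' @return A `quintile_gradient`.
#' @export
read_gradients <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("quintile", "mean", "median", "ui_low", "ui_high", "reference")
  if (!all(need %in% names(df))) stop("not a gradient CSV: ", path)
  new_quintile_gradient(df$mean, df$median, df$ui_low, df$ui_high,
                        reference = which(as.logical(df$reference))[1L])
}
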