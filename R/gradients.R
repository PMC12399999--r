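# Quintile aggregation, reference-value-1 normalization and reporting.

new_quintile_gradient <- function(mean, median, ui_low, ui_high, reference) {
  df <- data.frame(quintile = 1:5, mean = mean, median = median,
                   ui_low = ui_low, ui_high = ui_high,
                   reference = seq_len(5) == reference)
  structure(df, reference = as.integer(reference),
            class = c("quintile_gradient", "data.frame"))
}

#' @export
print.quintile_gradient <- function(x, ...) {
  cat("quintile risk gradient (reference quintile ",
      c("I", "II", "III", "IV", "V")[attr(x, "reference")], " = 1)\n", sep = "")
  NextMethod()
}

#' Per-replicate risk of death per child, by quintile
#'
#' Divides each replicate's quintile death counts by the quintile's weighted
#' child population.
#'
#' @param deaths A `quintile_deaths` object or a replicates x 5 matrix.
#' @param pop Length-5 vector of weighted child counts per quintile; taken
#'   from `deaths$pop` when omitted.
#' @return Replicates x 5 matrix of per-child risks.
#' @export
quintile_risks <- function(deaths, pop = NULL) {
  if (inherits(deaths, "quintile_deaths")) {
    if (is.null(pop)) pop <- deaths$pop
    deaths <- deaths$replicates
  }
  deaths <- rbind(deaths)
  pop <- as.numeric(pop)
  if (length(pop) != 5L || any(!is.finite(pop)) || any(pop <= 0))
    stop("zero population quintile: pop must be 5 positive values")
  sweep(deaths, 2L, pop, `/`)
}

#' Normalize quintile risks to the reference value 1
#'
#' The per-quintile mean risk across replicates is divided by its minimum,
#' so the lowest-risk quintile (in almost all settings the wealthiest,
#' quintile V) takes the reference value 1 exactly; the reference quintile
#' is reported explicitly for the exceptions. Medians and percentile 95%
#' uncertainty intervals are computed on the per-replicate risk vectors,
#' each divided by its own value at the reference quintile.
#'
#' @param risks Replicates x 5 matrix of positive per-child risks (see
#'   [quintile_risks()]).
#' @return A `quintile_gradient` data frame with columns `quintile`,
#'   `mean`, `median`, `ui_low`, `ui_high`, `reference`.
#' @export
normalize_gradient <- function(risks) {
  risks <- rbind(risks)
  if (ncol(risks) != 5L) stop("risks must have 5 quintile columns")
  if (any(!is.finite(risks)) || any(risks <= 0))
    stop("risks must be positive and finite")
  m <- colMeans(risks)
  qref <- which.min(m)
  norm_reps <- risks / risks[, qref]
  new_quintile_gradient(
    mean = m / m[qref],
    median = apply(norm_reps, 2, median),
    ui_low = apply(norm_reps, 2, quantile, probs = 0.025, names = FALSE),
    ui_high = apply(norm_reps, 2, quantile, probs = 0.975, names = FALSE),
    reference = qref)
}

#' Write gradient tables and a summary figure
#'
#' Writes one CSV per gradient (deterministic names
#' `<name>_gradient.csv`) and, when a graphics device is available, a
#' combined bar chart with quintiles I..V on the x-axis, relative risk of
#' death on the y-axis and uncertainty-interval whiskers.
#'
#' @param gradients Named list of `quintile_gradient` objects.
#' @param outdir Output directory (created if absent).
#' @param figure Attempt the PNG figure (default TRUE).
#' @return Invisibly, the paths written.
#' @export
render_outputs <- function(gradients, outdir, figure = TRUE) {
  stopifnot(length(gradients) >= 1L, !is.null(names(gradients)))
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", outdir)
  paths <- character(0)
  for (nm in names(gradients)) {
    path <- file.path(outdir, paste0(nm, "_gradient.csv"))
    write_gradients(gradients[[nm]], path)
    paths <- c(paths, path)
  }
  if (figure) {
    fig <- file.path(outdir, "risk_gradients.png")
    ok <- tryCatch({
      grDevices::png(fig, width = 360 * length(gradients), height = 360)
      on.exit(grDevices::dev.off(), add = TRUE)
      graphics::par(mfrow = c(1, length(gradients)), mar = c(4, 4, 3, 1))
      for (nm in names(gradients)) plot_gradient(gradients[[nm]], nm)
      TRUE
    }, error = function(e) {
      warning("figure skipped: ", conditionMessage(e))
      FALSE
    })
    if (ok) paths <- c(paths, fig)
  }
  invisible(paths)
}

plot_gradient <- function(g, title) {
  mids <- graphics::barplot(g$mean, names.arg = c("I", "II", "III", "IV", "V"),
                            ylim = c(0, max(g$ui_high) * 1.05),
                            xlab = "wealth quintile",
                            ylab = "relative risk of death", main = title,
                            col = "grey70", border = NA)
  has_width <- g$ui_high - g$ui_low > 1e-9
  if (any(has_width))
    graphics::arrows(mids[has_width], g$ui_low[has_width], mids[has_width],
                     g$ui_high[has_width], angle = 90, code = 3, length = 0.04)
  graphics::abline(h = 1, lty = 2)
}
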