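# Disease configuration: risk factors, vaccines, treatment.

#' Define an ordered-severity risk factor
#'
#' A risk factor has 2 or 3 ordered severity levels. Level index 0 is the
#' reference (factor absent); higher indices are more severe. Relative risks
#' are ratios of outcome probability at a level versus the reference level,
#' marginal over the other factors; they must start at exactly 1 and be
#' nondecreasing with severity. A factor may carry separate relative risks
#' for acquiring the disease (`rr_case`) and for dying from it (`rr_death`),
#' since the factor sets used for morbidity and mortality differ by disease.
#'
#' @param name Factor identifier, e.g. `"stunting"`.
#' @param levels Character vector of 2 or 3 ordered level labels, least
#'   severe first.
#' @param rr_case,rr_death Numeric vectors of relative risks, one per level.
#'   Index 1 (the reference level) is forced to 1; values must be >= 1 and
#'   nondecreasing. Either may be `NULL` when the factor is only used for
#'   the other outcome.
#' @return An object of class `risk_factor`.
#' @examples
#' risk_factor("stunting", c("none", "moderate", "severe"),
#'             rr_case = c(1, 1.6, 2.3), rr_death = c(1, 2.0, 3.2))
#' @export
risk_factor <- function(name, levels, rr_case = NULL, rr_death = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  levels <- as.character(levels)
  if (length(levels) < 2L || length(levels) > 3L)
    stop("factor '", name, "' must have 2 or 3 ordered severity levels")
  if (anyDuplicated(levels))
    stop("factor '", name, "' has duplicated level labels")
  structure(
    list(name = name, levels = levels,
         rr_case = check_rr(rr_case, name, length(levels), "case"),
         rr_death = check_rr(rr_death, name, length(levels), "death")),
    class = "risk_factor")
}

check_rr <- function(rr, name, n_levels, what) {
  if (is.null(rr)) return(NULL)
  rr <- as.numeric(rr)
  if (length(rr) != n_levels)
    stop("factor '", name, "': ", what, " relative risks must have one value per level")
  if (abs(rr[1L] - 1) > 1e-8)
    stop("factor '", name, "': ", what,
         " relative risk at the reference level must be 1 (got ", rr[1L], ")")
  rr[1L] <- 1
  if (any(rr < 1))
    stop("factor '", name, "': ", what, " relative risks must all be >= 1")
  if (any(diff(rr) < 0))
    stop("factor '", name, "': ", what,
         " relative risks must be nondecreasing with severity")
  rr
}

#' @export
print.risk_factor <- function(x, ...) {
  cat("risk factor '", x$name, "': levels ", paste(x$levels, collapse = " < "), "\n",
      sep = "")
  if (!is.null(x$rr_case)) cat("  rr (case):  ", paste(x$rr_case, collapse = ", "), "\n")
  if (!is.null(x$rr_death)) cat("  rr (death): ", paste(x$rr_death, collapse = ", "), "\n")
  invisible(x)
}

# rr vector of a factor for a given outcome, with a clear error when absent
factor_rr <- function(f, which = c("case", "death")) {
  which <- match.arg(which)
  rr <- if (which == "case") f$rr_case else f$rr_death
  if (is.null(rr))
    stop("factor '", f$name, "' has no ", which, " relative risks")
  rr
}

#' Define a vaccine
#'
#' @param name Vaccine identifier; the coverage table must contain a column
#'   `<name>_coverage`.
#' @param efficacy Point efficacy, a proportion in `[0, 1]`.
#' @param ui Length-2 numeric `(low, high)` 95% uncertainty interval
#'   bracketing `efficacy`.
#' @param attributable_fraction Proportion of the disease's cases caused by
#'   the agent the vaccine targets (1 for measles vaccine against measles;
#'   e.g. 0.330 for pneumococcus among pneumonia cases).
#' @return An object of class `vaccine_spec`.
#' @export
vaccine_spec <- function(name, efficacy, ui = c(efficacy, efficacy),
                         attributable_fraction = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  efficacy <- as.numeric(efficacy)
  ui <- as.numeric(ui)
  attributable_fraction <- as.numeric(attributable_fraction)
  if (length(efficacy) != 1L || efficacy < 0 || efficacy > 1)
    stop("vaccine '", name, "': efficacy must be a proportion in [0, 1]")
  if (length(ui) != 2L || ui[1L] > efficacy || ui[2L] < efficacy ||
      ui[1L] < 0 || ui[2L] > 1)
    stop("vaccine '", name, "': ui must satisfy 0 <= low <= efficacy <= high <= 1")
  if (attributable_fraction < 0 || attributable_fraction > 1)
    stop("vaccine '", name, "': attributable_fraction must be in [0, 1]")
  structure(list(name = name, efficacy = efficacy, ui = ui,
                 attributable_fraction = attributable_fraction),
            class = "vaccine_spec")
}

DISEASES <- c("diarrhoea", "pneumonia", "measles")

#' Assemble a disease specification
#'
#' Bundles the risk-factor sets for morbidity (cases) and mortality
#' (deaths), the vaccines relevant to the disease, and the treatment
#' efficacy. At most four risk factors are allowed per outcome.
#'
#' @param disease One of `"diarrhoea"`, `"pneumonia"`, `"measles"`.
#' @param case_factors,death_factors Lists of [risk_factor()] objects
#'   (at most 4 each); case factors must carry `rr_case`, death factors
#'   `rr_death`.
#' @param vaccines List of [vaccine_spec()] objects (may be empty).
#' @param treatment_efficacy Proportion in `[0, 1]`: probability that
#'   treatment averts death given the disease.
#' @param treatment_ui Length-2 uncertainty interval for
#'   `treatment_efficacy`.
#' @return An object of class `disease_spec`.
#' @export
disease_spec <- function(disease, case_factors, death_factors, vaccines = list(),
                         treatment_efficacy, treatment_ui = c(treatment_efficacy,
                                                              treatment_efficacy)) {
  disease <- match.arg(disease, DISEASES)
  check_factor_list <- function(fl, slot, label) {
    if (length(fl) < 1L || length(fl) > 4L)
      stop("between 1 and 4 ", label, " risk factors are supported (got ",
           length(fl), ")")
    for (f in fl) {
      if (!inherits(f, "risk_factor")) stop(label, " factors must be risk_factor objects")
      if (is.null(f[[slot]]))
        stop("factor '", f$name, "' is listed as a ", label,
             " factor but has no ", label, " relative risks")
    }
    if (anyDuplicated(vapply(fl, `[[`, "", "name")))
      stop("duplicated ", label, " factor names")
    fl
  }
  case_factors <- check_factor_list(case_factors, "rr_case", "case")
  death_factors <- check_factor_list(death_factors, "rr_death", "death")
  for (v in vaccines)
    if (!inherits(v, "vaccine_spec")) stop("vaccines must be vaccine_spec objects")
  treatment_efficacy <- as.numeric(treatment_efficacy)
  if (treatment_efficacy < 0 || treatment_efficacy > 1)
    stop("treatment efficacy must be a proportion in [0, 1]")
  structure(list(disease = disease, case_factors = case_factors,
                 death_factors = death_factors, vaccines = vaccines,
                 treatment_efficacy = treatment_efficacy,
                 treatment_ui = as.numeric(treatment_ui)),
            class = "disease_spec")
}

#' @export
print.disease_spec <- function(x, ...) {
  cat("disease spec:", x$disease, "\n")
  cat("  case factors:  ", paste(vapply(x$case_factors, `[[`, "", "name"),
                                 collapse = ", "), "\n")
  cat("  death factors: ", paste(vapply(x$death_factors, `[[`, "", "name"),
                                 collapse = ", "), "\n")
  if (length(x$vaccines))
    cat("  vaccines:      ",
        paste(vapply(x$vaccines, function(v)
          sprintf("%s (eff %.2f, AF %.3f)", v$name, v$efficacy,
                  v$attributable_fraction), ""), collapse = "; "), "\n")
  cat("  treatment efficacy:", x$treatment_efficacy, "\n")
  invisible(x)
}

spec_factors <- function(spec, outcome = c("case", "death")) {
  outcome <- match.arg(outcome)
  if (outcome == "case") spec$case_factors else spec$death_factors
}

#' Load a disease configuration file
#'
#' Reads a YAML (or JSON) disease configuration with keys `disease`,
#' `case_factors`, `death_factors`, `vaccines` and `treatment`. Each factor
#' block has `name`, `levels` and `rr` (one relative risk per level, applied
#' to the outcome whose list the block appears in); each vaccine block has
#' `name`, `efficacy`, `ui` and `attributable_fraction`; `treatment` has
#' `efficacy` and `ui`. The reference-level relative risk is forced to 1.
#'
#' Bundled illustrative configurations for the three diseases are available
#' via `system.file("extdata", "<disease>.yaml", package = "quintgrad")`.
#' Their vaccine and treatment efficacies are literature point estimates;
#' their relative-risk magnitudes are plausible placeholders and real
#' analyses must supply study-specific values.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [disease_spec()] object.
#' @export
load_disease_config <- function(path) {
  if (!file.exists(path)) stop("disease config not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  for (key in c("disease", "case_factors", "death_factors", "treatment"))
    if (is.null(raw[[key]])) stop("disease config missing key '", key, "'")
  mk_factor <- function(block, slot) {
    if (is.null(block$name) || is.null(block$levels) || is.null(block$rr))
      stop("factor block needs 'name', 'levels' and 'rr'")
    args <- list(name = block$name, levels = unlist(block$levels))
    args[[slot]] <- unlist(block$rr)
    do.call(risk_factor, args)
  }
  case_factors <- lapply(raw$case_factors, mk_factor, slot = "rr_case")
  death_factors <- lapply(raw$death_factors, mk_factor, slot = "rr_death")
  vaccines <- lapply(raw$vaccines, function(v) {
    vaccine_spec(v$name, v$efficacy,
                 ui = if (is.null(v$ui)) c(v$efficacy, v$efficacy) else unlist(v$ui),
                 attributable_fraction =
                   if (is.null(v$attributable_fraction)) 1 else v$attributable_fraction)
  })
  tr <- raw$treatment
  disease_spec(raw$disease, case_factors, death_factors, vaccines,
               treatment_efficacy = tr$efficacy,
               treatment_ui = if (is.null(tr$ui)) c(tr$efficacy, tr$efficacy)
                              else unlist(tr$ui))
}
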