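# Quintile-specific immunization and treatment adjustment.

#' Combined vaccine multiplier for a quintile
#'
#' Each vaccine's efficacy is scaled by the fraction of the disease's cases
#' attributable to the agent it targets, and by the quintile's coverage;
#' independent vaccines combine multiplicatively:
#' `prod_v (1 - AF_v * efficacy_v * coverage_vq)`. A vaccine with zero
#' coverage (e.g. not in the national programme) contributes a factor 1.
#'
#' @param vaccines List of [vaccine_spec()] objects.
#' @param coverage A [load_coverage()] table with a `<name>_coverage`
#'   column per vaccine.
#' @param q Quintile 1..5.
#' @return Multiplier in `[0, 1]`.
#' @export
vaccine_multiplier <- function(vaccines, coverage, q) {
  stopifnot(q %in% 1:5)
  unname(vaccine_multipliers(vaccines, coverage)[q])
}

# per-quintile multipliers, optionally with overridden efficacies
vaccine_multipliers <- function(vaccines, coverage, efficacies = NULL) {
  out <- rep(1, 5)
  for (i in seq_along(vaccines)) {
    v <- vaccines[[i]]
    col <- paste0(v$name, "_coverage")
    cov <- coverage[[col]]
    if (is.null(cov))
      stop("coverage table lacks column '", col, "'; use zeros for a ",
           "vaccine outside the national programme")
    if (any(is.na(cov))) stop("missing coverage values in '", col, "'")
    eff <- if (is.null(efficacies)) v$efficacy else efficacies[i]
    out <- out * (1 - v$attributable_fraction * eff * cov)
  }
  setNames(out, paste0("Q", 1:5))
}

#' Treatment multiplier
#'
#' The probability that a death is not averted by treatment:
#' `1 - treatment_efficacy * careseek`. Care-seeking proxies effective
#' treatment coverage; the multiplier applies to death outcomes only.
#'
#' @param treatment_efficacy Proportion in `[0, 1]`.
#' @param careseek_q Care-seeking proportion(s) in `[0, 1]`.
#' @return Multiplier(s) in `[0, 1]`.
#' @export
treatment_multiplier <- function(treatment_efficacy, careseek_q) {
  stopifnot(treatment_efficacy >= 0, treatment_efficacy <= 1,
            all(careseek_q >= 0), all(careseek_q <= 1))
  1 - treatment_efficacy * careseek_q
}

#' Apply coverage adjustments to expected outcome counts
#'
#' Starting from the unadjusted expectation `n[j, q] * p[j]`, immunization
#' coverage rescales every cell by the quintile's vaccine multiplier, and --
#' for death outcomes only -- treatment coverage further rescales by the
#' quintile's treatment multiplier. Adjustment never increases a cell.
#'
#' @param profiles A tabulated `profile_table`.
#' @param p_summary Per-profile probabilities in `[0, 1]` (e.g. ensemble
#'   means).
#' @param spec A [disease_spec()].
#' @param coverage A [load_coverage()] table.
#' @param outcome `"case"` or `"death"`.
#' @return An `adjusted_outcomes` object: `expected` (profiles x 5 matrix),
#'   the `multipliers` used, and a `stage` flag.
#' @export
apply_adjustments <- function(profiles, p_summary, spec, coverage,
                              outcome = c("case", "death")) {
  outcome <- match.arg(outcome)
  if (is.null(profiles$counts)) stop("profiles have no counts")
  p <- as.numeric(p_summary)
  stopifnot(length(p) == n_profiles(profiles), all(p >= 0), all(p <= 1))
  if (nrow(coverage) != 5L)
    stop("missing coverage row for a quintile: 5 rows required")
  vmult <- vaccine_multipliers(spec$vaccines, coverage)
  tmult <- if (outcome == "death")
    treatment_multiplier(spec$treatment_efficacy,
                         resolve_treatment_coverage(coverage, spec$disease))
  else rep(1, 5)
  mult <- vmult * tmult
  expected <- profiles$counts * outer(p, mult)
  structure(list(expected = expected, multipliers = mult,
                 vaccine_multipliers = vmult, treatment_multipliers = tmult,
                 stage = if (outcome == "death") "immunization+treatment"
                         else "immunization"),
            class = "adjusted_outcomes")
}

# Per-replicate quintile outcome counts for a whole ensemble: row k gives
# sum_j n[j, q] * p_k[j] * mult[q]. `mult` may be a length-5 vector or a
# replicates x 5 matrix (per-replicate sampled efficacies).
ensemble_quintile_counts <- function(solutions, counts, mult) {
  base <- solutions %*% counts                # replicates x 5
  if (is.matrix(mult)) base * mult
  else sweep(base, 2L, mult, `*`)
}

# Beta distribution moment-matched to a point estimate and a 95% interval;
# returns k draws (degenerate cases return the point estimate).
sample_efficacy <- function(point, ui, k) {
  sd <- (ui[2] - ui[1]) / (2 * qnorm(0.975))
  v <- sd^2
  if (v <= 0 || point <= 0 || point >= 1) return(rep(point, k))
  v <- min(v, 0.95 * point * (1 - point))
  a <- point * (point * (1 - point) / v - 1)
  b <- (1 - point) * (point * (1 - point) / v - 1)
  rbeta(k, a, b)
}

# replicates x 5 vaccine multipliers with per-replicate efficacies drawn
# from moment-matched Beta distributions
sample_vaccine_multipliers <- function(vaccines, coverage, k) {
  out <- matrix(1, k, 5)
  for (v in vaccines) {
    cov <- coverage[[paste0(v$name, "_coverage")]]
    eff <- sample_efficacy(v$efficacy, v$ui, k)
    out <- out * (1 - v$attributable_fraction * outer(eff, cov))
  }
  out
}

sample_treatment_multipliers <- function(spec, careseek, k) {
  eff <- sample_efficacy(spec$treatment_efficacy, spec$treatment_ui, k)
  1 - outer(eff, careseek)
}

#' @importFrom stats qnorm
NULL
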