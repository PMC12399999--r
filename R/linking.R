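# Linking morbidity and mortality: three approaches plus the main-analysis
# average of the first and third.

# Shared sub-pipeline: profiles -> counts -> system (+anchor) -> ensemble.
fit_outcome_ensemble <- function(spec, children, outcome, k, seed,
                                 anchor_risk = 0.05, p_cap = 0.5,
                                 attempt_cap = 10 * k) {
  factors <- spec_factors(spec, outcome)
  profiles <- tabulate_counts(children, enumerate_profiles(factors))
  order <- dominance_order(profiles)
  system <- add_anchor(build_marginal_equations(profiles, factors, outcome),
                       anchor_risk)
  ensemble <- sample_ensemble(system, order, k = k, seed = seed,
                              p_cap = p_cap, attempt_cap = attempt_cap)
  pop <- vapply(1:5, function(q) sum(children$weight[children$quintile == q]),
                numeric(1))
  list(factors = factors, profiles = profiles, order = order, system = system,
       ensemble = ensemble, pop = setNames(pop, paste0("Q", 1:5)))
}

new_quintile_deaths <- function(replicates, approach, pop = NULL) {
  replicates <- rbind(replicates)
  stopifnot(ncol(replicates) == 5L, all(replicates >= 0))
  colnames(replicates) <- paste0("Q", 1:5)
  structure(list(deaths = colMeans(replicates), replicates = replicates,
                 approach = approach, pop = pop),
            class = "quintile_deaths")
}

#' @export
print.quintile_deaths <- function(x, ...) {
  cat("quintile deaths (approach: ", x$approach, ", ",
      nrow(x$replicates), " replicate(s))\n", sep = "")
  print(round(x$deaths, 3))
  invisible(x)
}

#' Approach A: deaths estimated directly from death risk factors
#'
#' Runs the full pipeline on the mortality risk-factor set -- profile
#' enumeration, marginal system with anchor, constrained solution ensemble
#' -- then applies immunization and treatment coverage. Each ensemble
#' replicate yields the expected deaths per quintile.
#'
#' @param spec A [disease_spec()].
#' @param children A [child_table()] complete for the death factors.
#' @param coverage A [load_coverage()] table.
#' @param k Ensemble size.
#' @param seed Master seed.
#' @param anchor_risk Overall death risk for the anchor equation.
#' @param sample_efficacy_ui If TRUE, vaccine and treatment efficacies are
#'   redrawn per replicate from Beta distributions moment-matched to their
#'   uncertainty intervals, propagating efficacy uncertainty into the
#'   gradients.
#' @param ... Further arguments to the sampler ([sample_ensemble()]).
#' @return A `quintile_deaths` object with per-replicate death counts.
#' @export
deaths_direct <- function(spec, children, coverage, k = 1000L, seed = 1L,
                          anchor_risk = 0.05, sample_efficacy_ui = FALSE, ...) {
  fit <- fit_outcome_ensemble(spec, children, "death", k, seed,
                              anchor_risk, ...)
  mult <- death_multipliers(spec, coverage, k, seed, sample_efficacy_ui)
  reps <- ensemble_quintile_counts(fit$ensemble$solutions,
                                   fit$profiles$counts, mult)
  out <- new_quintile_deaths(reps, "direct", pop = fit$pop)
  out$fit <- fit
  out
}

#' Approach B: deaths estimated from case risk factors
#'
#' As [deaths_direct()], but the ensemble is fitted with the morbidity
#' risk-factor set, and both immunization and treatment coverage are then
#' applied to turn the case-risk distribution into a death distribution.
#' Reported for comparison; excluded from the main analysis.
#'
#' @inheritParams deaths_direct
#' @export
deaths_from_case_risks <- function(spec, children, coverage, k = 1000L,
                                   seed = 1L, anchor_risk = 0.05,
                                   sample_efficacy_ui = FALSE, ...) {
  fit <- fit_outcome_ensemble(spec, children, "case", k, seed,
                              anchor_risk, ...)
  mult <- death_multipliers(spec, coverage, k, seed, sample_efficacy_ui)
  reps <- ensemble_quintile_counts(fit$ensemble$solutions,
                                   fit$profiles$counts, mult)
  out <- new_quintile_deaths(reps, "case-risk", pop = fit$pop)
  out$fit <- fit
  out
}

death_multipliers <- function(spec, coverage, k, seed, sample_efficacy_ui) {
  careseek <- resolve_treatment_coverage(coverage, spec$disease)
  if (sample_efficacy_ui) {
    set.seed(seed + 1L)
    sample_vaccine_multipliers(spec$vaccines, coverage, k) *
      sample_treatment_multipliers(spec, careseek, k)
  } else {
    vaccine_multipliers(spec$vaccines, coverage) *
      treatment_multiplier(spec$treatment_efficacy, careseek)
  }
}

#' Approach C: deaths extrapolated from cases via the u5mr differential
#'
#' Scales the per-quintile expected case counts by the quintile's share of
#' the under-5 mortality rate: `deaths[q] = cases[q] * u5mr[q] / mean(u5mr)`.
#' The normalizer is arbitrary -- it cancels once the gradient is
#' normalized -- the quintile mean is used.
#'
#' @param cases Per-quintile expected cases: a length-5 vector, a
#'   replicates x 5 matrix, or a `quintile_deaths`-shaped object.
#' @param u5mr Length-5 vector of under-5 mortality rates (per 1000 live
#'   births, positive), quintiles I..V.
#' @return A `quintile_deaths` object.
#' @export
deaths_extrapolated <- function(cases, u5mr) {
  if (inherits(cases, "quintile_deaths")) {
    pop <- cases$pop
    cases <- cases$replicates
  } else pop <- NULL
  cases <- rbind(cases)
  stopifnot(ncol(cases) == 5L, all(cases >= 0))
  u5mr <- as.numeric(u5mr)
  if (length(u5mr) != 5L || any(!is.finite(u5mr)) || any(u5mr <= 0))
    stop("u5mr must be 5 positive values")
  reps <- sweep(cases, 2L, u5mr / mean(u5mr), `*`)
  new_quintile_deaths(reps, "extrapolated", pop = pop)
}

#' Main analysis: average of the direct and extrapolated gradients
#'
#' The headline gradient averages the normalized gradients of approach A
#' (direct) and approach C (extrapolated) elementwise, then renormalizes so
#' the minimum mean entry is exactly 1.
#'
#' @param gradA,gradC Normalized [quintile_gradient] objects.
#' @return A `quintile_gradient`.
#' @export
main_analysis <- function(gradA, gradC) {
  stopifnot(inherits(gradA, "quintile_gradient"),
            inherits(gradC, "quintile_gradient"))
  if (nrow(gradA) != nrow(gradC)) stop("gradients have mismatched lengths")
  for (g in list(gradA, gradC))
    if (abs(min(g$mean) - 1) > 1e-9)
      stop("main_analysis expects normalized gradients (min mean = 1)")
  m <- (gradA$mean + gradC$mean) / 2
  qref <- which.min(m)
  scale <- m[qref]
  new_quintile_gradient(mean = m / scale,
                        median = (gradA$median + gradC$median) / 2 / scale,
                        ui_low = (gradA$ui_low + gradC$ui_low) / 2 / scale,
                        ui_high = (gradA$ui_high + gradC$ui_high) / 2 / scale,
                        reference = qref)
}
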