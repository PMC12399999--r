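# End-to-end orchestration: simulate inputs, estimate gradients, report.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Estimate all quintile death gradients for one disease
#'
#' Runs the full estimation on in-memory inputs: complete-case filtering
#' per outcome, profile enumeration and tabulation, the anchored marginal
#' relative-risk system, the constrained solution ensemble, coverage
#' adjustment, the three morbidity-to-mortality linking approaches and the
#' main-analysis average of the direct (A) and extrapolated (C) gradients.
#'
#' @param spec A [disease_spec()].
#' @param microdata Path to the microdata CSV, or a data frame.
#' @param coverage A [load_coverage()] table (or path).
#' @param u5mr Length-5 u5mr vector (or path).
#' @param k Ensemble size per outcome (default 1000).
#' @param seed Master seed; all randomness derives from it.
#' @param anchor_risk Overall risk used in the anchor equation.
#' @param sample_efficacy_ui Propagate efficacy uncertainty (see
#'   [deaths_direct()]).
#' @param c_adjusted If TRUE (default) approach C extrapolates the
#'   immunization-adjusted case distribution; if FALSE, the raw fitted case
#'   distribution.
#' @param p_cap Upper bound of the random-start distribution.
#' @return An `estimate_result`: gradients `A`, `B`, `C`, `main`, the
#'   underlying `quintile_deaths`, and a run manifest.
#' @export
estimate_gradients <- function(spec, microdata, coverage, u5mr, k = 1000L,
                               seed = 1L, anchor_risk = 0.05,
                               sample_efficacy_ui = FALSE, c_adjusted = TRUE,
                               p_cap = 0.5) {
  stopifnot(inherits(spec, "disease_spec"))
  if (is.character(coverage)) coverage <- stage("load", load_coverage(coverage))
  if (is.character(u5mr)) u5mr <- stage("load", load_u5mr(u5mr))
  load_children <- function(outcome) {
    if (is.character(microdata)) load_microdata(microdata, spec, outcome)
    else child_table(microdata, spec_factors(spec, outcome))
  }
  children_death <- stage("load", load_children("death"))
  children_case <- stage("load", load_children("case"))

  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L)

  dA <- stage("deaths_direct",
              deaths_direct(spec, children_death, coverage, k = k,
                            seed = sub_seeds[1], anchor_risk = anchor_risk,
                            sample_efficacy_ui = sample_efficacy_ui,
                            p_cap = p_cap))
  dB <- stage("deaths_from_case_risks",
              deaths_from_case_risks(spec, children_case, coverage, k = k,
                                     seed = sub_seeds[2],
                                     anchor_risk = anchor_risk,
                                     sample_efficacy_ui = sample_efficacy_ui,
                                     p_cap = p_cap))
  # approach C reuses the case-factor ensemble fitted for B, with
  # immunization-only (or no) adjustment before the u5mr extrapolation
  dC <- stage("deaths_extrapolated", {
    vm <- if (c_adjusted) vaccine_multipliers(spec$vaccines, coverage)
          else rep(1, 5)
    cases <- ensemble_quintile_counts(dB$fit$ensemble$solutions,
                                      dB$fit$profiles$counts, vm)
    dd <- deaths_extrapolated(cases, u5mr)
    dd$pop <- dB$pop
    dd
  })

  gradients <- stage("gradients", {
    gA <- normalize_gradient(quintile_risks(dA))
    gB <- normalize_gradient(quintile_risks(dB))
    gC <- normalize_gradient(quintile_risks(dC))
    list(A = gA, B = gB, C = gC, main = main_analysis(gA, gC))
  })

  manifest <- list(
    package = "quintgrad",
    version = as.character(utils::packageVersion("quintgrad")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    disease = spec$disease, k = k, seed = seed, anchor_risk = anchor_risk,
    sample_efficacy_ui = sample_efficacy_ui, c_adjusted = c_adjusted,
    p_cap = p_cap,
    microdata = if (is.character(microdata))
      list(path = microdata, md5 = unname(tools::md5sum(microdata))) else "in-memory",
    dropped_rows = list(case = attr(children_case, "dropped"),
                        death = attr(children_death, "dropped")),
    n_children = list(case = nrow(children_case), death = nrow(children_death)),
    n_profiles = list(case = n_profiles(dB$fit$profiles),
                      death = n_profiles(dA$fit$profiles)),
    acceptance_rate = list(case = dB$fit$ensemble$acceptance_rate,
                           death = dA$fit$ensemble$acceptance_rate))

  structure(list(gradients = gradients,
                 deaths = list(A = dA, B = dB, C = dC),
                 manifest = manifest),
            class = "estimate_result")
}

#' @export
print.estimate_result <- function(x, ...) {
  cat("gradient estimate:", x$manifest$disease, "(k =", x$manifest$k,
      ", seed", paste0(x$manifest$seed, ")"), "\n")
  cat("main-analysis gradient (quintiles I..V):\n")
  print(round(x$gradients$main$mean, 3))
  invisible(x)
}

#' Run the full estimation from input files to output files
#'
#' File-level wrapper around [estimate_gradients()]: loads the disease
#' configuration and the three input tables, estimates, and writes one
#' gradient CSV per approach (A, B, C, main), a summary figure and a
#' `manifest.json` recording versions, seed, configuration and diagnostic
#' counts sufficient to reproduce the run exactly.
#'
#' @param disease_config Path to the disease YAML/JSON.
#' @param microdata,coverage,u5mr Paths to the three input CSVs.
#' @param outdir Output directory.
#' @param ... Options forwarded to [estimate_gradients()] (`k`, `seed`,
#'   `anchor_risk`, `sample_efficacy_ui`, `c_adjusted`, `p_cap`).
#' @param figure Attempt the summary figure (default TRUE).
#' @return Invisibly, the `estimate_result`.
#' @export
run_estimate <- function(disease_config, microdata, coverage, u5mr, outdir,
                         ..., figure = TRUE) {
  spec <- stage("load", load_disease_config(disease_config))
  res <- estimate_gradients(spec, microdata, coverage, u5mr, ...)
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", outdir)
  named <- setNames(res$gradients,
                    paste0(spec$disease, "_", names(res$gradients)))
  stage("report", render_outputs(named, outdir, figure = figure))
  res$manifest$disease_config <-
    list(path = disease_config, md5 = unname(tools::md5sum(disease_config)))
  jsonlite::write_json(res$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

#' Write a scenario's synthetic inputs to disk
#'
#' Generates and writes `microdata.csv`, `coverage.csv`, `u5mr.csv`, the
#' implied `disease.yaml` configuration and a `truth.json` with the
#' generative parameters and true per-profile probabilities.
#'
#' @param spec A [scenario_spec()] or a path to a scenario YAML.
#' @param outdir Output directory.
#' @return Invisibly, the paths written.
#' @export
run_simulate <- function(spec, outdir) {
  if (is.character(spec)) spec <- stage("load", load_scenario(spec))
  stopifnot(inherits(spec, "scenario_spec"))
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", outdir)
  children <- stage("simulate", generate_children(spec))
  tables <- stage("simulate", generate_tables(spec))
  paths <- file.path(outdir, c("microdata.csv", "coverage.csv", "u5mr.csv",
                               "disease.yaml", "truth.json"))
  write.csv(as.data.frame(children), paths[1], row.names = FALSE)
  write.csv(as.data.frame(tables$coverage), paths[2], row.names = FALSE)
  write.csv(data.frame(quintile = 1:5, u5mr_per_1000 = tables$u5mr),
            paths[3], row.names = FALSE)
  write_disease_yaml(scenario_disease_spec(spec), paths[4])
  truth <- list(
    disease = spec$disease, seed = spec$seed, rho = spec$rho,
    p0_case = spec$p0_case, p0_death = spec$p0_death,
    factors = lapply(spec$factors, function(f)
      list(name = f$name, levels = f$levels, rr_case = f$rr_case,
           rr_death = f$rr_death)),
    true_p_case = true_profile_probabilities(spec, "case"),
    true_p_death = true_profile_probabilities(spec, "death"))
  jsonlite::write_json(truth, paths[5], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

write_disease_yaml <- function(spec, path) {
  block <- function(f, slot) list(name = f$name, levels = as.list(f$levels),
                                  rr = as.list(f[[slot]]))
  yaml::write_yaml(list(
    disease = spec$disease,
    case_factors = lapply(spec$case_factors, block, slot = "rr_case"),
    death_factors = lapply(spec$death_factors, block, slot = "rr_death"),
    vaccines = lapply(spec$vaccines, function(v)
      list(name = v$name, efficacy = v$efficacy, ui = as.list(v$ui),
           attributable_fraction = v$attributable_fraction)),
    treatment = list(efficacy = spec$treatment_efficacy,
                     ui = as.list(spec$treatment_ui))), path)
  invisible(path)
}
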