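test_that("quintiles are assigned uniformly and generation is seed-deterministic", {
  sc <- default_scenario(n_children = 1000, seed = 3)
  ch <- generate_children(sc)
  sizes <- table(ch$quintile)
  expect_length(sizes, 5L)
  expect_true(all(sizes > 120 & sizes < 280))
  expect_identical(as.data.frame(generate_children(sc)), as.data.frame(ch))
  sc2 <- default_scenario(n_children = 1000, seed = 4)
  expect_false(identical(as.data.frame(generate_children(sc2)),
                         as.data.frame(ch)))
})

test_that("degenerate prevalence concentrates all children in one profile", {
  f <- list(f_stunting(), f_wasting())
  prev <- list(stunting = rbind(1, 0, 0)[, rep(1, 5)],
               wasting = rbind(1, 0, 0)[, rep(1, 5)])
  prev <- lapply(prev, function(P) matrix(P, 3, 5))
  sc <- scenario_spec("diarrhoea", 500, f, prev,
                      vaccines = list(list(spec = vaccine_spec("rotavirus", 0.5),
                                           base = 0.5, slope = 0)),
                      careseek = list(diarrhoea = c(0.5, 0)),
                      u5mr = rep(80, 5), p0_case = 0.05, p0_death = 0.004,
                      treatment_efficacy = 0.9, seed = 2)
  ch <- generate_children(sc)
  pt <- tabulate_counts(ch, enumerate_profiles(f))
  expect_equal(pt$totals[1], 500)
  expect_equal(sum(pt$totals[-1]), 0)
})

test_that("generated level frequencies match the configured prevalence", {
  f <- list(f_stunting())
  P <- matrix(rep(c(0.55, 0.30, 0.15), 5), 3, 5)
  sc <- scenario_spec("diarrhoea", 100000, f, list(stunting = P),
                      vaccines = list(list(spec = vaccine_spec("rotavirus", 0.5),
                                           base = 0.5, slope = 0)),
                      careseek = list(diarrhoea = c(0.5, 0)),
                      u5mr = rep(80, 5), p0_case = 0.05, p0_death = 0.004,
                      treatment_efficacy = 0.9, seed = 77)
  ch <- generate_children(sc)
  tab <- table(factor(ch$stunting, levels = 0:2))
  expect_gt(chisq.test(tab, p = c(0.55, 0.30, 0.15))$p.value, 0.001)
})

test_that("the multiplicative truth multiplies relative risks onto the baseline", {
  f1 <- risk_factor("x", c("a", "b", "c"), rr_case = c(1, 2, 4),
                    rr_death = c(1, 1, 1))
  P <- matrix(rep(c(0.5, 0.3, 0.2), 5), 3, 5)
  sc <- scenario_spec("diarrhoea", 100, list(f1), list(x = P),
                      vaccines = list(list(spec = vaccine_spec("rotavirus", 0.5),
                                           base = 0.5, slope = 0)),
                      careseek = list(diarrhoea = c(0.5, 0)),
                      u5mr = rep(80, 5), p0_case = 0.01, p0_death = 0.002,
                      treatment_efficacy = 0.9, seed = 1)
  expect_equal(true_profile_probabilities(sc, "case"), c(0.01, 0.02, 0.04))
  expect_equal(true_profile_probabilities(sc, "death"), rep(0.002, 3))
  # an infeasible truth (probability above 1) is rejected at construction
  f2 <- risk_factor("x", c("a", "b", "c"), rr_case = c(1, 2, 4),
                    rr_death = c(1, 2, 3))
  expect_error(scenario_spec("diarrhoea", 100, list(f2), list(x = P),
                             vaccines = list(), careseek = list(),
                             u5mr = rep(80, 5), p0_case = 0.3, p0_death = 0.002,
                             treatment_efficacy = 0.9, seed = 1),
               "infeasible")
})

test_that("coverage tables follow the clamped linear form", {
  sc <- default_scenario(n_children = 100, seed = 1)
  sc$vaccines[[1]]$base <- 0.5
  sc$vaccines[[1]]$slope <- 0.1
  tb <- generate_tables(sc)
  expect_equal(tb$coverage$rotavirus_coverage, seq(0.3, 0.7, by = 0.1))

  sc$vaccines[[1]]$slope <- 0
  expect_equal(generate_tables(sc)$coverage$rotavirus_coverage, rep(0.5, 5))

  sc$vaccines[[1]]$base <- 0.9
  sc$vaccines[[1]]$slope <- 0.3
  cv <- generate_tables(sc)$coverage$rotavirus_coverage
  expect_equal(cv, pmin(1, pmax(0, 0.9 + 0.3 * ((1:5) - 3))))
  expect_equal(cv[4:5], c(1, 1))
  expect_equal(unname(tb$u5mr), sc$u5mr)
})

test_that("the correlated mode induces cross-factor association", {
  sc0 <- default_scenario(n_children = 20000, seed = 9, rho = 0)
  sc1 <- default_scenario(n_children = 20000, seed = 9, rho = 0.8)
  ch0 <- generate_children(sc0)
  ch1 <- generate_children(sc1)
  expect_lt(abs(cor(ch0$stunting, ch0$wasting)), 0.05)
  expect_gt(cor(ch1$stunting, ch1$wasting), 0.3)
})

test_that("scenario YAML files load into equivalent specifications", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "disease: diarrhoea",
    "n_children: 400",
    "factors:",
    "  - name: stunting",
    "    levels: [none, moderate, severe]",
    "    rr_case: [1, 1.6, 2.3]",
    "    rr_death: [1, 2.0, 3.2]",
    "prevalence:",
    "  stunting:",
    "    - [0.55, 0.58, 0.60, 0.62, 0.65]",
    "    - [0.30, 0.28, 0.27, 0.26, 0.24]",
    "    - [0.15, 0.14, 0.13, 0.12, 0.11]",
    "vaccines:",
    "  - {name: rotavirus, efficacy: 0.5, ui: [0.11, 0.72],",
    "     attributable_fraction: 0.28, base: 0.55, slope: 0.08}",
    "careseek:",
    "  diarrhoea: [0.45, 0.07]",
    "  ari: [0.50, 0.07]",
    "u5mr: [110, 95, 82, 70, 55]",
    "p0_case: 0.06",
    "p0_death: 0.004",
    "treatment: {efficacy: 0.93, ui: [0.83, 0.98]}",
    "seed: 12"), path)
  sc <- load_scenario(path)
  expect_s3_class(sc, "scenario_spec")
  expect_equal(sc$n_children, 400L)
  expect_equal(sc$prevalence$stunting[2, 1], 0.30)
  ch <- generate_children(sc)
  expect_equal(nrow(ch), 400L)
})
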