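test_that("u5mr extrapolation is proportional and mean-normalized", {
  d1 <- deaths_extrapolated(rep(1, 5), rep(80, 5))
  expect_equal(unname(d1$deaths), rep(1, 5))
  d2 <- deaths_extrapolated(rep(1, 5), c(2, 1, 1, 1, 1) * 60)
  expect_equal(unname(d2$deaths[1] / d2$deaths[2]), 2)
  set.seed(3)
  cases <- matrix(runif(20, 0, 50), 4, 5)
  u5mr <- runif(5, 40, 130)
  d3 <- deaths_extrapolated(cases, u5mr)
  expect_equal(d3$replicates, sweep(cases, 2, u5mr / mean(u5mr), `*`),
               ignore_attr = TRUE)
  expect_error(deaths_extrapolated(rep(1, 5), c(0, 1, 1, 1, 1)), "positive")
  # gradient level is invariant to rescaling either input
  g1 <- normalize_gradient(quintile_risks(d3, rep(100, 5)))
  g2 <- normalize_gradient(quintile_risks(deaths_extrapolated(cases * 3,
                                                              u5mr * 0.5),
                                          rep(100, 5)))
  expect_equal(g1$mean, g2$mean, tolerance = 1e-12)
})

test_that("direct and case-risk approaches coincide for identical configs and seed", {
  sc <- default_scenario(n_children = 1500, seed = 5)
  ch <- generate_children(sc)
  spec <- scenario_disease_spec(sc)
  # same factor sets AND identical case/death relative risks
  equalised <- lapply(spec$death_factors, function(f) {
    f$rr_case <- f$rr_death
    f
  })
  spec$case_factors <- equalised
  spec$death_factors <- equalised
  cov <- generate_tables(sc)$coverage
  a <- deaths_direct(spec, ch, cov, k = 15, seed = 11)
  b <- deaths_from_case_risks(spec, ch, cov, k = 15, seed = 11)
  expect_identical(a$replicates, b$replicates)
})

test_that("zero treatment efficacy reduces the case-risk approach to immunization only", {
  sc <- default_scenario(n_children = 1500, seed = 6)
  ch <- generate_children(sc)
  spec <- scenario_disease_spec(sc)
  spec$treatment_efficacy <- 0
  cov <- generate_tables(sc)$coverage
  b <- deaths_from_case_risks(spec, ch, cov, k = 10, seed = 2)
  vm <- quintgrad:::vaccine_multipliers(spec$vaccines, cov)
  manual <- quintgrad:::ensemble_quintile_counts(
    b$fit$ensemble$solutions, b$fit$profiles$counts, vm)
  expect_equal(b$replicates, manual, ignore_attr = TRUE)
})

test_that("quintile deaths match a plug-in computation from the known truth", {
  # identified single-factor scenario: the anchored system pins the truth
  f <- list(f_stunting())
  P <- matrix(rep(c(0.6, 0.28, 0.12), 5), 3, 5)
  sc <- scenario_spec("diarrhoea", 20000, f, list(stunting = P),
                      vaccines = list(list(spec = vaccine_spec("rotavirus", 0.5,
                                                               c(0.11, 0.72), 0.28),
                                           base = 0.55, slope = 0.08)),
                      careseek = list(diarrhoea = c(0.45, 0.07),
                                      ari = c(0.5, 0.07), fever = c(0.55, 0.06)),
                      u5mr = c(110, 95, 82, 70, 55),
                      p0_case = 0.06, p0_death = 0.004,
                      treatment_efficacy = 0.93, seed = 31)
  ch <- generate_children(sc)
  spec <- scenario_disease_spec(sc)
  cov <- generate_tables(sc)$coverage
  pt <- tabulate_counts(ch, enumerate_profiles(f))
  truth <- true_profile_probabilities(sc, "death")
  anchor <- sum(pt$totals * truth) / sum(pt$totals)
  d <- deaths_direct(spec, ch, cov, k = 10, seed = 3, anchor_risk = anchor)
  vm <- quintgrad:::vaccine_multipliers(spec$vaccines, cov)
  tm <- treatment_multiplier(spec$treatment_efficacy,
                             resolve_treatment_coverage(cov, "diarrhoea"))
  plug_in <- as.vector(truth %*% pt$counts) * vm * tm
  expect_equal(unname(d$deaths), unname(plug_in), tolerance = 1e-6)
})

test_that("reruns with the same master seed are identical", {
  sc <- default_scenario(n_children = 1200, seed = 8)
  ch <- generate_children(sc)
  spec <- scenario_disease_spec(sc)
  cov <- generate_tables(sc)$coverage
  d1 <- deaths_direct(spec, ch, cov, k = 8, seed = 21)
  d2 <- deaths_direct(spec, ch, cov, k = 8, seed = 21)
  expect_identical(d1$replicates, d2$replicates)
})

test_that("the main analysis averages normalized gradients and renormalizes", {
  g <- normalize_gradient(rbind(c(5, 4, 3, 2, 1)))
  expect_equal(main_analysis(g, g)$mean, g$mean)

  gA <- normalize_gradient(rbind(c(3, 2.5, 2, 1.5, 1)))
  gC <- normalize_gradient(rbind(c(1, 1.5, 2, 2.5, 3)))
  m <- main_analysis(gA, gC)
  avg <- (gA$mean + gC$mean) / 2
  expect_equal(m$mean, avg / min(avg))
  expect_identical(min(m$mean), 1)

  set.seed(41)
  r1 <- matrix(rlnorm(50), 10, 5); r2 <- matrix(rlnorm(50), 10, 5)
  gA2 <- normalize_gradient(r1); gC2 <- normalize_gradient(r2)
  m2 <- main_analysis(gA2, gC2)
  avg2 <- (gA2$mean + gC2$mean) / 2
  expect_equal(m2$mean, avg2 / min(avg2))
  expect_error(main_analysis(gA2, gA2[1:4, ]), "length")
  bad <- gA2; bad$mean <- bad$mean * 2
  expect_error(main_analysis(bad, gC2), "normalized")
})
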