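test_that("monotone rearrangement is the identity on feasible inputs and midpoints violated pairs", {
  f <- list(f_sanitation())
  ord <- dominance_order(enumerate_profiles(f))
  expect_identical(monotone_rearrange(c(0.2, 0.8), ord), c(0.2, 0.8))
  # profile 2 dominates profile 1 but carries the smaller probability
  expect_equal(monotone_rearrange(c(0.8, 0.2), ord), c(0.5, 0.5))
})

test_that("rearranged vectors are feasible and stay within the input hull", {
  pt <- enumerate_profiles(list(f_stunting(), f_wasting()))
  ord <- dominance_order(pt)
  pairs <- brute_dominance_pairs(pt$profiles)
  set.seed(13)
  for (i in 1:30) {
    p <- runif(9)
    r <- monotone_rearrange(p, ord)
    expect_true(all(r[pairs[, 1]] >= r[pairs[, 2]]))
    expect_gte(min(r), min(p) - 1e-12)
    expect_lte(max(r), max(p) + 1e-12)
  }
})

test_that("a consistent anchored system is solved exactly from any seed", {
  fx <- two_profile_system()
  for (seed in c(1L, 7L, 99L)) {
    s <- solve_once(fx$system, fx$order, seed = seed)
    expect_lt(s$objective, 1e-12)
    expect_equal(s$p, fx$exact, tolerance = 1e-8)
  }
})

test_that("an infeasible unconstrained optimum lands on the dominance boundary", {
  # hand-built system whose marginal equation wants p2 = 0.5 * p1, which the
  # dominance constraint p2 >= p1 forbids; optimum has the pair tied
  sys <- structure(list(
    A = rbind(c(-0.5, 1), c(10, 10)), b = c(0, 2), scale = c(1, 20),
    labels = c("x:high", "anchor"), n = c(10, 10), J = 2L,
    anchored = TRUE, anchor_risk = 0.1, omitted = character(0)),
    class = "linear_system")
  ord <- structure(list(edges = cbind(a = 2L, b = 1L), n_profiles = 2L),
                   class = "dominance_order")
  s <- solve_once(sys, ord, seed = 5)
  expect_equal(s$p[1], s$p[2], tolerance = 1e-9)
  # 1-d oracle along the constrained ray p1 = p2 = t
  oracle <- optimize(function(t) residual_objective(sys, c(t, t)),
                     c(0, 1), tol = 1e-12)
  expect_equal(s$objective, oracle$objective, tolerance = 1e-9)
  expect_equal(s$p[1], oracle$minimum, tolerance = 1e-6)
})

test_that("identical seeds reproduce solutions bitwise", {
  fx <- two_profile_system()
  s1 <- solve_once(fx$system, fx$order, seed = 42)
  s2 <- solve_once(fx$system, fx$order, seed = 42)
  expect_identical(s1$p, s2$p)
  expect_identical(s1$objective, s2$objective)
})

test_that("ensembles of a uniquely solvable system collapse to the solution", {
  fx <- two_profile_system()
  # the anchored system has as many independent equations as unknowns
  expect_equal(qr(fx$system$A / fx$system$scale)$rank, fx$system$J)
  ens <- sample_ensemble(fx$system, fx$order, k = 50, seed = 2)
  expect_equal(nrow(ens$solutions), 50L)
  spread <- apply(ens$solutions, 2, function(x) diff(range(x)))
  expect_lt(max(spread), 1e-6)
  # singleton ensemble: summary equals the solution
  e1 <- sample_ensemble(fx$system, fx$order, k = 1, seed = 3)
  expect_equal(e1$summary$mean, as.vector(e1$solutions[1, ]))
  expect_equal(e1$summary$ui_low, e1$summary$ui_high)
})

test_that("ensemble summaries match independent sort-based percentiles", {
  vals <- matrix(c(0.1, 0.2, 0.3), 3, 1)
  ens <- structure(list(solutions = vals), class = "solution_ensemble")
  sm <- summarize_ensemble(ens)
  expect_equal(sm$median, 0.2)
  expect_equal(sm$mean, 0.2)

  const <- structure(list(solutions = matrix(0.4, 20, 2)),
                     class = "solution_ensemble")
  smc <- summarize_ensemble(const)
  expect_equal(smc$mean, smc$ui_low)
  expect_equal(smc$median, smc$ui_high)

  set.seed(17)
  S <- matrix(runif(3000), 1000, 3)
  sm3 <- summarize_ensemble(structure(list(solutions = S),
                                      class = "solution_ensemble"))
  for (j in 1:3) {
    srt <- sort(S[, j])
    expect_equal(sm3$median[j], median(srt))
    expect_equal(sm3$ui_low[j], quantile(srt, 0.025, names = FALSE))
    expect_equal(sm3$ui_high[j], quantile(srt, 0.975, names = FALSE))
  }
  expect_error(summarize_ensemble(structure(list(solutions = NULL),
                                            class = "solution_ensemble")),
               "empty")
})

test_that("every accepted ensemble solution is dominance-feasible", {
  sc <- default_scenario(n_children = 2000, seed = 23)
  ch <- generate_children(sc)
  spec <- scenario_disease_spec(sc)
  pt <- tabulate_counts(ch, enumerate_profiles(spec$death_factors))
  ord <- dominance_order(pt)
  sys <- add_anchor(build_marginal_equations(pt, spec$death_factors, "death"),
                    0.05)
  ens <- sample_ensemble(sys, ord, k = 100, seed = 4)
  pairs <- brute_dominance_pairs(pt$profiles)
  viol <- apply(ens$solutions, 1, function(p)
    any(p[pairs[, 1]] < p[pairs[, 2]] - 1e-9))
  expect_identical(sum(viol), 0L)
  expect_true(all(ens$solutions >= 0 & ens$solutions <= 1))
  # objectives sit within the acceptance window of the best
  expect_true(all(ens$objectives <= min(ens$objectives) * 1.01 + 1e-12))
})

test_that("solver objectives match dense grid search on tiny systems", {
  fx <- two_profile_system()
  s <- solve_once(fx$system, fx$order, seed = 8)
  g <- grid_min_objective(fx$system, fx$order, res = 0.01)
  expect_lte(s$objective, g + 1e-10)
})
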