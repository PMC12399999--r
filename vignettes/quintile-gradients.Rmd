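---
title: "Estimating wealth-quintile gradients in child deaths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating wealth-quintile gradients in child deaths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quintgrad)
```

## The problem

Household surveys in low- and middle-income countries record, for each child
under five, a wealth quintile (I = poorest to V = wealthiest), ordered risk
factors (stunting, wasting, underweight, vitamin A deficiency, unsafe
sanitation), and quintile-level coverage of immunization and care-seeking.
They do not record cause-specific deaths by wealth. quintgrad estimates how
the risk of dying from diarrhoea, pneumonia or measles varies across wealth
quintiles by combining these survey inputs with published relative risks,
vaccine and treatment efficacies, and quintile-disaggregated under-5
mortality.

## The model

**Risk profiles.** Each child occupies one *risk profile* $j$: a combination
of one severity level per risk factor (at most four factors per outcome, each
with 2–3 ordered levels, so at most 81 profiles). Weighted child counts
$n_{jq}$ are tabulated per profile $j$ and quintile $q$.

**The marginal relative-risk system.** An unknown probability $p_j$ of the
outcome (acquiring the disease, or dying of it) is attached to each profile.
A published relative risk $r_{f\ell}$ for level $\ell$ of factor $f$ asserts
that the mean risk among children at that level is $r_{f\ell}$ times the mean
among children at the factor's reference level, marginally over the other
factors:

$$\frac{1}{N_{f\ell}}\sum_{j:\,\ell_f(j)=\ell} n_j\,p_j
  \;-\; r_{f\ell}\,\frac{1}{N_{f0}}\sum_{j:\,\ell_f(j)=0} n_j\,p_j \;=\; 0 ,$$

with $N_{f\ell}$ the total weight at level $\ell$ and $n_j = \sum_q n_{jq}$.
One such equation per non-reference level, plus one *anchor* equation fixing
the population mean risk, $\sum_j n_j p_j = \rho \sum_j n_j$. Both group-mean
terms are divided by their group weights, so every marginal equation is
dimensionless: rescaling all counts leaves the residuals unchanged, and
factors with unbalanced level groups contribute comparably. The error
functional is the unweighted sum of squared scaled residuals — the simplest
defensible choice, kept explicit in `residual_objective()` so alternatives
can be audited against it.

**Dominance monotonicity.** If profile $a$ is at least as severe as profile
$b$ in *every* factor, then $p_a \ge p_b$. The constraint set is the product
partial order's cone, stored as its cover relations (on the full product
lattice these are the single-step severity moves). The box $0 \le p_j \le 1$
completes the feasible set. Empty profiles keep their unknowns and their
monotonicity constraints — this keeps the cone well defined — but carry zero
weight in every equation, so the data do not identify them.

**The solution ensemble.** The constrained least-squares problem typically
has a *set* of minimizers, not a point: with $E$ equations and $J > E$
profiles the zero-residual set is an affine section of dimension $J - E$
intersected with the cone. The method therefore samples 1000 minimizers from
random restarts: each restart draws a uniform start in $[0, 0.5]^J$,
rearranges it onto the cone (midpoint averaging over violated cover edges in
a fixed lexicographic linear extension, followed by an exact
max-accumulation pass), and runs projected gradient descent with Dykstra
projections, alternated with an exact refinement step described below.
Restarts whose objective is within 1% (relative, plus $10^{-12}$) of the
best objective found are accepted until 1000 solutions accumulate.
Per-profile means, medians and percentile 95% uncertainty intervals
summarize the ensemble. All restart seeds derive deterministically from one
master seed.

## Identifiability: what the ensemble mean does and does not estimate

The marginal system pins down group means per factor level — hence any
zero-residual solution reproduces the configured relative risks *exactly*
(`implied_relative_risks()`), and so does the ensemble mean, because the
constraints are affine. Per-profile probabilities are point-identified only
when the anchored system has full column rank; with a single 3-level factor
(3 equations, 3 unknowns) recovery is exact to machine precision, which is
how the package's parameter-recovery checks are constructed. With several
factors the zero-residual polytope has positive dimension, and the ensemble
*maps* that non-uniqueness instead of hiding it: the per-profile uncertainty
intervals then reflect genuine non-identification, not sampling noise. The
quintile-level gradients are far better determined than individual profiles,
because they aggregate over profiles with data-driven weights.

## Coverage adjustment

Immunization rescales expected outcomes in quintile $q$ by
$\prod_v\left(1 - \mathrm{AF}_v\, e_v\, c_{vq}\right)$, where $e_v$ is the
vaccine's efficacy, $c_{vq}$ its coverage in quintile $q$, and
$\mathrm{AF}_v$ the fraction of the disease's cases attributable to the agent
the vaccine targets (1 for measles vaccine; 0.330 and 0.216 for the
pneumococcal and Hib components of pneumonia). Vaccines combine
multiplicatively under the assumption of disjoint aetiologies. A vaccine
absent from the national programme is zero coverage, giving a factor of 1.

Treatment rescales **death** outcomes only, by $1 - e_T\, s_q$ with $e_T$
the treatment efficacy and $s_q$ the quintile's care-seeking proportion
(the survey proxy for effective treatment coverage): treatment averts death
given disease, while immunization averts the case itself. Care-seeking for
pneumonia is proxied by the acute-respiratory-infection column, falling back
to fever; measles uses the mean of the diarrhoea and respiratory proxies,
with the same fallback inside the respiratory component.

Optionally (`sample_efficacy_ui = TRUE`), efficacies are redrawn per
ensemble replicate from Beta distributions moment-matched to their published
95% intervals, propagating efficacy uncertainty into the gradient intervals.

## Linking morbidity and mortality

Three simple linking models produce quintile death distributions:

* **A (direct):** fit the ensemble on the mortality risk factors; apply
  immunization and treatment multipliers; deaths per quintile and replicate
  are $\sum_j n_{jq}\, p^{(k)}_j m_q$.
* **B (case-risk):** fit on the morbidity risk factors, then apply both
  multipliers. Reported for comparison, excluded from the headline result.
* **C (extrapolated):** take the fitted case distribution (immunization
  adjusted by default; `c_adjusted = FALSE` uses the raw fit) and scale by
  the quintile's share of under-5 mortality,
  $d_q = \text{cases}_q \cdot u_q / \bar u$. The normalizer $\bar u$ is
  arbitrary and cancels in the gradient.

The headline gradient averages the *normalized* gradients of A and C
elementwise and renormalizes. Averaging normalized gradients rather than
absolute deaths keeps the two approaches on a common scale — their absolute
levels are set by different, equally arbitrary anchors.

## Reporting

Per-replicate quintile risks $d^{(k)}_q / \text{pop}_q$ are averaged across
the ensemble; the five means are divided by their minimum, so the
lowest-risk quintile takes the reference value 1 *exactly*. Medians and
percentile 95% intervals are computed on the per-replicate vectors, each
divided by its own value at the reference quintile. The reference quintile
is reported explicitly because it is occasionally not the wealthiest.

## The anchor and scale invariance

The anchor value $\rho$ (default 0.05) only sets the overall scale of the
fitted probabilities; the reported gradients are ratios and should not
depend on it. The solver makes this exact by construction: anchored systems
are fitted at a fixed reference anchor and the solution is rescaled linearly
to the requested $\rho$ (the marginal equations and the dominance cone are
homogeneous, so the rescaled solution solves the rescaled problem). The
rescaled probabilities are clipped at 1 with a warning in the saturated
regime, where scale invariance genuinely fails and the anchor must be chosen
on substantive grounds.

## Numerical choices

* Projected gradient descent uses step $1/(2\sigma_{\max}(A)^2)$ and stops
  on iterate stabilisation or when the objective decrease falls below
  $10^{-13}$ relative.
* Feasibility projections use Dykstra's algorithm over the box and the edge
  halfspaces (tolerance $10^{-13}$, cycle cap 300), followed by one exact
  max-accumulation pass along the lexicographic linear extension, so
  accepted solutions satisfy the constraints exactly, not just to tolerance.
* The refinement step merges profiles joined by active edges (within
  $10^{-7}$), fixes variables at active bounds, and takes one pseudo-inverse
  step to the nearest least-squares solution on that manifold; when the step
  leaves the feasible set, the longest feasible sub-step is taken (the
  objective is convex along it). Alternating descent and refinement (up to 8
  rounds) converges to the constrained optimum at machine precision while
  preserving the start-dependence that lets the ensemble cover the minimizer
  set. The rearrangement of random starts is deliberately *not* a uniform
  sampler of the feasible set — no simple scheme is — so the ensemble maps
  the minimizer set under a fixed, reproducible sampling rule rather than an
  exactly uniform one.
* Midpoint rearrangement converges only geometrically on chains, so the
  sweep phase stops at violations below $10^{-12}$ (with a sweep cap) and
  the max-accumulation pass makes feasibility exact.

## The synthetic-data generator

`scenario_spec()` fixes a survey-like world with known truth: five equal
quintiles; per-quintile level prevalences per factor; linear
coverage/care-seeking gradients `clamp(base + slope (q - 3), 0, 1)`;
a quintile u5mr vector; and a multiplicative truth
$p_j = p_0 \prod_f r_{f\ell_f(j)}$ for both outcomes. The bundled
`default_scenario()` uses 10 000 children, three factors (stunting, wasting
3-level, unsafe sanitation 2-level; 18 profiles), severe levels more
prevalent and coverage lower among poorer quintiles, u5mr falling from 110
to 55 per 1000, and illustrative relative risks of plausible magnitude
(case 1.4–2.8, death 1.5–3.6), with a rotavirus vaccine (efficacy 0.50,
attributable fraction 0.28) and diarrhoea treatment efficacy 0.93.

With independent factors and quintile-constant prevalence the multiplicative
truth satisfies the marginal equations exactly in expectation (the
zero-residual regime used for recovery tests); quintile-graded prevalence
pools into correlated factors and makes the system genuinely inconsistent,
which is the regime real surveys produce. A `rho > 0` option draws levels
through a shared Gaussian latent severity for stronger within-child
correlation. The generator emulates none of the survey design beyond
weights (no clusters or strata), and its truth is multiplicative by
construction — passing recovery tests shows the estimation machinery is
correct, not that real risks combine multiplicatively.

## Worked example

```{r, eval = FALSE}
sc <- default_scenario(seed = 1)
sim <- tempfile(); run_simulate(sc, sim)
out <- tempfile()
res <- run_estimate(file.path(sim, "disease.yaml"),
                    file.path(sim, "microdata.csv"),
                    file.path(sim, "coverage.csv"),
                    file.path(sim, "u5mr.csv"),
                    out, k = 1000, seed = 1)
res$gradients$main
```

The run writes one gradient CSV per linking approach, a bar-chart figure and
a `manifest.json` (versions, seed, configuration, input checksums, dropped
row counts, sampler acceptance rate) sufficient to reproduce the run
byte-for-byte.

## Problem sizes and tunables

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 1000 | ensemble size (accepted minimizers per outcome) |
| `anchor_risk` | 0.05 | overall outcome probability fixing the scale |
| `p_cap` | 0.5 | upper bound of the uniform random starts |
| acceptance window | 1% relative | closeness to the best objective |
| `attempt_cap` | 10·k | restart budget before erroring with diagnostics |
| UI | 2.5–97.5 percentiles | ensemble uncertainty convention |

The package's own validation runs use the bundled 18-profile scenario at
10 000 children with full 1000-replicate ensembles, 50 000 children for
parameter recovery, and 20 independent scenario draws at k = 100 for the
monotonicity check.

## Limitations

* Relative-risk magnitudes, and the rotavirus attributable fraction, are
  shipped as clearly labelled illustrative placeholders; real analyses must
  supply literature values through the disease configuration.
* The model is static: no transmission dynamics or herd effects, which
  matter most for measles; only first-dose measles vaccination is
  represented.
* Care-seeking is an imperfect proxy for effective treatment coverage.
* Complete-case filtering can shrink the analysed sample and its
  representativeness; dropped-row counts are reported in the manifest.
* Per-profile probabilities are reported with honest non-identification
  intervals (see the identifiability section); comparisons should be made at
  the gradient level.
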