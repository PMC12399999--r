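# Shared in-code fixtures: small factors, specs and tables built on the fly.

f_stunting <- function(rr_case = c(1, 1.6, 2.3), rr_death = c(1, 2.0, 3.2))
  risk_factor("stunting", c("none", "moderate", "severe"),
              rr_case = rr_case, rr_death = rr_death)

f_wasting <- function(rr_case = c(1, 1.8, 2.8), rr_death = c(1, 2.2, 3.6))
  risk_factor("wasting", c("none", "moderate", "severe"),
              rr_case = rr_case, rr_death = rr_death)

f_sanitation <- function()
  risk_factor("unsafe_sanitation", c("improved", "unimproved"),
              rr_case = c(1, 1.4), rr_death = c(1, 1.5))

toy_spec <- function(factors = list(f_stunting(), f_wasting()),
                     vaccines = list(vaccine_spec("rotavirus", 0.5,
                                                  ui = c(0.11, 0.72),
                                                  attributable_fraction = 0.28)),
                     treatment_efficacy = 0.93)
  disease_spec("diarrhoea", case_factors = factors, death_factors = factors,
               vaccines = vaccines, treatment_efficacy = treatment_efficacy,
               treatment_ui = c(0.83, 0.98))

# coverage table built directly (same shape as load_coverage() output)
cov_table <- function(rotavirus = rep(0, 5), diarrhoea = rep(0.5, 5),
                      ari = rep(0.5, 5), fever = rep(0.5, 5), ...) {
  df <- data.frame(quintile = 1:5, rotavirus_coverage = rotavirus,
                   careseek_diarrhoea = diarrhoea, careseek_ari = ari,
                   careseek_fever = fever)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  structure(df, class = c("coverage_table", "data.frame"))
}

# children table from explicit columns
make_children <- function(quintile, levels, factors, weight = 1) {
  df <- as.data.frame(levels)
  names(df) <- vapply(factors, `[[`, "", "name")
  df$quintile <- quintile
  df$weight <- weight
  child_table(df, factors)
}

# profile table with hand-set counts (bypasses tabulation)
with_counts <- function(pt, counts) {
  pt$counts <- counts
  pt$totals <- rowSums(counts)
  pt
}

# ordered pairs (a, b), a != b, with a componentwise >= b -- the reference
# dominance relation computed by exhaustive comparison
brute_dominance_pairs <- function(M) {
  J <- nrow(M)
  out <- matrix(0L, 0L, 2L)
  for (a in seq_len(J)) for (b in seq_len(J)) {
    if (a != b && all(M[a, ] >= M[b, ]))
      out <- rbind(out, c(a, b))
  }
  out
}

# reachability closure of a dominance_order's cover edges
closure_pairs <- function(order) {
  J <- order$n_profiles
  R <- matrix(FALSE, J, J)
  R[order$edges] <- TRUE
  repeat {
    R2 <- R | ((R %*% R) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  which(R, arr.ind = TRUE)
}

# residual objective via an explicit per-equation loop (independent oracle)
naive_objective <- function(system, p) {
  tot <- 0
  for (i in seq_len(nrow(system$A))) {
    r <- (sum(system$A[i, ] * p) - system$b[i]) / system$scale[i]
    tot <- tot + r^2
  }
  tot
}

# two-profile anchored fixture: one 2-level factor, rr = 2, n = (10, 10),
# overall risk 0.1; exact solution (1/15, 2/15)
two_profile_system <- function() {
  f <- risk_factor("stunting", c("none", "stunted"), rr_case = c(1, 2),
                   rr_death = c(1, 2))
  ch <- make_children(quintile = rep(1L, 20),
                      levels = list(stunting = rep(0:1, each = 10)),
                      factors = list(f))
  pt <- tabulate_counts(ch, enumerate_profiles(list(f)))
  ord <- dominance_order(pt)
  sys <- add_anchor(build_marginal_equations(pt, list(f), "case"), 0.1)
  list(factors = list(f), profiles = pt, order = ord, system = sys,
       exact = c(1 / 15, 2 / 15))
}

# dense feasible grid search over [0, 1]^J at a given resolution; returns the
# minimum residual objective over dominance-feasible grid points
grid_min_objective <- function(system, order, res = 0.01) {
  J <- system$J
  At <- system$A / system$scale
  bt <- system$b / system$scale
  axis <- seq(0, 1, by = res)
  ea <- order$edges[, "a"]; eb <- order$edges[, "b"]
  eval_block <- function(P) {
    keep <- rep(TRUE, nrow(P))
    for (e in seq_along(ea)) keep <- keep & (P[, ea[e]] >= P[, eb[e]])
    P <- P[keep, , drop = FALSE]
    if (!nrow(P)) return(Inf)
    Rm <- P %*% t(At)
    Rm <- sweep(Rm, 2L, bt, `-`)
    min(rowSums(Rm * Rm))
  }
  if (J <= 3L) {
    P <- as.matrix(do.call(expand.grid, rep(list(axis), J)))
    colnames(P) <- NULL
    eval_block(P)
  } else {
    sub <- as.matrix(do.call(expand.grid, rep(list(axis), J - 1L)))
    best <- Inf
    for (x1 in axis) {
      P <- cbind(x1, sub)
      colnames(P) <- NULL
      best <- min(best, eval_block(P))
    }
    best
  }
}

write_csv_fixture <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}
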