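# The marginal relative-risk linear system on per-profile probabilities.

#' Build the marginal relative-risk equations
#'
#' For every factor f and non-reference level l, the relative risk rr
#' asserts that the mean outcome probability among children at level l of f
#' equals rr times the mean among children at the reference level of f,
#' marginally over the other factors. With per-profile unknowns p and
#' weighted counts n, each equation is stored in dimensionless group-mean
#' form
#'
#'   (1/N_l) * sum over j with level l of n_j p_j
#'     - rr * (1/N_0) * sum over j with level 0 of n_j p_j  =  0,
#'
#' where N_l is the total weight at level l. Equations whose level group (or
#' the reference group) is empty are omitted and reported via `message()`.
#'
#' @param profiles A tabulated `profile_table` (see [tabulate_counts()]).
#' @param factors The factor list used to enumerate `profiles`.
#' @param which `"case"` or `"death"`: which relative risks to encode.
#' @return A `linear_system` with coefficient matrix `A`, right-hand side
#'   `b`, per-equation scale (1 for marginal rows), labels and profile
#'   weights.
#' @export
build_marginal_equations <- function(profiles, factors, which = c("case", "death")) {
  which <- match.arg(which)
  if (is.null(profiles$counts))
    stop("profiles have no counts; run tabulate_counts() first")
  n <- profiles$totals
  M <- profiles$profiles
  J <- n_profiles(profiles)
  rows <- list(); labels <- character(0); omitted <- character(0)
  for (f in seq_along(factors)) {
    rr <- factor_rr(factors[[f]], which)
    ref <- M[, f] == 0L
    N0 <- sum(n[ref])
    for (l in seq_len(length(rr) - 1L)) {
      grp <- M[, f] == l
      Nl <- sum(n[grp])
      lab <- paste0(factors[[f]]$name, ":", factors[[f]]$levels[l + 1L])
      if (Nl == 0 || N0 == 0) {
        omitted <- c(omitted, lab)
        next
      }
      row <- numeric(J)
      row[grp] <- n[grp] / Nl
      row[ref] <- row[ref] - rr[l + 1L] * n[ref] / N0
      rows[[length(rows) + 1L]] <- row
      labels <- c(labels, lab)
    }
  }
  if (length(omitted))
    message("omitted ", length(omitted), " empty marginal equation(s): ",
            paste(omitted, collapse = ", "))
  if (!length(rows)) stop("system empty: all marginal equations were omitted")
  A <- do.call(rbind, rows)
  structure(list(A = A, b = numeric(length(rows)), scale = rep(1, length(rows)),
                 labels = labels, n = n, J = J, anchored = FALSE,
                 anchor_risk = NA_real_, omitted = omitted),
            class = "linear_system")
}

#' Add the anchor equation fixing the overall outcome scale
#'
#' Appends the equation `sum_j n_j p_j = overall_risk * sum_j n_j` (expected
#' number of outcomes in the whole population). In the residual objective
#' this row is scaled by the total weight so its residual is in probability
#' units. The final normalized gradients are invariant to the anchor value
#' as long as no probability is pushed against the upper bound 1.
#'
#' @param system A `linear_system`.
#' @param overall_risk Overall outcome probability in (0, 1).
#' @return The anchored `linear_system`.
#' @export
add_anchor <- function(system, overall_risk) {
  stopifnot(inherits(system, "linear_system"))
  if (system$anchored) stop("anchor already present")
  if (!is.numeric(overall_risk) || length(overall_risk) != 1L ||
      overall_risk <= 0 || overall_risk >= 1)
    stop("overall_risk must lie strictly between 0 and 1")
  N <- sum(system$n)
  system$A <- rbind(system$A, system$n)
  system$b <- c(system$b, overall_risk * N)
  system$scale <- c(system$scale, N)
  system$labels <- c(system$labels, "anchor")
  system$anchored <- TRUE
  system$anchor_risk <- overall_risk
  rownames(system$A) <- NULL
  system
}

#' @export
print.linear_system <- function(x, ...) {
  cat("linear system: ", nrow(x$A), " equation(s), ", x$J, " profile unknowns",
      if (x$anchored) paste0(" (anchored at overall risk ", x$anchor_risk, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Sum-of-squares residual of a probability vector
#'
#' Returns the unweighted sum over equations of the squared scaled residual
#' `((A p - b) / scale)^2`: marginal rows are already dimensionless
#' group-mean differences, and the anchor row is divided by the total weight
#' so its residual is in probability units. This is the error functional the
#' constrained sampler minimizes.
#'
#' @param system A `linear_system`.
#' @param p Numeric vector, one probability per profile.
#' @return Nonnegative scalar.
#' @export
residual_objective <- function(system, p) {
  stopifnot(inherits(system, "linear_system"))
  if (length(p) != system$J)
    stop("p has length ", length(p), " but the system has ", system$J,
         " profiles")
  r <- (as.vector(system$A %*% p) - system$b) / system$scale
  sum(r * r)
}

# equation matrix/rhs with all rows brought to the dimensionless scale,
# optionally replacing the anchored overall risk by `anchor_override`
scaled_system <- function(system, anchor_override = NULL) {
  A <- system$A / system$scale
  b <- system$b / system$scale
  if (!is.null(anchor_override)) {
    stopifnot(system$anchored)
    b[length(b)] <- anchor_override
  }
  list(A = A, b = b)
}

#' Marginal relative risks implied by a probability vector
#'
#' Recomputes, from a per-profile probability vector and the tabulated
#' weights, the ratio of group-mean risk at each non-reference factor level
#' versus the factor's reference level. On any zero-residual solution these
#' equal the configured relative risks exactly.
#'
#' @param profiles A tabulated `profile_table`.
#' @param factors Factor list used for the enumeration.
#' @param p Per-profile probability vector.
#' @return Named numeric vector `factor:level` of implied relative risks.
#' @export
implied_relative_risks <- function(profiles, factors, p) {
  n <- profiles$totals
  M <- profiles$profiles
  out <- numeric(0)
  for (f in seq_along(factors)) {
    L <- length(factors[[f]]$levels)
    ref <- M[, f] == 0L
    m0 <- sum(n[ref] * p[ref]) / sum(n[ref])
    for (l in seq_len(L - 1L)) {
      grp <- M[, f] == l
      ml <- sum(n[grp] * p[grp]) / sum(n[grp])
      out[paste0(factors[[f]]$name, ":", factors[[f]]$levels[l + 1L])] <- ml / m0
    }
  }
  out
}
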