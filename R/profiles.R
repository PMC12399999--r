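# Risk-profile enumeration, per-quintile tabulation and the dominance order.

#' Enumerate multidimensional risk profiles
#'
#' A risk profile is one severity level per factor. The full Cartesian
#' product of level indices is enumerated in lexicographic order (first
#' factor most significant), e.g. two 3-level factors give the nine
#' profiles (0,0), (0,1), ..., (2,2).
#'
#' @param factors List of 1 to 4 [risk_factor()] objects.
#' @return A `profile_table`: profile matrix (rows = profiles, columns =
#'   factors), level counts, and empty count slots to be filled by
#'   [tabulate_counts()].
#' @export
enumerate_profiles <- function(factors) {
  if (length(factors) < 1L)
    stop("at least one risk factor is required to enumerate profiles")
  if (length(factors) > 4L)
    stop("at most 4 risk factors are supported")
  fnames <- vapply(factors, `[[`, "", "name")
  n_levels <- vapply(factors, function(f) length(f$levels), integer(1))
  # expand.grid varies the first column fastest; feed factors reversed so
  # the first factor ends up most significant, then restore column order
  g <- do.call(expand.grid, rev(lapply(n_levels, function(L) 0:(L - 1L))))
  profiles <- as.matrix(g[, rev(seq_along(factors)), drop = FALSE])
  dimnames(profiles) <- list(NULL, fnames)
  storage.mode(profiles) <- "integer"
  structure(list(profiles = profiles, factor_names = fnames,
                 n_levels = n_levels, counts = NULL, totals = NULL),
            class = "profile_table")
}

n_profiles <- function(pt) nrow(pt$profiles)

#' @export
print.profile_table <- function(x, ...) {
  cat("profile table: ", n_profiles(x), " profiles over ",
      length(x$factor_names), " factor(s) (",
      paste(x$n_levels, collapse = "x"), " levels)\n", sep = "")
  if (!is.null(x$counts))
    cat("  tabulated weight: ", format(sum(x$counts)), " across 5 quintiles\n",
        sep = "")
  invisible(x)
}

# profile row index (1-based) of each child's level vector, mixed radix with
# the first factor most significant
profile_index <- function(levels_matrix, n_levels) {
  radix <- rev(cumprod(rev(c(n_levels[-1L], 1L))))
  as.integer(levels_matrix %*% radix) + 1L
}

#' Tabulate weighted child counts per profile and quintile
#'
#' Each child contributes its survey weight to exactly one (profile,
#' quintile) cell. Profiles with no children are retained with zero weight.
#'
#' @param children A [child_table()] complete for the profile factors.
#' @param profiles A `profile_table` from [enumerate_profiles()].
#' @return The `profile_table` with `counts` (profiles x 5 matrix) and
#'   `totals` filled in.
#' @export
tabulate_counts <- function(children, profiles) {
  fnames <- profiles$factor_names
  miss <- setdiff(fnames, names(children))
  if (length(miss))
    stop("child table lacks factor column(s): ", paste(miss, collapse = ", "))
  lev <- as.matrix(children[, fnames, drop = FALSE])
  for (k in seq_along(fnames))
    if (any(lev[, k] < 0L | lev[, k] >= profiles$n_levels[k]))
      stop("child level outside the range of factor '", fnames[k], "'")
  j <- profile_index(lev, profiles$n_levels)
  J <- n_profiles(profiles)
  counts <- matrix(0, J, 5L, dimnames = list(NULL, paste0("Q", 1:5)))
  agg <- tapply(children$weight,
                list(factor(j, levels = seq_len(J)),
                     factor(children$quintile, levels = 1:5)),
                sum)
  agg[is.na(agg)] <- 0
  counts[] <- agg
  profiles$counts <- counts
  profiles$totals <- rowSums(counts)
  profiles
}

#' Build the dominance partial order on risk profiles
#'
#' Profile a dominates profile b when a's severity level is greater than or
#' equal to b's in every factor; the monotonicity constraint then requires
#' a's outcome probability to be at least b's. The order is returned as its
#' cover relations (transitive reduction): on the full product lattice these
#' are exactly the pairs differing by one severity step in a single factor.
#'
#' @param profiles A `profile_table`.
#' @return A `dominance_order`: integer matrix `edges` with columns `a`
#'   (dominant) and `b` (dominated), ordered by dominant profile index.
#' @export
dominance_order <- function(profiles) {
  M <- profiles$profiles
  nl <- profiles$n_levels
  J <- nrow(M)
  ea <- integer(0); eb <- integer(0)
  for (jj in seq_len(J)) {
    for (f in seq_along(nl)) {
      if (M[jj, f] > 0L) {
        low <- M[jj, , drop = TRUE]
        low[f] <- low[f] - 1L
        ea <- c(ea, jj)
        eb <- c(eb, profile_index(matrix(low, 1L), nl))
      }
    }
  }
  ord <- order(ea, eb)
  edges <- cbind(a = ea[ord], b = eb[ord])
  structure(list(edges = edges, n_profiles = J), class = "dominance_order")
}

#' @export
print.dominance_order <- function(x, ...) {
  cat("dominance order: ", nrow(x$edges), " cover edge(s) on ",
      x$n_profiles, " profiles\n", sep = "")
  invisible(x)
}

#' Write a dominance order as an edge-list text file (debugging aid)
#' @param order A `dominance_order`.
#' @param path Output path; each line `a b` means profile a dominates b.
#' @export
write_dominance_edges <- function(order, path) {
  write.table(order$edges, path, row.names = FALSE, col.names = TRUE,
              quote = FALSE)
  invisible(path)
}
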