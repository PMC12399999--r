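test_that("profile enumeration is the full Cartesian product in lexicographic order", {
  pt <- enumerate_profiles(list(f_stunting(), f_wasting()))
  expect_equal(nrow(pt$profiles), 9L)
  expect_equal(pt$profiles[1, ], c(stunting = 0L, wasting = 0L))
  expect_equal(pt$profiles[2, ], c(stunting = 0L, wasting = 1L))
  expect_equal(pt$profiles[9, ], c(stunting = 2L, wasting = 2L))

  expect_equal(nrow(enumerate_profiles(list(f_sanitation()))$profiles), 2L)

  four <- list(f_stunting(), f_wasting(),
               risk_factor("underweight", c("no", "mild", "severe"),
                           rr_case = c(1, 1.5, 2)),
               risk_factor("vad", c("no", "mild", "severe"),
                           rr_case = c(1, 1.2, 1.5)))
  pt4 <- enumerate_profiles(four)
  # independent brute-force enumeration of the product set
  oracle <- nrow(unique(expand.grid(0:2, 0:2, 0:2, 0:2)))
  expect_equal(nrow(pt4$profiles), oracle)
  expect_error(enumerate_profiles(list()), "at least one")
})

test_that("tabulation puts each child's weight in exactly one cell", {
  f <- list(f_stunting(), f_wasting())
  pt <- enumerate_profiles(f)
  ch <- make_children(rep(1L, 5),
                      list(stunting = rep(1L, 5), wasting = rep(2L, 5)), f)
  tc <- tabulate_counts(ch, pt)
  expect_equal(sum(tc$counts), 5)
  expect_equal(unname(tc$counts[6, 1]), 5)  # profile (1,2) is row 6 lexicographically
  expect_equal(sum(tc$counts[-6, ]), 0)

  ch2 <- make_children(c(1L, 2L, 2L, 5L),
                       list(stunting = c(0L, 1L, 1L, 2L),
                            wasting = c(0L, 0L, 0L, 2L)), f, weight = 0.5)
  tc2 <- tabulate_counts(ch2, pt)
  expect_equal(sum(tc2$counts), 2.0)
})

test_that("tabulated cells match an independent group-by tally", {
  f <- list(f_stunting(), f_wasting())
  set.seed(11)
  n <- 200
  df <- data.frame(quintile = sample(1:5, n, TRUE),
                   stunting = sample(0:2, n, TRUE),
                   wasting = sample(0:2, n, TRUE),
                   weight = runif(n, 0.2, 2))
  ch <- child_table(df, f)
  tc <- tabulate_counts(ch, enumerate_profiles(f))
  for (s in 0:2) for (w in 0:2) for (q in 1:5) {
    oracle <- sum(df$weight[df$stunting == s & df$wasting == w &
                              df$quintile == q])
    expect_equal(unname(tc$counts[3 * s + w + 1, q]), oracle)
  }
  expect_equal(sum(tc$counts), sum(df$weight))
  # row order of the input does not matter
  perm <- sample(n)
  tc2 <- tabulate_counts(child_table(df[perm, ], f), enumerate_profiles(f))
  expect_equal(tc2$counts, tc$counts)
})

test_that("levels outside the factor range are rejected at tabulation", {
  f <- list(f_sanitation())
  pt <- enumerate_profiles(f)
  ch <- make_children(1L, list(unsafe_sanitation = 1L), f)
  ch$unsafe_sanitation <- 5L
  expect_error(tabulate_counts(ch, pt), "outside the range")
})

test_that("dominance covers are correct on chains and small lattices", {
  chain <- enumerate_profiles(list(f_stunting()))
  ord <- dominance_order(chain)
  expect_equal(nrow(ord$edges), 2L)
  expect_equal(unname(ord$edges[, "a"]), c(2L, 3L))
  expect_equal(unname(ord$edges[, "b"]), c(1L, 2L))

  sq <- enumerate_profiles(list(f_sanitation(),
                                risk_factor("underweight", c("no", "yes"),
                                            rr_case = c(1, 2))))
  ords <- dominance_order(sq)
  # profiles: 1=(0,0) 2=(0,1) 3=(1,0) 4=(1,1); (0,1) and (1,0) incomparable
  expect_setequal(paste(ords$edges[, 1], ords$edges[, 2]),
                  c("2 1", "3 1", "4 2", "4 3"))
})

test_that("the transitive closure of the covers equals componentwise dominance", {
  pt <- enumerate_profiles(list(f_stunting(), f_wasting()))
  ord <- dominance_order(pt)
  got <- closure_pairs(ord)
  want <- brute_dominance_pairs(pt$profiles)
  key <- function(m) sort(paste(m[, 1], m[, 2]))
  expect_identical(key(got), key(want))
  # comparable ordered pairs counted over all 81 ordered pairs
  expect_equal(nrow(want), nrow(got))
})

test_that("count conservation holds for arbitrary generated child tables", {
  f <- list(f_stunting(), f_sanitation())
  pt <- enumerate_profiles(f)
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(20:200, 1)
    df <- data.frame(quintile = sample(1:5, n, TRUE),
                     stunting = sample(0:2, n, TRUE),
                     unsafe_sanitation = sample(0:1, n, TRUE),
                     weight = rexp(n) + 0.01)
    tc <- tabulate_counts(child_table(df, f), pt)
    expect_equal(sum(tc$counts), sum(df$weight))
    expect_true(all(tc$counts >= 0))
  }
})
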