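test_that("d reduces to the pooled-variance t statistic when s0 = 0", {
  withr::with_seed(10, {
    for (i in 1:200) {
      a <- rnorm(sample(2:6, 1)); b <- rnorm(sample(2:6, 1))
      expect_lt(abs(sam_d(a, b, 0)$d - t_stat_oracle(a, b)), 1e-10)
    }
  })
})

test_that("d is zero for identical groups and antisymmetric under swap", {
  expect_equal(sam_d(c(1, 2, 3), c(1, 2, 3), 0.5)$d, 0)
  a <- c(1.2, 3.4, 2.2); b <- c(0.1, 0.4, 0.9)
  expect_equal(sam_d(a, b, 0.3)$d, -sam_d(b, a, 0.3)$d)
  expect_error(sam_d(1, c(1, 2)), "at least 2")
})

test_that("s0 selection matches an independent percentile computation", {
  expect_equal(choose_s0(rep(0.7, 10)), 0.7)
  withr::with_seed(11, s <- rexp(101))
  expect_equal(choose_s0(s, value = 0), min(s))
  expect_equal(choose_s0(s, value = 100), max(s))
  # with n = 101, the 50th percentile (type 7) is the 51st order statistic
  expect_equal(choose_s0(s, value = 50), sort(s)[51])
  expect_equal(choose_s0(s, mode = "fixed", value = 0.123), 0.123)
  expect_error(choose_s0(numeric(0)), "empty")
})

test_that("a 3v3 design enumerates exactly 20 assignments, identity first", {
  en <- introcold:::enumerate_assignments(6, 3, 1000, seed = 1)
  expect_true(en$exhaustive)
  expect_equal(ncol(en$assignments), 20)
  expect_equal(en$assignments[, 1], 1:3)
  expect_equal(nrow(unique(t(en$assignments))), 20)
  expect_error(introcold:::enumerate_assignments(3, 3, 10, 1), "fewer than 2")
})

test_that("exhaustive per-gene p agrees with brute-force enumeration", {
  withr::with_seed(12, X <- matrix(rnorm(30 * 6), 30, 6,
                                   dimnames = list(sprintf("g%02d", 1:30), NULL)))
  res <- sam_permutation(X, rep(c(TRUE, FALSE), each = 3),
                         sam_params(null_mode = "per_gene"))
  s0 <- attr(res, "s0")
  expect_equal(attr(res, "n_assignments"), 20)
  expect_true(all(abs(res$p_value * 20 - round(res$p_value * 20)) < 1e-12))

  # oracle: direct enumeration over all 20 subsets
  subsets <- combn(6, 3)
  d_of <- function(x, ia) {
    a <- x[ia]; b <- x[-ia]
    se <- sqrt((1 / 3 + 1 / 3) * (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 4)
    (mean(a) - mean(b)) / (se + s0)
  }
  for (g in 1:30) {
    dstar <- apply(subsets, 2, function(ia) d_of(X[g, ], ia))
    d_obs <- d_of(X[g, ], 1:3)
    expect_equal(res$p_value[g], mean(abs(dstar) >= abs(d_obs)))
  }
})

test_that("pooled-null p agrees with brute-force pooling across genes", {
  withr::with_seed(13, X <- matrix(rnorm(25 * 6), 25, 6,
                                   dimnames = list(sprintf("g%02d", 1:25), NULL)))
  res <- sam_permutation(X, rep(c(TRUE, FALSE), each = 3), sam_params())
  s0 <- attr(res, "s0")
  subsets <- combn(6, 3)
  d_of <- function(x, ia) {
    a <- x[ia]; b <- x[-ia]
    se <- sqrt((2 / 3) * (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 4)
    (mean(a) - mean(b)) / (se + s0)
  }
  all_d <- abs(vapply(seq_len(ncol(subsets)), function(j) {
    vapply(1:25, function(g) d_of(X[g, ], subsets[, j]), numeric(1))
  }, numeric(25)))
  for (g in 1:25) {
    expect_equal(res$p_value[g], mean(all_d >= abs(all_d[g, 1])))
  }
})

test_that("p is invariant under group relabelling while d changes sign", {
  withr::with_seed(14, X <- matrix(rnorm(40 * 6), 40, 6,
                                   dimnames = list(sprintf("g%02d", 1:40), NULL)))
  lab <- rep(c(TRUE, FALSE), each = 3)
  a <- sam_permutation(X, lab, sam_params())
  b <- sam_permutation(X[, c(4:6, 1:3)], lab, sam_params())
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$d, -b$d)
})

test_that("a gene with effectively infinite separation hits the p floor", {
  # one extreme gene among flat-noise genes: only the identity assignment and
  # its mirror attain |d|, so the per-gene p floor is 2/20
  withr::with_seed(15, X <- matrix(rnorm(50 * 6, sd = 0.1), 50, 6))
  X[1, ] <- c(100, 101, 102, 0, 1, 2)
  rownames(X) <- sprintf("g%02d", 1:50)
  pg <- sam_permutation(X, rep(c(TRUE, FALSE), each = 3),
                        sam_params(null_mode = "per_gene"))
  expect_equal(pg$p_value[1], 2 / 20)
  pooled <- sam_permutation(X, rep(c(TRUE, FALSE), each = 3), sam_params())
  expect_equal(pooled$p_value[1], 2 / (50 * 20))
})

test_that("sampled mode is reproducible under a fixed seed", {
  withr::with_seed(16, X <- matrix(rnorm(20 * 10), 20, 10,
                                   dimnames = list(sprintf("g%02d", 1:20), NULL)))
  lab <- rep(c(TRUE, FALSE), each = 5)
  p <- sam_params(n_permutations = 100, seed = 99) # choose(10,5) = 252 > 100
  a <- sam_permutation(X, lab, p)
  expect_false(attr(a, "exhaustive"))
  expect_identical(a, sam_permutation(X, lab, p))
})

test_that("q-values are within [0,1] and monotone in |d|", {
  st <- small_study()
  d <- tibble::as_tibble(st$degs)
  one <- d[d$contrast == d$contrast[1], ]
  expect_true(all(one$q_value >= 0 & one$q_value <= 1))
  ord <- order(abs(one$d_statistic), decreasing = TRUE)
  expect_true(!is.unsorted(one$q_value[ord]))
})

test_that("significance is the conjunction of the p cutoff and the 5-fold gate", {
  st <- small_study()
  d <- tibble::as_tibble(st$degs)
  expect_true(all(d$p_value[d$significant] < 0.05))
  expect_true(all(d$fold_change[d$significant] > 5 |
                    d$fold_change[d$significant] < 1 / 5))
  # genes passing only one gate are not called
  expect_true(any(d$p_value < 0.05 & !d$significant))
  only_fc <- d$fold_change > 5 & d$p_value >= 0.05
  expect_true(all(!d$significant[only_fc]))
})

test_that("unknown contrasts and malformed groups are rejected", {
  st <- small_study()
  expect_error(cold_contrast("bogus", 2), "unknown genotype")
  expect_error(call_degs(st$norm, st$sim$design, cold_contrast("recurrent", 3)),
               "not resolvable")
})
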