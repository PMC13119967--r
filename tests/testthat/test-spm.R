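test_that("the paired t curve follows the textbook formula", {
  a <- matrix(rnorm(5 * 101), 5)
  expect_equal(paired_t_curve(a, a), rep(0, 101))

  d <- matrix(c(1, 2, 3), 3, 4)       # d = {1,2,3} at every node
  z <- matrix(0, 3, 4)
  expect_equal(paired_t_curve(d, z), rep(2 / (1 / sqrt(3)), 4))

  b <- matrix(rnorm(5 * 101), 5)
  expect_equal(paired_t_curve(a, b), -paired_t_curve(b, a))

  expect_error(paired_t_curve(a[1, , drop = FALSE], b[1, , drop = FALSE]),
               "at least 2")
  expect_error(paired_t_curve(a, b[, 1:50]), "identical dimensions")

  # zero-variance sentinels
  cst <- matrix(2, 3, 2)
  expect_identical(paired_t_curve(cst, matrix(0, 3, 2)), rep(Inf, 2))
  expect_identical(paired_t_curve(-cst, matrix(0, 3, 2)), rep(-Inf, 2))
})

test_that("a saturated side effect attains the exhaustive minimum p", {
  set.seed(1)
  for (n in c(7, 6)) {
    D <- matrix(5, n, 101) + matrix(rnorm(n * 101, 0, 1e-4), n)
    res <- spm_paired_permutation(D)
    expect_identical(res$n_permutations, as.integer(2^n))
    expect_equal(min(res$clusters$p), 1 / 2^n)
  }
  # n = 4: minimum attainable p is 1/16 > 0.05, nothing can pass
  D4 <- matrix(5, 4, 101) + matrix(rnorm(4 * 101, 0, 1e-4), 4)
  r4 <- spm_paired_permutation(D4)
  expect_identical(nrow(r4$clusters), 0L)
})

test_that("every reported p is a multiple of 1/2^n and at least 1/2^n", {
  set.seed(33)
  for (rep in 1:5) {
    n <- sample(5:8, 1)
    D <- matrix(rnorm(n * 101), n) + 1.2
    res <- spm_paired_permutation(D)
    if (nrow(res$clusters)) {
      expect_true(all(res$clusters$p * 2^n == round(res$clusters$p * 2^n)))
      expect_true(all(res$clusters$p >= 1 / 2^n))
      expect_true(all(res$clusters$p <= 1))
    }
  }
})

test_that("inference is invariant to subject order and equivariant in sign", {
  set.seed(9)
  D <- matrix(rnorm(6 * 101), 6) + 1.5
  res <- spm_paired_permutation(D)
  perm <- spm_paired_permutation(D[sample(6), ])
  expect_equal(perm$t, res$t)
  expect_equal(perm$crit, res$crit)
  expect_equal(perm$clusters$p, res$clusters$p)

  neg <- spm_paired_permutation(-D)
  expect_equal(neg$t, -res$t)
  expect_equal(neg$crit, res$crit)
  expect_equal(neg$clusters[c("node_start", "node_end", "extent", "p")],
               res$clusters[c("node_start", "node_end", "extent", "p")])
  expect_equal(neg$clusters$direction, -res$clusters$direction)
})

test_that("clusters are maximal supra-threshold runs sorted by onset", {
  set.seed(40)
  D <- matrix(rnorm(7 * 101, 0, 0.3), 7)
  D[, 20:30] <- D[, 20:30] + 3    # two separated effects
  D[, 60:80] <- D[, 60:80] - 3
  res <- spm_paired_permutation(D)
  cl <- res$clusters
  expect_gt(nrow(cl), 0)
  expect_true(all(diff(cl$node_start) > 0))
  expect_equal(cl$extent, cl$node_end - cl$node_start + 1)
  for (i in seq_len(nrow(cl))) {
    nodes <- (cl$node_start[i]:cl$node_end[i]) + 1L
    expect_true(all(abs(res$t[nodes]) > res$crit))
    if (cl$node_start[i] > 0)
      expect_lte(abs(res$t[cl$node_start[i]]), res$crit)
    if (cl$node_end[i] < 100)
      expect_lte(abs(res$t[cl$node_end[i] + 2]), res$crit)
  }
})

test_that("exhaustive inference matches the brute-force enumerator exactly", {
  set.seed(77)
  n_checked <- 0
  for (k in 1:22) {
    n <- sample(4:8, 1)
    q <- sample(c(24, 51, 101), 1)
    shift <- sample(c(0, 0.8, 1.6), 1)
    D <- matrix(rnorm(n * q), n) + shift
    res <- spm_paired_permutation(D)
    ora <- oracle_spm(D)
    expect_equal(res$crit, ora$crit)
    if (is.null(ora$clusters)) {
      expect_identical(nrow(res$clusters), 0L)
    } else {
      expect_equal(res$clusters$node_start, ora$clusters$node_start)
      expect_equal(res$clusters$node_end, ora$clusters$node_end)
      expect_equal(res$clusters$p, ora$clusters$p)
      n_checked <- n_checked + nrow(ora$clusters)
    }
  }
  expect_gt(n_checked, 5)   # the sweep exercised real clusters
})

test_that("the exhaustive cap errors with Monte-Carlo guidance", {
  D <- matrix(rnorm(25 * 10), 25)
  expect_error(spm_paired_permutation(D, cap = 2^20), "Monte-Carlo")
  mc <- spm_paired_permutation(D + 2, exhaustive = FALSE, n_iter = 500,
                               seed = 1)
  expect_identical(mc$n_permutations, 500L)
  if (nrow(mc$clusters))
    expect_true(all(mc$clusters$p >= 1 / 500 & mc$clusters$p <= 1))
})

test_that("Benjamini-Hochberg step-up decisions follow the rule", {
  dec <- bh_fdr(c(a = 0.01, b = 0.02, c = 0.04, d = 0.20))
  expect_identical(dec$reject, c(TRUE, TRUE, FALSE, FALSE))

  none <- bh_fdr(rep(1, 5))
  expect_false(any(none$reject))

  single <- bh_fdr(c(x = 0.04))
  expect_true(single$reject)

  empty <- bh_fdr(numeric(0))
  expect_identical(nrow(empty), 0L)

  # rejection set is a down-set of the sorted p-values
  set.seed(3)
  p <- runif(20)^2
  dec2 <- bh_fdr(p)
  o <- order(dec2$p)
  r <- dec2$reject[o]
  expect_true(all(diff(as.integer(r)) <= 0))
})
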