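test_that("quantile discretization gives balanced bins and handles ties", {
  fd <- tiny_flat(cbind(as.double(1:100)), rep(0:1, 50))
  dd <- discretize(fd, 20)
  expect_equal(unname(table(dd$bins[, 1])), rep(5L, 20), ignore_attr = TRUE)
  expect_equal(dd$effective_bins[1], 20L)
  expect_equal(sort(unique(as.vector(dd$bins))), 0:19)

  # constant feature: one effective bin, zero MI downstream
  fd2 <- tiny_flat(cbind(rep(1.5, 40), as.double(1:40)), rep(0:1, 20))
  dd2 <- discretize(fd2, 20)
  expect_equal(dd2$effective_bins[1], 1L)
  expect_true(all(dd2$bins[, 1] == 0L))
  expect_equal(estimate_importance(dd2)[1], 0)
  expect_equal(estimate_redundancy(dd2, rbind(c(1, 2)))$value, 0)

  # heavy ties: repeated values collapse duplicate edges
  fd3 <- tiny_flat(cbind(rep(c(0, 0, 0, 1), 25)), rep(0:1, 50))
  dd3 <- discretize(fd3, 20)
  expect_lte(length(unique(dd3$bins[, 1])), 2L)
  expect_lt(dd3$effective_bins[1], 20L)
  expect_error(discretize(fd, 1), "n_bins")
})

test_that("probability tables are normalized with consistent marginals", {
  set.seed(21)
  for (rep in 1:3) {
    fd <- tiny_flat(matrix(runif(60 * 3), 60, 3),
                    sample(0:2, 60, replace = TRUE))
    dd <- discretize(fd, 5)
    for (j in 1:3) {
      tab <- joint_table_fy(dd, j)
      expect_equal(sum(tab), 1, tolerance = 1e-12)
      expect_true(all(tab >= 0))
      # marginal over labels equals bin marginal from the pairwise table
      tff <- joint_table_ff(dd, j, (j %% 3) + 1)
      expect_equal(sum(tff), 1, tolerance = 1e-12)
      expect_equal(rowSums(tab), rowSums(tff), tolerance = 1e-12)
    }
  }
})

test_that("importance matches hand-enumerated and analytic values", {
  # perfect dependence, balanced binary: MI = H(y) = ln 2
  fd <- tiny_flat(cbind(rep(c(0, 1), each = 20)), rep(c(0L, 1L), each = 20))
  dd <- discretize(fd, 2)
  expect_equal(estimate_importance(dd)[1], log(2), tolerance = 1e-12)

  # 8-sample worked table: counts (b,y) = (0,0):3 (0,1):1 (1,0):1 (1,1):3
  # MI = 2*(3/8)log(1.5) + 2*(1/8)log(0.5)  [cell enumeration]
  fd8 <- tiny_flat(cbind(c(0, 0, 0, 0, 1, 1, 1, 1)),
                   c(0L, 0L, 0L, 1L, 0L, 1L, 1L, 1L))
  dd8 <- discretize(fd8, 2)
  expected <- 2 * (3 / 8) * log(1.5) + 2 * (1 / 8) * log(0.5)
  expect_equal(estimate_importance(dd8)[1], expected, tolerance = 1e-12)
  expect_equal(expected, 0.13081203, tolerance = 1e-7)

  # permutation-decoupled feature: MI near 0 and below the dependent case
  set.seed(5)
  y <- rep(0:1, 30)
  x_dep <- y + rnorm(60, 0, 0.1)
  x_ind <- sample(x_dep)
  dd2 <- discretize(tiny_flat(cbind(x_dep, x_ind), y), 4)
  imp <- estimate_importance(dd2)
  expect_lt(imp[2], imp[1])
  expect_lt(imp[2], 0.1)
  expect_true(all(imp >= 0))
})

test_that("redundancy matches analytic values and is symmetric", {
  x <- rep(c(1, 2, 3, 4), each = 10)
  dd <- discretize(tiny_flat(cbind(x, x, sample(x)), rep(0:1, 20)), 4)
  red <- estimate_redundancy(dd, rbind(c(1, 2)))
  expect_equal(red$value, log(4), tolerance = 1e-12)  # R(x,x) = H(x)
  # column order cannot matter: swap the roles of the two features
  dd_sw <- discretize(tiny_flat(cbind(dd$bins[, 2], dd$bins[, 1]),
                                rep(0:1, 20)), 4)
  expect_equal(estimate_redundancy(dd_sw, rbind(c(1, 2)))$value, red$value)

  expect_error(estimate_redundancy(dd, rbind(c(2, 1))), "i < j")
  expect_error(estimate_redundancy(dd, rbind(c(1, 9))), "out of range")

  # omitted pairs argument computes all i < j
  all_red <- estimate_redundancy(dd)
  expect_equal(nrow(all_red), 3)
})

test_that("MI agrees with the brute-force contingency oracle", {
  set.seed(77)
  for (rep in 1:5) {
    n_feat <- sample(2:5, 1)
    N <- sample(c(30, 60, 100), 1)
    feats <- matrix(sample.int(4, N * n_feat, replace = TRUE) +
                      runif(N * n_feat, 0, 0.01), N, n_feat)
    y <- sample(0:2, N, replace = TRUE)
    dd <- discretize(tiny_flat(feats, y), 4)
    imp <- estimate_importance(dd)
    for (j in seq_len(n_feat)) {
      expect_equal(imp[j], mi_bruteforce(dd$bins[, j], y), tolerance = 1e-10)
    }
    red <- estimate_redundancy(dd)
    for (r in seq_len(nrow(red))) {
      expect_equal(red$value[r],
                   mi_bruteforce(dd$bins[, red$i[r]], dd$bins[, red$j[r]]),
                   tolerance = 1e-10)
    }
  }
})

test_that("merging bins never increases MI with the label", {
  set.seed(31)
  for (rep in 1:10) {
    N <- 80
    bins <- sample.int(4, N, replace = TRUE) - 1L
    y <- sample(0:1, N, replace = TRUE,
                prob = c(0.5, 0.5) + runif(1, -0.2, 0.2) * c(1, -1))
    full <- mi_bruteforce(bins, y)
    merged <- mi_bruteforce(pmin(bins, 2L), y)  # merge bins 2 and 3
    expect_lte(merged, full + 1e-12)
  }
})

test_that("MI matrices round-trip through the NPZ cache", {
  set.seed(9)
  fd <- tiny_flat(matrix(runif(50 * 4), 50, 4), rep(0:1, 25))
  mi <- mi_matrices(discretize(fd, 5))
  path <- tempfile(fileext = ".npz")
  write_mi_matrices(mi, path)
  back <- read_mi_matrices(path)
  expect_equal(back$importance, mi$importance)
  expect_equal(back$redundancy$value, mi$redundancy$value)
  expect_equal(redundancy_matrix(back), redundancy_matrix(mi))
  expect_true(isSymmetric(redundancy_matrix(mi)))
})
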