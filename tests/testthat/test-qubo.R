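mi_fixture <- function() {
  structure(list(importance = c(0.5, 0.3),
                 redundancy = data.frame(i = 1L, j = 2L, value = 0.1),
                 n = 2L),
            class = "mi_matrices")
}

test_that("build_mi_qubo negates importance and copies redundancy", {
  q <- build_mi_qubo(mi_fixture())
  expect_equal(q$linear, c(-0.5, -0.3))
  expect_equal(q$quad$value, 0.1)
  expect_equal(q$offset, 0)
  expect_equal(qubo_energy(q, c(1, 1)), -0.7)
  expect_equal(qubo_energy(q, c(1, 0)), -0.5)
  expect_equal(qubo_energy(q, c(0, 0)), 0)

  zero <- build_mi_qubo(structure(list(importance = numeric(3),
                                       redundancy = data.frame(),
                                       n = 3L), class = "mi_matrices"))
  for (x in list(c(0, 0, 0), c(1, 0, 1), c(1, 1, 1))) {
    expect_equal(qubo_energy(zero, x), 0)
  }
})

test_that("qubo_problem folds symmetric input and validates masks", {
  q <- qubo_problem(3, c(1, 2, 3),
                    data.frame(i = c(2L, 1L, 1L), j = c(1L, 2L, 3L),
                               value = c(0.5, 0.25, 0)))
  expect_equal(nrow(q$quad), 1)  # (1,2) summed, zero entry dropped
  expect_equal(q$quad$value, 0.75)
  expect_error(qubo_energy(q, c(1, 0)), "length")
  expect_error(qubo_energy(q, c(1, 2, 0)), "0 or 1")
  expect_error(qubo_problem(2, c(1, 2),
                            data.frame(i = 1L, j = 1L, value = 1)),
               "diagonal")
})

test_that("energy matches the dense-matrix oracle on random instances", {
  set.seed(14)
  for (rep in 1:10) {
    q <- random_qubo(8, density = 0.6)
    q$offset <- rnorm(1)
    x <- sample(0:1, 8, replace = TRUE)
    expect_equal(qubo_energy(q, x), qubo_energy_dense(q, x),
                 tolerance = 1e-12)
  }
})

test_that("quadratic constraint equals alpha*(h-k)^2 and connects the graph", {
  # n=3, k=1, alpha=1 on a zero base: energies by Hamming weight 1,0,1,4
  q <- add_quadratic_constraint(qubo_problem(3), k = 1, alpha = 1)
  masks <- all_masks(3)
  for (r in seq_len(nrow(masks))) {
    h <- sum(masks[r, ])
    expect_equal(qubo_energy(q, masks[r, ]), (h - 1)^2)
  }
  expect_equal(nrow(q$quad), 3)  # fully connected

  # brute force at n = 7: penalty zero iff h == k, alpha-scaled square else
  set.seed(3)
  base <- random_qubo(7, 0.4)
  for (k in c(2, 4)) {
    alpha <- 1.7
    qc <- add_quadratic_constraint(base, k, alpha)
    expect_equal(nrow(qc$quad), choose(7, 2))
    masks <- all_masks(7)
    for (r in seq_len(nrow(masks))) {
      x <- masks[r, ]
      pen <- qubo_energy(qc, x) - qubo_energy(base, x)
      expect_equal(pen, alpha * (sum(x) - k)^2, tolerance = 1e-12)
    }
  }
})

test_that("linear penalty shifts only the diagonal", {
  set.seed(4)
  q <- random_qubo(8, 0.5)
  expect_equal(add_linear_penalty(q, 0), q)
  qp <- add_linear_penalty(q, 3.25)
  expect_equal(qp$linear, q$linear + 3.25)
  expect_equal(qp$quad, q$quad)
  expect_equal(qp$offset, q$offset)

  # alpha_l larger than any |linear|: empty set is the exhaustive optimum
  qbig <- add_linear_penalty(q, max(abs(q$linear)) + 10)
  expect_equal(solve_exhaustive(qbig)$mask, rep(0L, 8))
  expect_equal(brute_minimum(qbig)$energy, 0)
})

test_that("Ising mapping preserves energies exactly in both domains", {
  # closed-form single-variable case, mu in {-1/2, +1/2}
  q1 <- qubo_problem(1, linear = 2.5)
  is1 <- to_ising(q1, "half")
  expect_equal(is1$h, 2.5)
  expect_equal(is1$offset, 1.25)
  expect_equal(ising_energy(is1, -0.5), 0)
  expect_equal(ising_energy(is1, 0.5), 2.5)

  # zero QUBO maps to the zero Ising problem
  is0 <- to_ising(qubo_problem(3), "pm1")
  expect_equal(is0$h, numeric(3))
  expect_equal(is0$offset, 0)

  # exhaustive correspondence on random instances, both domains
  set.seed(8)
  for (rep in 1:5) {
    q <- random_qubo(6, 0.7)
    q$offset <- rnorm(1)
    masks <- all_masks(6)
    for (dom in c("pm1", "half")) {
      is <- to_ising(q, dom)
      for (r in seq_len(nrow(masks))) {
        x <- masks[r, ]
        expect_equal(ising_energy(is, mask_to_spins(x, dom)),
                     qubo_energy(q, x), tolerance = 1e-9)
      }
    }
  }
  expect_error(to_ising(qubo_problem(2), "pm2"), "arg")
})

test_that("assembly order never changes the coefficient map", {
  mi <- mi_fixture()
  a <- add_linear_penalty(add_quadratic_constraint(build_mi_qubo(mi), 1, 2), 0.3)
  b <- add_quadratic_constraint(add_linear_penalty(build_mi_qubo(mi), 0.3), 1, 2)
  expect_equal(a$linear, b$linear)
  expect_equal(a$quad, b$quad)
  expect_equal(a$offset, b$offset)
})

test_that("QUBO serialization round-trips through JSON and COO text", {
  set.seed(6)
  q <- random_qubo(5, 0.5)
  q$offset <- 0.125
  pj <- tempfile(fileext = ".json")
  write_qubo_json(q, pj)
  qj <- read_qubo_json(pj)
  expect_equal(qj$linear, q$linear)
  expect_equal(qj$quad, q$quad)
  expect_equal(qj$offset, q$offset)

  pc <- tempfile(fileext = ".txt")
  write_qubo_coo(q, pc)
  qc <- read_qubo_coo(pc)
  expect_equal(qc$linear, q$linear)
  expect_equal(qc$quad, q$quad)
  expect_equal(qc$offset, q$offset)
})
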