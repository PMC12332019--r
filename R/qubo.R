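# QUBO assembly, energies, cardinality penalties, and the Ising mapping.
#
# A QUBO minimizes f(x) = sum_i Q_ii x_i + sum_{i<j} Q_ij x_i x_j + offset
# over binary x. Coefficients are stored upper-triangular (i < j);
# symmetric or lower-triangular input is folded by summation.

#' Construct a QUBO problem
#'
#' @param n number of binary variables.
#' @param linear length-n vector of diagonal terms Q_ii.
#' @param quad optional data.frame with columns `i`, `j`, `value`
#'   (1-based indices; entries with i > j are folded onto (j, i),
#'   duplicates are summed, exact zeros dropped). i == j is not allowed
#'   (diagonal lives in `linear`).
#' @param offset constant added to every energy.
#' @return A `qubo_problem`.
#' @export
qubo_problem <- function(n, linear = numeric(n), quad = NULL, offset = 0) {
  n <- as.integer(n)
  if (length(linear) != n) stop_input("linear terms must have length n")
  if (is.null(quad) || nrow(quad) == 0) {
    quad <- data.frame(i = integer(0), j = integer(0), value = numeric(0))
  } else {
    i <- as.integer(quad$i); j <- as.integer(quad$j); v <- as.double(quad$value)
    if (any(i == j)) stop_input("diagonal entries belong in `linear`")
    if (any(i < 1 | i > n | j < 1 | j > n)) stop_input("index out of range")
    lo <- pmin(i, j); hi <- pmax(i, j)
    key <- (lo - 1) * n + hi
    agg <- rowsum(v, key)
    key <- as.numeric(rownames(agg))
    keep <- agg[, 1] != 0
    lo <- as.integer((key[keep] - 1) %/% n + 1)
    hi <- as.integer((key[keep] - 1) %% n + 1)
    v <- as.double(agg[keep, 1])
    ord <- order(lo, hi)
    quad <- data.frame(i = lo[ord], j = hi[ord], value = v[ord])
  }
  structure(list(n = n, linear = as.double(linear), quad = quad,
                 offset = as.double(offset)),
            class = "qubo_problem")
}

#' @export
print.qubo_problem <- function(x, ...) {
  cat(sprintf("<qubo_problem: n=%d, %d couplings, offset=%g>\n",
              x$n, nrow(x$quad), x$offset))
  invisible(x)
}

#' QUBO energy of a binary mask
#'
#' @param q a `qubo_problem`.
#' @param x binary vector of length `q$n`.
#' @return Scalar energy including the offset.
#' @export
qubo_energy <- function(q, x) {
  x <- assert_binary_mask(x, q$n)
  e <- q$offset + sum(q$linear * x)
  if (nrow(q$quad)) {
    e <- e + sum(q$quad$value * x[q$quad$i] * x[q$quad$j])
  }
  e
}

#' Assemble the MI feature-selection QUBO
#'
#' Q = -I + R before any cardinality constraint: diagonal entries are the
#' negated importances (informative features lower the energy when
#' selected), off-diagonal entries are the pairwise redundancies
#' (co-selecting mutually informative features raises it).
#'
#' @param mi an `mi_matrices` object.
#' @return A `qubo_problem` with zero offset.
#' @export
build_mi_qubo <- function(mi) {
  stopifnot(inherits(mi, "mi_matrices"))
  if (length(mi$importance) != mi$n) stop_input("importance length mismatch")
  if (nrow(mi$redundancy) &&
      max(mi$redundancy$i, mi$redundancy$j) > mi$n) {
    stop_input("redundancy index exceeds n")
  }
  qubo_problem(mi$n, linear = -mi$importance, quad = mi$redundancy)
}

#' Add the quadratic k-of-n cardinality penalty
#'
#' Adds the algebraic expansion of `alpha * (sum_i x_i - k)^2`:
#' `alpha * (1 - 2k)` to every diagonal term, `2 * alpha` to every
#' unordered pair, and `alpha * k^2` to the offset. The penalty is zero
#' iff exactly k variables are set, and makes the problem graph fully
#' connected.
#'
#' @param q a `qubo_problem`.
#' @param k target subset size, 0 < k < n.
#' @param alpha penalty weight > 0.
#' @return A new `qubo_problem`.
#' @export
add_quadratic_constraint <- function(q, k, alpha) {
  stopifnot(inherits(q, "qubo_problem"))
  if (!(k > 0 && k < q$n)) stop_input("need 0 < k < n")
  if (!(alpha > 0)) stop_input("alpha must be positive")
  ap <- all_pairs(q$n)
  quad <- rbind(q$quad,
                data.frame(i = ap[, 1], j = ap[, 2],
                           value = rep(2 * alpha, nrow(ap))))
  qubo_problem(q$n, q$linear + alpha * (1 - 2 * k), quad,
               q$offset + alpha * k^2)
}

#' Add the linear Ising cardinality penalty
#'
#' Adds a uniform offset `alpha_l` to every diagonal term, leaving the
#' couplings (and therefore the problem-graph sparsity) untouched. Tuning
#' `alpha_l` moves the Hamming weight of the unconstrained optimum; see
#' [tune_linear_penalty()].
#'
#' @param q a `qubo_problem`.
#' @param alpha_l diagonal offset (any finite sign).
#' @return A new `qubo_problem`.
#' @export
add_linear_penalty <- function(q, alpha_l) {
  stopifnot(inherits(q, "qubo_problem"), is.finite(alpha_l))
  qubo_problem(q$n, q$linear + alpha_l, q$quad, q$offset)
}

#' Convert a QUBO to Ising form
#'
#' Exact affine change of variables: `"pm1"` (annealer-API convention)
#' uses spins s in {-1, +1} with x = (s + 1) / 2; `"half"` uses
#' mu in {-1/2, +1/2} with x = mu + 1/2. Energies correspond exactly on
#' every configuration.
#'
#' @param q a `qubo_problem`.
#' @param spin_domain `"pm1"` (default) or `"half"`.
#' @return An `ising_problem` with fields `h`, `J` (COO data.frame),
#'   `offset`, `spin_domain`.
#' @export
to_ising <- function(q, spin_domain = c("pm1", "half")) {
  stopifnot(inherits(q, "qubo_problem"))
  spin_domain <- match.arg(spin_domain)
  qi <- q$quad$i; qj <- q$quad$j; qv <- q$quad$value
  if (spin_domain == "pm1") {
    # x = (s + 1)/2:  Q_ij x_i x_j = Q/4 (s_i s_j + s_i + s_j + 1)
    Jv <- qv / 4
    add <- qv / 4
    h <- q$linear / 2 + tapply_add(add, qi, q$n) + tapply_add(add, qj, q$n)
    off <- q$offset + sum(q$linear) / 2 + sum(add)
  } else {
    # x = mu + 1/2:  Q_ij x_i x_j = Q (mu_i mu_j + mu_i/2 + mu_j/2 + 1/4)
    Jv <- qv
    add <- qv / 2
    h <- q$linear + tapply_add(add, qi, q$n) + tapply_add(add, qj, q$n)
    off <- q$offset + sum(q$linear) / 2 + sum(qv) / 4
  }
  structure(list(n = q$n, h = h,
                 J = data.frame(i = qi, j = qj, value = Jv),
                 offset = off, spin_domain = spin_domain),
            class = "ising_problem")
}

tapply_add <- function(v, idx, n) {
  out <- numeric(n)
  agg <- rowsum(v, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Ising energy of a spin configuration
#'
#' @param is an `ising_problem`.
#' @param s spin vector in the problem's domain ({-1,1} or {-1/2,1/2}).
#' @return Scalar energy including the offset.
#' @export
ising_energy <- function(is, s) {
  stopifnot(inherits(is, "ising_problem"))
  dom <- if (is$spin_domain == "pm1") c(-1, 1) else c(-0.5, 0.5)
  if (length(s) != is$n || !all(s %in% dom)) {
    stop_input("spins must be length n with values in {",
               paste(dom, collapse = ", "), "}")
  }
  e <- is$offset + sum(is$h * s)
  if (nrow(is$J)) e <- e + sum(is$J$value * s[is$J$i] * s[is$J$j])
  e
}

#' Map a binary mask into the Ising spin domain
#' @param x binary vector.
#' @param spin_domain `"pm1"` or `"half"`.
#' @return Spin vector.
#' @export
mask_to_spins <- function(x, spin_domain = c("pm1", "half")) {
  spin_domain <- match.arg(spin_domain)
  if (spin_domain == "pm1") 2 * x - 1 else x - 0.5
}

# --- serialization ---------------------------------------------------------

#' Write a QUBO as JSON
#'
#' Layout: `{n, linear, quadratic: [[i, j, value], ...], offset, domain}`
#' with 0-based indices for interoperability with annealer toolchains.
#'
#' @param q a `qubo_problem`.
#' @param path output path.
#' @export
write_qubo_json <- function(q, path) {
  obj <- list(n = q$n, linear = q$linear,
              quadratic = unname(Map(function(i, j, v) list(i - 1L, j - 1L, v),
                                     q$quad$i, q$quad$j, q$quad$value)),
              offset = q$offset, domain = "binary")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a QUBO written by [write_qubo_json()]
#' @param path JSON path.
#' @return A `qubo_problem`.
#' @export
read_qubo_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  quad <- NULL
  if (length(obj$quadratic)) {
    qm <- if (is.matrix(obj$quadratic)) obj$quadratic else
      matrix(unlist(obj$quadratic), ncol = 3, byrow = TRUE)
    quad <- data.frame(i = qm[, 1] + 1L, j = qm[, 2] + 1L, value = qm[, 3])
  }
  qubo_problem(obj$n, obj$linear, quad, obj$offset)
}

#' Write a QUBO in flat COO text form
#'
#' One `i j value` triple per line with 0-based indices; diagonal terms
#' appear as `i == j`. The offset is written as a `# offset` comment line.
#'
#' @param q a `qubo_problem`.
#' @param path output path.
#' @export
write_qubo_coo <- function(q, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n %d", q$n), con)
  writeLines(sprintf("# offset %.17g", q$offset), con)
  nz <- which(q$linear != 0)
  for (i in nz) {
    writeLines(sprintf("%d %d %.17g", i - 1L, i - 1L, q$linear[i]), con)
  }
  if (nrow(q$quad)) {
    writeLines(sprintf("%d %d %.17g", q$quad$i - 1L, q$quad$j - 1L,
                       q$quad$value), con)
  }
  invisible(path)
}

#' Read a QUBO written by [write_qubo_coo()]
#' @param path COO text path.
#' @return A `qubo_problem`.
#' @export
read_qubo_coo <- function(path) {
  lines <- readLines(path)
  n <- as.integer(sub("^# n ", "", lines[grepl("^# n ", lines)][1]))
  off_line <- lines[grepl("^# offset ", lines)]
  offset <- if (length(off_line)) as.numeric(sub("^# offset ", "",
                                                 off_line[1])) else 0
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  linear <- numeric(n)
  quad <- NULL
  if (length(body)) {
    m <- do.call(rbind, lapply(strsplit(body, "\\s+"), as.numeric))
    i <- as.integer(m[, 1]) + 1L; j <- as.integer(m[, 2]) + 1L
    diag_rows <- i == j
    if (any(diag_rows)) {
      agg <- rowsum(m[diag_rows, 3], i[diag_rows])
      linear[as.integer(rownames(agg))] <- agg[, 1]
    }
    if (any(!diag_rows)) {
      quad <- data.frame(i = i[!diag_rows], j = j[!diag_rows],
                         value = m[!diag_rows, 3])
    }
  }
  qubo_problem(n, linear, quad, offset)
}
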