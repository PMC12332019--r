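# Classical QUBO solvers: exhaustive enumeration (ground-truth oracle for
# small n) and multi-restart simulated annealing (stand-in for the
# annealer / tabu-decomposition black box), plus the linear-penalty tuner.

#' Simulated-annealing parameters
#'
#' Each read is an independent restart of single-spin-flip Metropolis with
#' a geometric temperature schedule over `sweeps` full sweeps. When
#' `t_hot`/`t_cold` are `NULL` they are auto-scaled per instance from the
#' maximum single-flip energy magnitude (`t_hot` = max_i(|l_i| +
#' sum_j |Q_ij|), `t_cold` = 1e-4 * t_hot), so the schedule tracks the
#' coefficient scale of the problem.
#'
#' @param n_reads independent restarts (default 1000, the read count used
#'   on annealing hardware).
#' @param sweeps Metropolis sweeps per read (default 100).
#' @param t_hot,t_cold temperature schedule endpoints (geometric decay);
#'   `NULL` for per-instance auto-scaling.
#' @param seed integer seed for the solver's own RNG stream.
#' @return An `anneal_params` list.
#' @export
anneal_params <- function(n_reads = 1000, sweeps = 100, t_hot = NULL,
                          t_cold = NULL, seed = 1) {
  if (n_reads < 1) stop_input("n_reads must be >= 1")
  if (sweeps < 0) stop_input("sweeps must be >= 0")
  if (!is.null(t_hot) && !is.null(t_cold) && !(t_hot > t_cold && t_cold > 0)) {
    stop_input("need t_hot > t_cold > 0")
  }
  structure(list(n_reads = as.integer(n_reads), sweeps = as.integer(sweeps),
                 t_hot = t_hot, t_cold = t_cold, seed = as.integer(seed)),
            class = "anneal_params")
}

solve_result <- function(mask, energy, solver, n_reads, seed,
                         read_energies = energy, repaired = FALSE) {
  structure(list(mask = as.integer(mask),
                 hamming_weight = sum(mask),
                 energy = energy, solver = solver,
                 n_reads = as.integer(n_reads), seed = seed,
                 read_energies = read_energies, repaired = repaired),
            class = "solve_result")
}

#' @export
print.solve_result <- function(x, ...) {
  cat(sprintf("<solve_result [%s]: energy=%.6g, weight=%d/%d%s>\n",
              x$solver, x$energy, x$hamming_weight, length(x$mask),
              if (x$repaired) ", repaired" else ""))
  invisible(x)
}

#' Solve a QUBO exactly by enumeration
#'
#' Gray-code enumeration of all 2^n masks; ties are broken by the
#' lexicographically smallest mask. Intended as the ground-truth oracle
#' for small instances.
#'
#' @param q a `qubo_problem`.
#' @param cap refuse instances with n above this (default 22).
#' @return A `solve_result`.
#' @export
solve_exhaustive <- function(q, cap = 22) {
  stopifnot(inherits(q, "qubo_problem"))
  if (q$n > cap) {
    stop_input("n = ", q$n, " exceeds the exhaustive cap (", cap,
               "); use solve_sa()")
  }
  res <- cpp_solve_exhaustive(q$n, q$linear, q$quad$i - 1L, q$quad$j - 1L,
                              q$quad$value, q$offset)
  solve_result(res$mask, res$energy, "exhaustive", 1L, NA_integer_)
}

sa_temps <- function(q, p) {
  if (!is.null(p$t_hot) && !is.null(p$t_cold)) {
    return(c(p$t_hot, p$t_cold))
  }
  flip <- abs(q$linear)
  if (nrow(q$quad)) {
    av <- abs(q$quad$value)
    flip <- flip + tapply_add(av, q$quad$i, q$n) + tapply_add(av, q$quad$j, q$n)
  }
  hot <- max(flip, 1e-8)
  c(hot, 1e-4 * hot)
}

#' Solve a QUBO by multi-restart simulated annealing
#'
#' Runs `n_reads` independent single-spin-flip Metropolis restarts with
#' geometric cooling and returns the lowest-energy state visited (the
#' read-selection rule used with annealing hardware). Fully reproducible
#' given `p$seed`; the solver uses its own RNG stream and never touches
#' R's global RNG.
#'
#' @param q a `qubo_problem`.
#' @param p an [anneal_params()] object.
#' @return A `solve_result` with per-read best energies.
#' @export
solve_sa <- function(q, p = anneal_params()) {
  stopifnot(inherits(q, "qubo_problem"), inherits(p, "anneal_params"))
  tt <- sa_temps(q, p)
  res <- cpp_solve_sa(q$n, q$linear, q$quad$i - 1L, q$quad$j - 1L,
                      q$quad$value, q$offset, p$n_reads, p$sweeps,
                      tt[1], tt[2], p$seed)
  solve_result(res$mask, res$energy, "sa", p$n_reads, p$seed,
               read_energies = res$read_energies)
}

solver_fun <- function(solver, p, cap = 22) {
  switch(solver,
         exhaustive = function(q) solve_exhaustive(q, cap = cap),
         sa = function(q) solve_sa(q, p),
         stop_input("unknown solver '", solver, "'"))
}

# marginal energy change of flipping variable v of mask x under q
marginal_delta <- function(q, x, v) {
  d <- q$linear[v]
  if (nrow(q$quad)) {
    hit <- (q$quad$i == v & x[q$quad$j] == 1) |
      (q$quad$j == v & x[q$quad$i] == 1)
    d <- d + sum(q$quad$value[hit])
  }
  if (x[v] == 1) -d else d
}

greedy_repair <- function(q, mask, k) {
  mask <- as.integer(mask)
  while (sum(mask) < k) {
    cand <- which(mask == 0)
    deltas <- vapply(cand, function(v) marginal_delta(q, mask, v), 0)
    mask[cand[which.min(deltas)]] <- 1L
  }
  while (sum(mask) > k) {
    cand <- which(mask == 1)
    deltas <- vapply(cand, function(v) marginal_delta(q, mask, v), 0)
    # removing v changes energy by delta; drop the one freeing most energy
    mask[cand[which.min(deltas)]] <- 0L
  }
  mask
}

#' Tune the linear Ising penalty to an exact subset size
#'
#' Deterministic search over the diagonal offset `alpha_l`: starting from
#' 0 with step `max(|linear|)/10`, the weight is bracketed by geometric
#' expansion (x2) and then bisected until the solver's best mask has
#' Hamming weight exactly `k`. If no tested `alpha_l` attains exact k
#' within `max_iter` solves (possible with plateaus or degenerate
#' landscapes), the closest mask is greedily repaired to weight k under
#' the base objective and the result is flagged `repaired`.
#'
#' @param q the pre-penalty QUBO (-I + R, possibly sparsified).
#' @param k target subset size.
#' @param solver `"sa"` or `"exhaustive"`.
#' @param p [anneal_params()] for the SA solver (its seed fixes the whole
#'   tuning trajectory).
#' @param max_iter maximum number of solver calls (default 40).
#' @param cap exhaustive-solver size cap.
#' @return List with `penalty` (the final `alpha_l`), `result` (a
#'   `solve_result` of weight k), and `trajectory` (data.frame of tested
#'   `alpha_l` and weights).
#' @export
tune_linear_penalty <- function(q, k, solver = c("sa", "exhaustive"),
                                p = anneal_params(), max_iter = 40,
                                cap = 22) {
  stopifnot(inherits(q, "qubo_problem"))
  if (!(k > 0 && k < q$n)) stop_input("need 0 < k < n")
  solver <- match.arg(solver)
  fn <- solver_fun(solver, p, cap)
  traj <- data.frame(alpha_l = numeric(0), weight = integer(0))
  best_res <- NULL; best_alpha <- NA_real_
  solve_at <- function(a) {
    r <- fn(add_linear_penalty(q, a))
    traj[nrow(traj) + 1L, ] <<- list(a, r$hamming_weight)
    if (is.null(best_res) ||
        abs(r$hamming_weight - k) < abs(best_res$hamming_weight - k)) {
      best_res <<- r; best_alpha <<- a
    }
    r
  }
  finish <- function(res, alpha, repaired) {
    if (repaired) {
      mask <- greedy_repair(q, res$mask, k)
      res <- solve_result(mask, qubo_energy(add_linear_penalty(q, alpha), mask),
                          res$solver, res$n_reads, res$seed, repaired = TRUE)
    }
    list(penalty = alpha, result = res, trajectory = traj)
  }
  r0 <- solve_at(0)
  if (r0$hamming_weight == k) return(finish(r0, 0, FALSE))
  dir <- if (r0$hamming_weight > k) 1 else -1  # raise alpha to shrink weight
  step <- max(abs(q$linear), 1e-3) / 10
  a_lo <- 0; w_lo <- r0$hamming_weight
  a <- dir * step
  crossed <- FALSE
  while (nrow(traj) < max_iter) {
    r <- solve_at(a)
    if (r$hamming_weight == k) return(finish(r, a, FALSE))
    if (sign(r$hamming_weight - k) != sign(w_lo - k)) {
      crossed <- TRUE
      break
    }
    a_lo <- a; w_lo <- r$hamming_weight
    a <- a * 2
    if (!is.finite(a)) break
  }
  if (crossed) {
    a_hi <- a
    while (nrow(traj) < max_iter && abs(a_hi - a_lo) >
           1e-12 * max(1, abs(a_hi))) {
      mid <- (a_lo + a_hi) / 2
      r <- solve_at(mid)
      if (r$hamming_weight == k) return(finish(r, mid, FALSE))
      if (sign(r$hamming_weight - k) == sign(w_lo - k)) {
        a_lo <- mid
      } else {
        a_hi <- mid
      }
    }
  }
  if (is.null(best_res)) {
    stop("linear-penalty tuning failed; trajectory:\n",
         paste(utils::capture.output(print(traj)), collapse = "\n"))
  }
  finish(best_res, best_alpha, TRUE)
}

#' Map a selection mask back to pixel coordinates
#'
#' @param result a `solve_result` or a binary mask vector.
#' @param shape original image shape `(H, W)`.
#' @param sm optional `subsample_map` when the mask lives on the reduced
#'   grid; `NULL` for the identity (full-grid) mapping.
#' @return m x 2 matrix of 1-based (row, col) original-image coordinates,
#'   sorted row-major.
#' @export
select_features <- function(result, shape, sm = NULL) {
  mask <- if (inherits(result, "solve_result")) result$mask else
    as.integer(result)
  if (!is.null(sm)) {
    if (length(mask) != length(sm$kept_indices)) {
      stop_input("mask length does not match subsample map")
    }
    flat <- sm$kept_indices[mask == 1]
  } else {
    if (length(mask) != shape[1] * shape[2]) {
      stop_input("mask length does not match grid size")
    }
    flat <- which(mask == 1)
  }
  flat <- sort(flat)
  W <- shape[2]
  cbind(row = (flat - 1L) %/% W + 1L, col = (flat - 1L) %% W + 1L)
}

#' Expand a reduced-grid mask to the full pixel grid
#' @param mask binary mask on the reduced grid.
#' @param sm the `subsample_map`.
#' @param n_full number of pixels in the full grid.
#' @return Binary mask of length `n_full`.
#' @export
expand_mask <- function(mask, sm, n_full) {
  full <- integer(n_full)
  full[sm$kept_indices[mask == 1]] <- 1L
  full
}
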