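# End-to-end experiment orchestration: data -> MI -> QUBO -> (sparsify) ->
# solve -> decode -> report.

#' Experiment configuration
#'
#' Aggregates the pipeline's tunable constants. Defaults follow the
#' reference protocol: 20 quantile bins, k = 25 selected pixels, 2 x 2
#' subsampling blocks, 2000 retained couplings, SA solver with 1000
#' reads, decoder trained 5 times with derived seeds.
#'
#' @param n_bins quantile bins for MI estimation.
#' @param k target subset size.
#' @param constraint `"linear"` (sparsity-preserving, tuned) or
#'   `"quadratic"` (fully connected penalty).
#' @param alpha quadratic-penalty weight; `NULL` uses
#'   `max(|Q_ij|) * n` (a documented package choice; the reference
#'   protocol does not state one).
#' @param block subsampling block `(b_r, b_c)`.
#' @param m_couplings couplings kept by thresholding.
#' @param solver `"sa"` or `"exhaustive"`.
#' @param anneal [anneal_params()] for the SA solver.
#' @param decoder_channels `(c1, c2)` hidden channels of the decoder.
#' @param epochs,batch_size,lr decoder training parameters.
#' @param repeats decoder train/eval repetitions R (default 5).
#' @param seed master seed; all stage seeds derive from it.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(n_bins = 20, k = 25,
                              constraint = c("linear", "quadratic"),
                              alpha = NULL, block = c(2, 2),
                              m_couplings = 2000,
                              solver = c("sa", "exhaustive"),
                              anneal = NULL,
                              decoder_channels = c(32, 16),
                              epochs = 20, batch_size = 128, lr = 0.001,
                              repeats = 5, seed = 1) {
  constraint <- match.arg(constraint)
  solver <- match.arg(solver)
  if (repeats < 1) stop_input("repeats must be >= 1")
  structure(list(n_bins = n_bins, k = k, constraint = constraint,
                 alpha = alpha, block = block, m_couplings = m_couplings,
                 solver = solver,
                 anneal = anneal %||% anneal_params(seed = derive_seed(seed, 21)),
                 decoder_channels = decoder_channels, epochs = epochs,
                 batch_size = batch_size, lr = lr,
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "experiment_config")
}

decoder_cfg_for <- function(cfg, k, side, seed) {
  decoder_config(k = k, side = side, c1 = cfg$decoder_channels[1],
                 c2 = cfg$decoder_channels[2], lr = cfg$lr,
                 epochs = cfg$epochs, batch_size = cfg$batch_size,
                 seed = seed)
}

# R decoder repeats for a fixed mask; returns mean/sd of test MSE
eval_mask_repeats <- function(mask, train_fd, test_fd, cfg) {
  side <- train_fd$shape[1]
  Xtr <- mask_inputs(train_fd, mask)
  Xte <- mask_inputs(test_fd, mask)
  mses <- vapply(seq_len(cfg$repeats), function(r) {
    dcfg <- decoder_cfg_for(cfg, sum(mask), side, derive_seed(cfg$seed, 100 + r))
    fit <- train_decoder(build_decoder(dcfg), Xtr, train_fd$features)
    evaluate_mse(fit$decoder, Xte, test_fd$features)
  }, 0)
  mses
}

report_row <- function(method, name, mses, k, cfg) {
  data.frame(method = method, dataset = name, k = k,
             repeats = length(mses), mean_mse = mean(mses),
             sd_mse = stats::sd(mses))
}

finalize_report <- function(rows, cfg, extra = list()) {
  rep <- do.call(rbind, rows)
  attr(rep, "meta") <- c(list(config_hash = content_hash(unclass(cfg)),
                              seed = cfg$seed,
                              package_version =
                                as.character(utils::packageVersion("qubofs"))),
                         extra)
  class(rep) <- c("eval_report", class(rep))
  rep
}

#' Write an evaluation report as CSV
#' @param report an `eval_report`.
#' @param path output CSV path.
#' @export
write_eval_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}

#' Run the full (dense) QUBO experiment
#'
#' Builds the complete n x n MI QUBO with the quadratic cardinality
#' penalty, solves it classically (exhaustive when n is within the cap,
#' otherwise SA), and evaluates the resulting mask with `repeats`
#' decoder trainings. Intended at full scale with a decomposition-style
#' solver; at desk scale use small images.
#'
#' @param train,test [image_dataset()]s.
#' @param cfg an [experiment_config()].
#' @return List with `report`, `mask` (full-grid), `coords`, `solve`,
#'   `qubo_stats`.
#' @export
run_full_qubo_experiment <- function(train, test, cfg = experiment_config()) {
  fd <- flatten(train)
  fd_test <- flatten(test)
  n <- ncol(fd$features)
  dd <- discretize(fd, cfg$n_bins)
  mi <- mi_matrices(dd)
  q <- build_mi_qubo(mi)
  alpha <- cfg$alpha %||%
    (max(abs(q$quad$value), 0) * q$n)
  if (cfg$constraint == "quadratic") {
    qc <- add_quadratic_constraint(q, cfg$k, alpha)
    res <- if (cfg$solver == "exhaustive" && n <= 22) {
      solve_exhaustive(qc)
    } else {
      solve_sa(qc, cfg$anneal)
    }
    if (res$hamming_weight != cfg$k) {
      res <- solve_result(greedy_repair(qc, res$mask, cfg$k),
                          NA_real_, res$solver, res$n_reads, res$seed,
                          repaired = TRUE)
      res$energy <- qubo_energy(qc, res$mask)
    }
  } else {
    tuned <- tune_linear_penalty(q, cfg$k, cfg$solver, cfg$anneal)
    res <- tuned$result
  }
  mask <- res$mask
  mses <- eval_mask_repeats(mask, fd, fd_test, cfg)
  list(report = finalize_report(list(report_row("qubo_full", train$name,
                                                mses, cfg$k, cfg)), cfg),
       mask = mask,
       coords = select_features(mask, fd$shape),
       solve = res,
       qubo_stats = list(n = q$n, couplings = nrow(q$quad), alpha = alpha))
}

#' Run the sparsified (hardware-shaped) experiment
#'
#' Subsamples the grid by per-block max importance, recomputes redundancy
#' on the kept columns only, thresholds to `m_couplings`, tunes the
#' linear Ising penalty to exact weight k, solves with SA (the classical
#' stand-in for the annealer), maps the mask back to original pixels and
#' evaluates it with `repeats` decoder trainings.
#'
#' @param train,test [image_dataset()]s.
#' @param cfg an [experiment_config()].
#' @return List with `report`, `mask` (full-grid), `coords`,
#'   `reduced_mask`, `subsample_map`, `solve`, `penalty`, `qubo_stats`.
#' @export
run_sparsified_experiment <- function(train, test,
                                      cfg = experiment_config()) {
  fd <- flatten(train)
  fd_test <- flatten(test)
  dd <- discretize(fd, cfg$n_bins)
  importance <- estimate_importance(dd)
  sm <- subsample_by_importance(importance, fd$shape, cfg$block)
  ddr <- restrict_discretized(dd, sm$kept_indices)
  mi <- structure(list(importance = importance[sm$kept_indices],
                       redundancy = estimate_redundancy(ddr),
                       n = length(sm$kept_indices)),
                  class = "mi_matrices")
  q <- build_mi_qubo(mi)
  qs <- threshold_couplings(q, cfg$m_couplings)
  tuned <- tune_linear_penalty(qs, cfg$k, cfg$solver, cfg$anneal)
  res <- tuned$result
  mask <- expand_mask(res$mask, sm, ncol(fd$features))
  mses <- eval_mask_repeats(mask, fd, fd_test, cfg)
  list(report = finalize_report(list(report_row("qubo_sparsified",
                                                train$name, mses, cfg$k,
                                                cfg)), cfg),
       mask = mask,
       coords = select_features(res$mask, fd$shape, sm),
       reduced_mask = res$mask,
       subsample_map = sm,
       solve = res,
       penalty = tuned$penalty,
       qubo_stats = list(n = qs$n, couplings = nrow(qs$quad),
                         penalty_trajectory = tuned$trajectory))
}

#' Benchmark several selection methods
#'
#' One report row per method, mean +/- sd of test MSE over `repeats`
#' decoder trainings. Mask methods reuse one selection per method
#' (random re-draws per repeat); `autoencoder` and `spca` are
#' transformed-feature comparators evaluated through the same decoder
#' machinery.
#'
#' @param train,test [image_dataset()]s.
#' @param cfg an [experiment_config()].
#' @param methods subset of `random`, `sampled`, `lasso`, `qubo_full`,
#'   `qubo_sparsified`, `autoencoder`, `spca`. Duplicates are dropped
#'   with a warning.
#' @return An `eval_report` data.frame.
#' @export
run_benchmark <- function(train, test, cfg = experiment_config(),
                          methods = c("random", "sampled", "lasso",
                                      "qubo_sparsified")) {
  known <- c("random", "sampled", "lasso", "qubo_full", "qubo_sparsified",
             "autoencoder", "spca")
  bad <- setdiff(methods, known)
  if (length(bad)) stop_input("unknown method tag(s): ",
                              paste(bad, collapse = ", "))
  if (anyDuplicated(methods)) {
    warning("duplicate method tags dropped")
    methods <- unique(methods)
  }
  fd <- flatten(train)
  fd_test <- flatten(test)
  side <- fd$shape[1]
  n <- ncol(fd$features)
  rows <- list()
  for (m in methods) {
    mses <- switch(m,
      random = vapply(seq_len(cfg$repeats), function(r) {
        mask <- select_random(n, cfg$k, derive_seed(cfg$seed, 200 + r))
        dcfg <- decoder_cfg_for(cfg, cfg$k, side, derive_seed(cfg$seed, 100 + r))
        fit <- train_decoder(build_decoder(dcfg), mask_inputs(fd, mask),
                             fd$features)
        evaluate_mse(fit$decoder, mask_inputs(fd_test, mask),
                     fd_test$features)
      }, 0),
      sampled = eval_mask_repeats(select_grid(fd$shape, cfg$k), fd, fd_test,
                                  cfg),
      lasso = eval_mask_repeats(select_by_coefficients(fd, cfg$k), fd,
                                fd_test, cfg),
      qubo_full = eval_mask_repeats(
        run_full_qubo_experiment(train, test, cfg)$mask, fd, fd_test, cfg),
      qubo_sparsified = eval_mask_repeats(
        run_sparsified_experiment(train, test, cfg)$mask, fd, fd_test, cfg),
      autoencoder = vapply(seq_len(cfg$repeats), function(r) {
        dcfg <- decoder_cfg_for(cfg, cfg$k, side, derive_seed(cfg$seed, 100 + r))
        dec <- add_linear_encoder(build_decoder(dcfg), n)
        fit <- train_decoder(dec, fd$features, fd$features)
        evaluate_mse(fit$decoder, fd_test$features, fd_test$features)
      }, 0),
      spca = {
        tr <- spca_features(fd$features, cfg$k)
        Ztr <- tr$transform(fd$features)
        Zte <- tr$transform(fd_test$features)
        vapply(seq_len(cfg$repeats), function(r) {
          dcfg <- decoder_cfg_for(cfg, cfg$k, side, derive_seed(cfg$seed, 100 + r))
          fit <- train_decoder(build_decoder(dcfg), Ztr, fd$features)
          evaluate_mse(fit$decoder, Zte, fd_test$features)
        }, 0)
      })
    rows[[m]] <- report_row(m, train$name, mses, cfg$k, cfg)
  }
  finalize_report(rows, cfg, extra = list(methods = methods))
}
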