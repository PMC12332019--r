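# Quantile discretization and mutual-information estimation.
#
# All MI values are in nats (natural log). The log base is a global scale
# on the QUBO and cannot change its argmin; natural log is used throughout
# and documented here once.

#' Discretize features by empirical quantiles
#'
#' Per feature, cut points are the (1/n_bins, ..., (n_bins-1)/n_bins)
#' empirical quantiles; duplicate cut points (ties in discrete-valued
#' data) are merged, and cut points at or below the feature minimum are
#' dropped (they would create empty bins). The bin index of a value is
#' the count of cut points strictly below it, so indices are 0-based. A
#' constant feature collapses to a single effective bin.
#'
#' @param fd a `flat_dataset` from [flatten()].
#' @param n_bins maximum number of bins per feature (default 20).
#' @return A `discretized_dataset` with `bins` (N x n integer matrix of
#'   0-based indices), `bin_edges` (per-feature numeric vectors),
#'   `effective_bins`, `labels`, `n_bins`, `n_classes`.
#' @export
discretize <- function(fd, n_bins = 20) {
  stopifnot(inherits(fd, "flat_dataset"))
  if (n_bins < 2) stop_input("n_bins must be >= 2")
  N <- nrow(fd$features)
  if (N < 2) stop_input("need at least 2 samples to discretize")
  n <- ncol(fd$features)
  bins <- matrix(0L, N, n)
  edges <- vector("list", n)
  probs <- seq_len(n_bins - 1) / n_bins
  for (j in seq_len(n)) {
    x <- fd$features[, j]
    e <- unique(stats::quantile(x, probs = probs, names = FALSE, type = 7))
    e <- e[e > min(x)]
    edges[[j]] <- e
    bins[, j] <- findInterval(x, e, left.open = TRUE)
  }
  structure(list(bins = bins, bin_edges = edges,
                 effective_bins = lengths(edges) + 1L,
                 labels = fd$labels, n_bins = as.integer(n_bins),
                 n_classes = fd$n_classes),
            class = "discretized_dataset")
}

# column subset of a discretized dataset (binning is per-feature, so this
# is identical to re-discretizing the restricted flat dataset)
restrict_discretized <- function(dd, cols) {
  structure(list(bins = dd$bins[, cols, drop = FALSE],
                 bin_edges = dd$bin_edges[cols],
                 effective_bins = dd$effective_bins[cols],
                 labels = dd$labels, n_bins = dd$n_bins,
                 n_classes = dd$n_classes),
            class = "discretized_dataset")
}

#' Empirical joint table of a feature with the label
#'
#' @param dd a `discretized_dataset`.
#' @param j feature index.
#' @return Matrix `p[b, y]` of empirical joint probabilities (sums to 1).
#' @export
joint_table_fy <- function(dd, j) {
  nb <- dd$effective_bins[j]
  ny <- dd$n_classes
  tab <- matrix(0, nb, ny)
  for (i in seq_len(nrow(dd$bins))) {
    tab[dd$bins[i, j] + 1L, dd$labels[i] + 1L] <-
      tab[dd$bins[i, j] + 1L, dd$labels[i] + 1L] + 1
  }
  tab / nrow(dd$bins)
}

#' Empirical joint table of two features
#'
#' @param dd a `discretized_dataset`.
#' @param i,j feature indices.
#' @return Matrix `p[b_i, b_j]` of empirical joint probabilities.
#' @export
joint_table_ff <- function(dd, i, j) {
  tab <- matrix(0, dd$effective_bins[i], dd$effective_bins[j])
  for (s in seq_len(nrow(dd$bins))) {
    tab[dd$bins[s, i] + 1L, dd$bins[s, j] + 1L] <-
      tab[dd$bins[s, i] + 1L, dd$bins[s, j] + 1L] + 1
  }
  tab / nrow(dd$bins)
}

#' Estimate feature importance I(x_i, y)
#'
#' Plug-in mutual information (nats) between each discretized feature and
#' the class label, from the empirical joint table; `0 * log(0/q) = 0`.
#' Values are clamped at zero (numerical round-off only; the estimator is
#' nonnegative).
#'
#' @param dd a `discretized_dataset`.
#' @return Numeric vector of length n, entries >= 0.
#' @export
estimate_importance <- function(dd) {
  stopifnot(inherits(dd, "discretized_dataset"))
  if (nrow(dd$bins) == 0 || ncol(dd$bins) == 0) stop_input("empty dataset")
  mi <- cpp_importance(dd$bins, dd$labels, max(dd$effective_bins),
                       dd$n_classes)
  if (any(mi < -1e-9)) stop("internal error: MI clamping exceeded 1e-9")
  pmax(mi, 0)
}

#' Estimate pairwise feature redundancy R(x_i, x_j)
#'
#' Pairwise plug-in mutual information from 2-D joint histograms of bin
#' indices, for the requested pairs only (all i < j pairs if `pairs` is
#' omitted). Computing only requested pairs keeps the sparsified pipeline
#' from paying for the full n(n-1)/2 pass.
#'
#' @param dd a `discretized_dataset`.
#' @param pairs optional m x 2 matrix of 1-based feature indices, i < j.
#' @return data.frame with columns `i`, `j`, `value` (nats, >= 0).
#' @export
estimate_redundancy <- function(dd, pairs = NULL) {
  stopifnot(inherits(dd, "discretized_dataset"))
  n <- ncol(dd$bins)
  if (is.null(pairs)) {
    pairs <- all_pairs(n)
  } else {
    pairs <- as.matrix(pairs)
    if (any(pairs < 1 | pairs > n)) stop_input("pair index out of range")
    if (any(pairs[, 1] >= pairs[, 2])) stop_input("pairs must satisfy i < j")
  }
  if (nrow(pairs) == 0) {
    return(data.frame(i = integer(0), j = integer(0), value = numeric(0)))
  }
  v <- cpp_pairwise_mi(dd$bins, pairs[, 1] - 1L, pairs[, 2] - 1L,
                       max(dd$effective_bins))
  data.frame(i = as.integer(pairs[, 1]), j = as.integer(pairs[, 2]),
             value = pmax(v, 0))
}

all_pairs <- function(n) {
  if (n < 2) return(matrix(integer(0), 0, 2))
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  cbind(i, j)
}

#' Bundle importance and redundancy estimates
#'
#' @param dd a `discretized_dataset`.
#' @param pairs optional pair restriction passed to [estimate_redundancy()].
#' @return An `mi_matrices` object with `importance` (length-n vector),
#'   `redundancy` (COO data.frame, i < j), and `n`.
#' @export
mi_matrices <- function(dd, pairs = NULL) {
  structure(list(importance = estimate_importance(dd),
                 redundancy = estimate_redundancy(dd, pairs),
                 n = ncol(dd$bins)),
            class = "mi_matrices")
}

#' Dense symmetric redundancy matrix (zero diagonal)
#' @param mi an `mi_matrices` object.
#' @return n x n symmetric matrix.
#' @export
redundancy_matrix <- function(mi) {
  R <- matrix(0, mi$n, mi$n)
  R[cbind(mi$redundancy$i, mi$redundancy$j)] <- mi$redundancy$value
  R[cbind(mi$redundancy$j, mi$redundancy$i)] <- mi$redundancy$value
  R
}

#' Cache MI matrices to an NPZ archive
#' @param mi an `mi_matrices` object.
#' @param path output `.npz` path.
#' @export
write_mi_matrices <- function(mi, path) {
  write_npz(path, list(importance = as.double(mi$importance),
                       red_i = as.integer(mi$redundancy$i),
                       red_j = as.integer(mi$redundancy$j),
                       red_v = as.double(mi$redundancy$value)))
}

#' Load MI matrices cached by [write_mi_matrices()]
#' @param path `.npz` path.
#' @return An `mi_matrices` object.
#' @export
read_mi_matrices <- function(path) {
  a <- read_npz(path)
  structure(list(importance = a$importance,
                 redundancy = data.frame(i = a$red_i, j = a$red_j,
                                         value = a$red_v),
                 n = length(a$importance)),
            class = "mi_matrices")
}
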