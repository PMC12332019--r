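# Comparison selectors: random, grid-sampled, and L1-coefficient (Lasso)
# selection. Transformed-feature comparators (autoencoder / sparse-PCA
# stand-in) live in decoder.R behind the benchmark harness.

#' Select k features uniformly at random
#'
#' @param n total number of features.
#' @param k subset size.
#' @param seed integer seed (local stream; global RNG untouched).
#' @return Binary mask of length n with exactly k ones.
#' @export
select_random <- function(n, k, seed = 1) {
  if (k > n) stop_input("k must not exceed n")
  mask <- integer(n)
  if (k > 0) {
    idx <- with_seed(seed, sample.int(n, k))
    mask[idx] <- 1L
  }
  mask
}

#' Select pixels on a regular grid
#'
#' Deterministic placement: with `g` the smallest integer such that
#' `g^2 >= round(sqrt(k))^2` covers k, lattice positions are
#' `round(linspace(0, H-1, g))` per axis (0-based), combined row-major;
#' excess points beyond k are dropped from the end in raster order.
#'
#' @param shape image shape `(H, W)`.
#' @param k subset size (<= H*W).
#' @return Binary mask of length H*W (row-major) with exactly k ones.
#' @export
select_grid <- function(shape, k) {
  H <- shape[1]; W <- shape[2]
  if (k > H * W) stop_input("k must not exceed the number of pixels")
  mask <- integer(H * W)
  if (k == 0) return(mask)
  g <- max(1L, as.integer(round(sqrt(k))))
  while (g^2 < k) g <- g + 1L
  rows <- unique(round(seq(0, H - 1, length.out = g))) + 1L
  cols <- unique(round(seq(0, W - 1, length.out = g))) + 1L
  pts <- cbind(rep(rows, each = length(cols)), rep(cols, times = length(rows)))
  if (nrow(pts) < k) stop_input("grid placement cannot reach k distinct pixels")
  pts <- pts[seq_len(k), , drop = FALSE]
  mask[(pts[, 1] - 1L) * W + pts[, 2]] <- 1L
  mask
}

#' Select features by L1-regularized coefficients
#'
#' Fits one-vs-rest L1 logistic regressions (standardized features) along
#' glmnet's regularization path, takes the largest penalty at which at
#' least k features are active in the union over classes, ranks features
#' by their maximum absolute coefficient across classes, and returns the
#' top k (path-position, then index, breaks ties).
#'
#' @param fd a `flat_dataset` with labels.
#' @param k subset size.
#' @param nlambda glmnet path length (default 100).
#' @return Binary mask of length n with exactly k ones.
#' @export
select_by_coefficients <- function(fd, k, nlambda = 100) {
  stopifnot(inherits(fd, "flat_dataset"))
  n <- ncol(fd$features)
  if (k > n) stop_input("k must not exceed n")
  classes <- sort(unique(fd$labels))
  if (length(classes) < 2) stop_input("labels contain a single class")
  # drop constant columns: glmnet standardization cannot use them
  keep <- which(apply(fd$features, 2, function(x) diff(range(x))) > 0)
  if (length(keep) < k) stop_input("fewer than k non-constant features")
  x <- fd$features[, keep, drop = FALSE]
  fits <- lapply(classes, function(cl) {
    glmnet::glmnet(x, as.integer(fd$labels == cl), family = "binomial",
                   alpha = 1, standardize = TRUE, nlambda = nlambda)
  })
  # per path position: union active set and max |coef| across classes
  nlam <- min(vapply(fits, function(f) length(f$lambda), 0L))
  score <- NULL
  for (s in seq_len(nlam)) {
    cf <- sapply(fits, function(f) abs(as.vector(f$beta[, s])))
    sc <- apply(cf, 1, max)
    if (sum(sc > 0) >= k) { score <- sc; break }
  }
  if (is.null(score)) {  # path never activates k features; use densest fit
    cf <- sapply(fits, function(f) abs(as.vector(f$beta[, nlam])))
    score <- apply(cf, 1, max)
  }
  top <- order(-score, seq_along(score))[seq_len(k)]
  mask <- integer(n)
  mask[keep[top]] <- 1L
  mask
}
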