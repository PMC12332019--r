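# Hardware-motivated reductions: block subsampling by importance and
# coupling thresholding.

#' Subsample the pixel grid by per-block importance
#'
#' Partitions the H x W grid into non-overlapping blocks (default 2 x 2)
#' and keeps, per block, the pixel with the highest importance. Ties go to
#' the smallest row-major flat index, so the map is deterministic.
#'
#' @param importance length-(H*W) importance vector in row-major pixel
#'   order (as produced by [estimate_importance()] on a flattened dataset).
#' @param shape integer `(H, W)`.
#' @param block integer `(b_r, b_c)` block size, default `c(2, 2)`.
#' @return A `subsample_map` with `block`, `kept_indices` (1-based
#'   row-major flat indices into the original grid, one per block in
#'   row-major block order) and `reduced_shape`.
#' @export
subsample_by_importance <- function(importance, shape, block = c(2, 2)) {
  H <- shape[1]; W <- shape[2]
  br <- block[1]; bc <- block[2]
  if (length(importance) != H * W) {
    stop_input("importance length must equal H * W")
  }
  if (H %% br != 0) stop_input("height ", H, " not divisible by block rows ", br)
  if (W %% bc != 0) stop_input("width ", W, " not divisible by block cols ", bc)
  nbr <- H %/% br; nbc <- W %/% bc
  kept <- integer(nbr * nbc)
  idx <- 1L
  for (brow in seq_len(nbr)) {
    for (bcol in seq_len(nbc)) {
      rows <- (brow - 1L) * br + seq_len(br)
      cols <- (bcol - 1L) * bc + seq_len(bc)
      # row-major enumeration inside the block: which.max -> smallest flat
      flat <- as.vector(t(outer((rows - 1L) * W, cols, `+`)))
      kept[idx] <- flat[which.max(importance[flat])]
      idx <- idx + 1L
    }
  }
  structure(list(block = c(br, bc), kept_indices = kept,
                 reduced_shape = c(nbr, nbc)),
            class = "subsample_map")
}

#' Restrict a flat dataset to the kept columns of a subsample map
#'
#' The restricted `coord_map` still holds original-image coordinates, so
#' downstream selections always report original pixels.
#'
#' @param fd a `flat_dataset`.
#' @param sm a `subsample_map` (or an integer vector of column indices).
#' @return A restricted `flat_dataset`.
#' @export
restrict_dataset <- function(fd, sm) {
  stopifnot(inherits(fd, "flat_dataset"))
  idx <- if (inherits(sm, "subsample_map")) sm$kept_indices else as.integer(sm)
  if (any(idx < 1 | idx > ncol(fd$features))) {
    stop_input("kept index out of range")
  }
  out <- fd
  out$features <- fd$features[, idx, drop = FALSE]
  out$coord_map <- fd$coord_map[idx, , drop = FALSE]
  out
}

#' Keep only the largest-magnitude couplings
#'
#' Retains the `m` quadratic entries of largest absolute value (all of
#' them if fewer exist); ties at the cutoff are broken by lexicographic
#' (i, j) order, smaller first. Diagonal terms and the offset are
#' untouched.
#'
#' @param q a `qubo_problem`.
#' @param m number of couplings to keep (>= 0).
#' @return A sparsified `qubo_problem`.
#' @export
threshold_couplings <- function(q, m) {
  stopifnot(inherits(q, "qubo_problem"))
  if (m < 0) stop_input("m must be non-negative")
  if (nrow(q$quad) <= m) return(q)
  ord <- order(-abs(q$quad$value), q$quad$i, q$quad$j)
  keep <- sort(ord[seq_len(m)])
  qubo_problem(q$n, q$linear, q$quad[keep, , drop = FALSE], q$offset)
}

#' Serialize a subsample map to JSON
#'
#' Indices are written 0-based for interoperability.
#'
#' @param sm a `subsample_map`.
#' @param path output path.
#' @export
write_subsample_map <- function(sm, path) {
  jsonlite::write_json(list(block = sm$block,
                            kept_indices = sm$kept_indices - 1L,
                            reduced_shape = sm$reduced_shape),
                       path, digits = NA)
  invisible(path)
}

#' Read a subsample map written by [write_subsample_map()]
#' @param path JSON path.
#' @return A `subsample_map`.
#' @export
read_subsample_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(block = obj$block,
                 kept_indices = as.integer(obj$kept_indices) + 1L,
                 reduced_shape = obj$reduced_shape),
            class = "subsample_map")
}
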