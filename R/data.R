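# Image datasets, flattening, and the planted-structure synthetic generator.

#' Construct an image dataset
#'
#' Container for a stack of square grayscale images with class labels.
#' Integer-valued intensities (e.g. uint8 0..255) are rescaled by 1/255;
#' after construction all intensities lie in \[0, 1\].
#'
#' @param images N x H x W array of pixel intensities.
#' @param labels length-N integer vector of 0-based class labels.
#' @param split split tag, `"train"` or `"test"`.
#' @param name dataset name used in reports.
#' @return An object of class `image_dataset` with fields `images`,
#'   `labels`, `split`, `name`, `n_classes`.
#' @export
image_dataset <- function(images, labels, split = "train", name = "dataset") {
  if (length(dim(images)) != 3L) {
    stop_input("images must be an N x H x W array")
  }
  d <- dim(images)
  if (d[2] != d[3]) {
    stop_input("images must be square (H == W), got ", d[2], " x ", d[3])
  }
  images <- images * 1.0
  if (max(images) > 1 + 1e-9) images <- images / 255
  if (min(images) < -1e-9 || max(images) > 1 + 1e-9) {
    stop_input("intensities outside [0, 1] after rescaling")
  }
  labels <- as.integer(round(as.vector(labels)))
  if (length(labels) != d[1]) {
    stop_input("labels length ", length(labels), " != N = ", d[1])
  }
  if (any(labels < 0)) stop_input("labels must be non-negative integers")
  if (!split %in% c("train", "test")) stop_input("split must be train or test")
  structure(list(images = images, labels = labels, split = split,
                 name = name, n_classes = max(labels) + 1L),
            class = "image_dataset")
}

#' @export
print.image_dataset <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<image_dataset '%s' [%s]: N=%d, %dx%d, %d classes>\n",
              x$name, x$split, d[1], d[2], d[3], x$n_classes))
  invisible(x)
}

#' Load an image dataset from a MedMNIST-style NPZ archive
#'
#' Expects members `{split}_images` (N x H x W) and `{split}_labels`
#' (N or N x 1); other key names can be supplied via `keys`.
#'
#' @param path path to the `.npz` archive.
#' @param split `"train"` or `"test"`.
#' @param keys optional `list(images =, labels =)` overriding member names.
#' @param name dataset name; defaults to the file name.
#' @return An [image_dataset()].
#' @export
load_npz_dataset <- function(path, split = "train", keys = NULL,
                             name = NULL) {
  arrays <- read_npz(path)
  ik <- keys$images %||% paste0(split, "_images")
  lk <- keys$labels %||% paste0(split, "_labels")
  for (k in c(ik, lk)) {
    if (is.null(arrays[[k]])) {
      stop_input("archive is missing required member '", k, "'")
    }
  }
  imgs <- arrays[[ik]]
  if (length(dim(imgs)) != 3L) stop_input("'", ik, "' is not N x H x W")
  if (dim(imgs)[2] != dim(imgs)[3]) {
    stop_input("non-square images in '", ik, "': ",
               dim(imgs)[2], " x ", dim(imgs)[3])
  }
  image_dataset(imgs, arrays[[lk]], split = split,
                name = name %||% sub("\\.npz$", "", basename(path)))
}

#' Export a dataset to the MedMNIST NPZ layout
#'
#' @param ds an [image_dataset()].
#' @param path output `.npz` path.
#' @param dtype `"u1"` stores uint8 (intensities x 255), `"f8"` doubles.
#' @export
write_npz_dataset <- function(ds, path, dtype = c("u1", "f8")) {
  dtype <- match.arg(dtype)
  imgs <- ds$images
  if (dtype == "u1") {
    imgs <- array(as.raw(round(imgs * 255)), dim = dim(imgs))
  }
  arrays <- list(imgs, as.integer(ds$labels))
  names(arrays) <- paste0(ds$split, c("_images", "_labels"))
  write_npz(path, arrays)
}

#' Flatten images to feature vectors
#'
#' Row-major flattening: feature j corresponds to pixel
#' `coord_map[j, ] = (row, col)` with `j = (row - 1) * W + col` (1-based).
#'
#' @param ds an [image_dataset()].
#' @return A `flat_dataset` with `features` (N x n matrix), `labels`,
#'   `coord_map` (n x 2), `shape`, and provenance fields.
#' @export
flatten <- function(ds) {
  stopifnot(inherits(ds, "image_dataset"))
  d <- dim(ds$images)
  N <- d[1]; H <- d[2]; W <- d[3]
  feats <- aperm(ds$images, c(1, 3, 2))
  dim(feats) <- c(N, W * H)
  coord_map <- cbind(row = rep(seq_len(H), each = W),
                     col = rep(seq_len(W), times = H))
  structure(list(features = feats, labels = ds$labels,
                 coord_map = coord_map, shape = c(H, W),
                 name = ds$name, split = ds$split,
                 n_classes = ds$n_classes),
            class = "flat_dataset")
}

#' Reassemble images from a flat dataset
#'
#' Inverse of [flatten()] for full (unrestricted) flat datasets.
#'
#' @param fd a `flat_dataset` whose `coord_map` covers the full grid.
#' @return An [image_dataset()].
#' @export
unflatten <- function(fd) {
  stopifnot(inherits(fd, "flat_dataset"))
  H <- fd$shape[1]; W <- fd$shape[2]
  if (nrow(fd$coord_map) != H * W) {
    stop_input("cannot unflatten a restricted dataset")
  }
  N <- nrow(fd$features)
  imgs <- fd$features
  dim(imgs) <- c(N, W, H)
  image_dataset(aperm(imgs, c(1, 3, 2)), fd$labels, split = fd$split,
                name = fd$name)
}

#' Specify a synthetic dataset with planted MI structure
#'
#' The generated world has three pixel populations: *informative* pixels
#' whose means shift with the class label (via a seeded per-pixel, per-class
#' sign table, so distinct informative pixels carry near-orthogonal class
#' profiles and stay mutually non-redundant), *redundancy groups* whose
#' members share one latent value per sample plus small independent noise,
#' and pure-noise background pixels.
#'
#' @param n_samples number of images.
#' @param height,width image size (default 28 x 28).
#' @param n_classes number of (uniform) class labels, default 8.
#' @param informative_pixels either a count (auto-placed from `seed`) or an
#'   m x 2 matrix of 1-based (row, col) coordinates.
#' @param redundancy_groups either a count of groups or a list of
#'   coordinate matrices; `group_size` applies to auto-placement.
#' @param group_size pixels per auto-placed redundancy group.
#' @param noise_sd Gaussian noise sd for background and informative pixels
#'   (default 0.15 in intensity units).
#' @param class_shift total class mean separation for informative pixels
#'   (default 0.5: means at 0.5 +/- 0.25).
#' @param group_noise_sd member noise sd inside redundancy groups (0.05).
#' @param seed integer seed; drives placement, sign table, and sampling.
#' @return A `synthetic_spec` with resolved coordinate matrices.
#' @export
synthetic_spec <- function(n_samples = 2000, height = 28, width = 28,
                           n_classes = 8, informative_pixels = 25,
                           redundancy_groups = 5, group_size = 4,
                           noise_sd = 0.15, class_shift = 0.5,
                           group_noise_sd = 0.05, seed = 1) {
  stopifnot(n_samples >= 2, height >= 1, width >= 1, n_classes >= 2,
            noise_sd >= 0, group_noise_sd >= 0, class_shift >= 0)
  auto_inf <- is.numeric(informative_pixels) &&
    length(informative_pixels) == 1L
  auto_grp <- is.numeric(redundancy_groups) && !is.list(redundancy_groups)
  n_auto <- (if (auto_inf) informative_pixels else 0) +
    (if (auto_grp) redundancy_groups * group_size else 0)
  placed <- NULL
  if (n_auto > 0) {
    if (n_auto > height * width) stop_input("more planted pixels than grid")
    placed <- with_seed(derive_seed(seed, 1), {
      flat <- sample.int(height * width, n_auto)
      cbind(row = (flat - 1L) %/% width + 1L, col = (flat - 1L) %% width + 1L)
    })
  }
  used <- 0L
  if (auto_inf) {
    informative_pixels <- if (informative_pixels > 0) {
      placed[seq_len(informative_pixels), , drop = FALSE]
    } else {
      matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col")))
    }
    used <- nrow(informative_pixels)
  } else {
    informative_pixels <- as.matrix(informative_pixels)
  }
  if (auto_grp) {
    n_grp <- redundancy_groups
    redundancy_groups <- lapply(seq_len(n_grp), function(g) {
      placed[used + (g - 1L) * group_size + seq_len(group_size), ,
             drop = FALSE]
    })
  } else {
    redundancy_groups <- lapply(redundancy_groups, as.matrix)
  }
  all_coords <- rbind(informative_pixels, do.call(rbind, redundancy_groups))
  if (length(all_coords)) {
    if (any(all_coords[, 1] < 1 | all_coords[, 1] > height |
            all_coords[, 2] < 1 | all_coords[, 2] > width)) {
      stop_input("planted coordinates out of bounds")
    }
    flat <- (all_coords[, 1] - 1) * width + all_coords[, 2]
    if (anyDuplicated(flat)) {
      stop_input("informative and redundancy-group coordinates must be disjoint")
    }
  }
  structure(list(n_samples = as.integer(n_samples),
                 height = as.integer(height), width = as.integer(width),
                 n_classes = as.integer(n_classes),
                 informative_pixels = informative_pixels,
                 redundancy_groups = redundancy_groups,
                 noise_sd = noise_sd, class_shift = class_shift,
                 group_noise_sd = group_noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Generate a synthetic dataset from a spec
#'
#' Fully reproducible given `spec$seed`; all randomness flows through one
#' seeded stream and the caller's RNG state is untouched.
#'
#' @param spec a [synthetic_spec()].
#' @param split split tag for the resulting dataset.
#' @return An [image_dataset()].
#' @export
generate_synthetic <- function(spec, split = "train") {
  stopifnot(inherits(spec, "synthetic_spec"))
  N <- spec$n_samples; H <- spec$height; W <- spec$width
  with_seed(derive_seed(spec$seed, 2), {
    labels <- sample.int(spec$n_classes, N, replace = TRUE) - 1L
    imgs <- array(clip01(stats::rnorm(N * H * W, 0.5, spec$noise_sd)),
                  dim = c(N, H, W))
    n_inf <- nrow(spec$informative_pixels)
    if (n_inf > 0) {
      # per-pixel random class sign profile: mean = 0.5 +/- class_shift/2
      signs <- matrix(sample(c(-1, 1), n_inf * spec$n_classes,
                             replace = TRUE),
                      nrow = n_inf)
      for (j in seq_len(n_inf)) {
        r <- spec$informative_pixels[j, 1]; c <- spec$informative_pixels[j, 2]
        mu <- 0.5 + spec$class_shift / 2 * signs[j, labels + 1L]
        imgs[, r, c] <- clip01(mu + stats::rnorm(N, 0, spec$noise_sd))
      }
    }
    for (grp in spec$redundancy_groups) {
      latent <- stats::runif(N, 0.2, 0.8)
      for (j in seq_len(nrow(grp))) {
        imgs[, grp[j, 1], grp[j, 2]] <-
          clip01(latent + stats::rnorm(N, 0, spec$group_noise_sd))
      }
    }
    ds <- image_dataset(imgs, labels, split = split, name = "synthetic")
    ds$n_classes <- spec$n_classes
    ds
  })
}
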