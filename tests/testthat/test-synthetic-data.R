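make_small_spec <- function(seed = 3, n = 600) {
  synthetic_spec(n_samples = n, height = 8, width = 8, n_classes = 4,
                 informative_pixels = 6, redundancy_groups = 2,
                 group_size = 3, seed = seed)
}

test_that("NPZ dataset loading validates, rescales and round-trips", {
  ds <- generate_synthetic(make_small_spec(), split = "train")
  path <- tempfile(fileext = ".npz")
  write_npz_dataset(ds, path, dtype = "u1")
  back <- load_npz_dataset(path, "train")
  expect_equal(dim(back$images), dim(ds$images))
  expect_equal(back$labels, ds$labels)
  # uint8 storage quantizes to 1/255 steps
  expect_lt(max(abs(back$images - ds$images)), 0.5 / 255)
  expect_gte(min(back$images), 0)
  expect_lte(max(back$images), 1)

  # uint8 value 255 loads as exactly 1.0
  imgs <- array(as.raw(255), dim = c(2, 4, 4))
  p2 <- tempfile(fileext = ".npz")
  write_npz(p2, list(train_images = imgs, train_labels = c(0L, 1L)))
  expect_equal(max(load_npz_dataset(p2, "train")$images), 1.0)

  # missing member named in the error
  p3 <- tempfile(fileext = ".npz")
  write_npz(p3, list(test_images = imgs))
  expect_error(load_npz_dataset(p3, "test"), "test_labels")

  # non-square images rejected with a dimension error
  p4 <- tempfile(fileext = ".npz")
  write_npz(p4, list(train_images = array(as.raw(0), dim = c(2, 4, 6)),
                     train_labels = c(0L, 1L)))
  expect_error(load_npz_dataset(p4, "train"), "non-square")

  # key overrides support other archive dialects
  p5 <- tempfile(fileext = ".npz")
  write_npz(p5, list(imgs = imgs, labs = c(0L, 1L)))
  d5 <- load_npz_dataset(p5, "train", keys = list(images = "imgs",
                                                  labels = "labs"))
  expect_equal(dim(d5$images), c(2, 4, 4))
})

test_that("flatten is row-major and unflatten inverts it exactly", {
  img <- array(0, dim = c(1, 2, 2))
  img[1, , ] <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2, byrow = TRUE)
  ds <- image_dataset(img, 0L)
  fd <- flatten(ds)
  expect_equal(as.vector(fd$features), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(unname(fd$coord_map),
               cbind(c(1L, 1L, 2L, 2L), c(1L, 2L, 1L, 2L)))

  set.seed(7)
  ds2 <- image_dataset(array(runif(5 * 4 * 4), dim = c(5, 4, 4)),
                       sample(0:2, 5, replace = TRUE))
  expect_equal(ncol(flatten(ds2)$features), 16)
  expect_equal(unflatten(flatten(ds2))$images, ds2$images)
  # features[i, j] == images[i, coord_map[j, ]]
  fd2 <- flatten(ds2)
  for (j in c(1, 7, 16)) {
    expect_equal(fd2$features[, j],
                 ds2$images[, fd2$coord_map[j, 1], fd2$coord_map[j, 2]])
  }
})

test_that("synthetic generation is deterministic and respects the spec", {
  spec <- make_small_spec()
  a <- generate_synthetic(spec)
  b <- generate_synthetic(spec)
  expect_identical(a$images, b$images)
  expect_identical(a$labels, b$labels)
  expect_gte(min(a$images), 0)
  expect_lte(max(a$images), 1)

  expect_error(
    synthetic_spec(height = 8, width = 8,
                   informative_pixels = rbind(c(2, 2)),
                   redundancy_groups = list(rbind(c(2, 2), c(3, 3)))),
    "disjoint")
  expect_error(
    synthetic_spec(height = 4, width = 4,
                   informative_pixels = rbind(c(5, 1)),
                   redundancy_groups = list()),
    "out of bounds")
})

test_that("a spec with no planted structure gives near-zero importance", {
  spec <- synthetic_spec(n_samples = 1500, height = 6, width = 6,
                         n_classes = 2, informative_pixels = 0,
                         redundancy_groups = 0, seed = 11)
  dd <- discretize(flatten(generate_synthetic(spec)), 20)
  imp <- estimate_importance(dd)
  # small-sample bias bound for independent data: ~ (bins-1)(classes-1)/(2N),
  # allow a generous factor for variance across 36 pixels
  bias <- (20 - 1) * (2 - 1) / (2 * 1500)
  expect_lt(max(imp), 6 * bias)
})

test_that("planted informative pixels dominate the importance ranking", {
  for (seed in 1:10) {
    spec <- synthetic_spec(n_samples = 2000, seed = seed)
    ds <- generate_synthetic(spec)
    fd <- flatten(ds)
    imp <- estimate_importance(discretize(fd, 20))
    planted <- (spec$informative_pixels[, 1] - 1) * spec$width +
      spec$informative_pixels[, 2]
    top <- order(-imp)[seq_len(nrow(spec$informative_pixels))]
    expect_gte(length(intersect(top, planted)), 20)

    noise <- setdiff(seq_len(spec$height * spec$width),
                     c(planted, unlist(lapply(spec$redundancy_groups,
                                              function(g) (g[, 1] - 1) *
                                                spec$width + g[, 2]))))
    expect_gt(mean(imp[planted]), mean(imp[noise]))
  }
})

test_that("redundancy groups show high within-group pairwise MI", {
  spec <- make_small_spec(seed = 5, n = 2000)
  dd <- discretize(flatten(generate_synthetic(spec)), 20)
  grp <- spec$redundancy_groups[[1]]
  gflat <- sort((grp[, 1] - 1) * spec$width + grp[, 2])
  pairs <- t(combn(gflat, 2))
  within <- estimate_redundancy(dd, pairs)$value
  # a decoupled control pair: group pixel vs a noise pixel
  planted <- c((spec$informative_pixels[, 1] - 1) * spec$width +
                 spec$informative_pixels[, 2],
               unlist(lapply(spec$redundancy_groups,
                             function(g) (g[, 1] - 1) * spec$width + g[, 2])))
  # control: group pixel vs noise pixels; their estimated MI is pure
  # small-sample bias (~ (nb-1)^2 / 2N nats)
  noise <- setdiff(seq_len(64), planted)[1:4]
  ctrl_pairs <- t(vapply(noise, function(nz) sort(c(gflat[1], nz)),
                         numeric(2)))
  ctrl <- mean(estimate_redundancy(dd, ctrl_pairs)$value)
  expect_gt(min(within), 4 * ctrl)
})
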