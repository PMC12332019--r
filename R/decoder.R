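# Convolutional reconstruction decoder: linear layer -> ReLU -> transposed
# conv (stride 2) -> ReLU -> transposed conv (stride 2) -> sigmoid, trained
# with Adam on MSE. Implemented directly on BLAS matrix ops: activations
# are stored as (N*positions, channels) matrices, and each transposed
# convolution is a sum over kernel offsets of a gather -> matmul -> scatter,
# which is exact and fast at these image sizes. No deep-learning backend
# is available in this environment, so the network and its gradients are
# authored here.

#' Decoder configuration
#'
#' @param k number of input values (selected pixels or latent size).
#' @param side output image side; must be divisible by 4 (two stride-2
#'   upsampling layers; other sides are rejected rather than padded).
#' @param c1,c2 hidden channel counts of the two transposed-conv layers
#'   (defaults 32 and 16).
#' @param kernel,stride,pad transposed-conv geometry (defaults 4 / 2 / 1,
#'   giving side/4 -> side/2 -> side).
#' @param lr Adam learning rate (default 0.001).
#' @param epochs training epochs (default 20).
#' @param batch_size minibatch size (default 128).
#' @param seed seed for parameter init and batch shuffling.
#' @return A `decoder_config`.
#' @export
decoder_config <- function(k, side, c1 = 32, c2 = 16, kernel = 4,
                           stride = 2, pad = 1, lr = 0.001, epochs = 20,
                           batch_size = 128, seed = 1) {
  if (side %% 4 != 0) {
    stop_input("image side must be divisible by 4 (got ", side, ")")
  }
  s4 <- side %/% 4
  up <- function(h) (h - 1) * stride - 2 * pad + kernel
  if (up(s4) != side %/% 2 || up(side %/% 2) != side) {
    stop_input("kernel/stride/pad do not upsample side/4 to side")
  }
  structure(list(k = as.integer(k), side = as.integer(side),
                 c1 = as.integer(c1), c2 = as.integer(c2),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 pad = as.integer(pad), lr = lr,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "decoder_config")
}

# per kernel-offset valid (input position, output position) pairs for a
# transposed convolution (H, W) -> (H2, W2); positions row-major 1-based
convt_index <- function(H, W, H2, W2, kernel, stride, pad) {
  ipos <- vector("list", kernel * kernel)
  opos <- vector("list", kernel * kernel)
  o <- 1L
  for (kh in 0:(kernel - 1)) {
    ih <- 0:(H - 1); oh <- stride * ih - pad + kh
    vr <- oh >= 0 & oh < H2
    for (kw in 0:(kernel - 1)) {
      iw <- 0:(W - 1); ow <- stride * iw - pad + kw
      vc <- ow >= 0 & ow < W2
      ihv <- ih[vr]; ohv <- oh[vr]; iwv <- iw[vc]; owv <- ow[vc]
      ipos[[o]] <- as.integer(rep(ihv * W, each = length(iwv)) +
                                rep(iwv, times = length(ihv)) + 1L)
      opos[[o]] <- as.integer(rep(ohv * W2, each = length(owv)) +
                                rep(owv, times = length(ohv)) + 1L)
      o <- o + 1L
    }
  }
  list(ipos = ipos, opos = opos, P_in = H * W, P_out = H2 * W2)
}

rows_for <- function(pos, N) {
  as.vector(outer(seq_len(N), (pos - 1L) * N, `+`))
}

convt_fwd <- function(A, Wk, bias, idx, N, Cout) {
  Y <- matrix(0, N * idx$P_out, Cout)
  for (o in seq_along(idx$ipos)) {
    ip <- idx$ipos[[o]]
    if (!length(ip)) next
    ro <- rows_for(idx$opos[[o]], N)
    Y[ro, ] <- Y[ro, ] + A[rows_for(ip, N), , drop = FALSE] %*% Wk[[o]]
  }
  for (cc in seq_len(Cout)) Y[, cc] <- Y[, cc] + bias[cc]
  Y
}

convt_bwd <- function(dY, A, Wk, idx, N, Cin) {
  dA <- matrix(0, N * idx$P_in, Cin)
  dWk <- vector("list", length(Wk))
  for (o in seq_along(idx$ipos)) {
    ip <- idx$ipos[[o]]
    if (!length(ip)) { dWk[[o]] <- Wk[[o]] * 0; next }
    ri <- rows_for(ip, N); ro <- rows_for(idx$opos[[o]], N)
    dYo <- dY[ro, , drop = FALSE]
    dA[ri, ] <- dA[ri, ] + dYo %*% t(Wk[[o]])
    dWk[[o]] <- crossprod(A[ri, , drop = FALSE], dYo)
  }
  list(dA = dA, dWk = dWk, db = colSums(dY))
}

relu <- function(x) x * (x > 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Build an (untrained) reconstruction decoder
#'
#' Parameter initialization is seeded (He-style normal scaling for ReLU
#' layers, Xavier-style for the sigmoid output layer); two builds with the
#' same config are bit-identical.
#'
#' @param cfg a [decoder_config()].
#' @return A `decoder` object holding parameters, Adam state and the
#'   precomputed scatter indices.
#' @export
build_decoder <- function(cfg) {
  stopifnot(inherits(cfg, "decoder_config"))
  s4 <- cfg$side %/% 4; s2 <- cfg$side %/% 2
  nk <- cfg$kernel^2
  with_seed(derive_seed(cfg$seed, 11), {
    params <- list(
      W0 = matrix(stats::rnorm(cfg$k * cfg$c1 * s4^2,
                               sd = sqrt(2 / cfg$k)),
                  cfg$k, cfg$c1 * s4^2),
      b0 = numeric(cfg$c1 * s4^2),
      W1 = lapply(seq_len(nk), function(o)
        matrix(stats::rnorm(cfg$c1 * cfg$c2, sd = sqrt(2 / (cfg$c1 * nk))),
               cfg$c1, cfg$c2)),
      b1 = numeric(cfg$c2),
      W2 = lapply(seq_len(nk), function(o)
        matrix(stats::rnorm(cfg$c2, sd = sqrt(1 / (cfg$c2 * nk))),
               cfg$c2, 1)),
      b2 = numeric(1))
    structure(list(cfg = cfg, params = params, encoder = NULL,
                   idx1 = convt_index(s4, s4, s2, s2, cfg$kernel,
                                      cfg$stride, cfg$pad),
                   idx2 = convt_index(s2, s2, cfg$side, cfg$side,
                                      cfg$kernel, cfg$stride, cfg$pad),
                   adam = NULL),
              class = "decoder")
  })
}

#' Attach a linear encoder (autoencoder variant)
#'
#' Adds a seeded linear map from `n_in` inputs (full flattened image) to
#' the k-dimensional latent that feeds the decoder; encoder and decoder
#' are then trained jointly, giving a lightweight autoencoder whose
#' decoder matches the reconstruction network.
#'
#' @param dec a `decoder`.
#' @param n_in input dimension of the encoder.
#' @return The decoder with an `encoder` component.
#' @export
add_linear_encoder <- function(dec, n_in) {
  stopifnot(inherits(dec, "decoder"))
  dec$encoder <- with_seed(derive_seed(dec$cfg$seed, 12), list(
    We = matrix(stats::rnorm(n_in * dec$cfg$k, sd = sqrt(1 / n_in)),
                n_in, dec$cfg$k),
    be = numeric(dec$cfg$k)))
  dec
}

decoder_forward <- function(dec, X, cache = FALSE) {
  cfg <- dec$cfg; p <- dec$params
  N <- nrow(X)
  X0 <- NULL
  if (!is.null(dec$encoder)) {
    X0 <- X
    X <- X %*% dec$encoder$We
    X <- sweep(X, 2, dec$encoder$be, `+`)
  }
  Z0 <- X %*% p$W0
  Z0 <- sweep(Z0, 2, p$b0, `+`)
  A0 <- relu(Z0)
  s4 <- cfg$side %/% 4
  A0m <- A0
  dim(A0m) <- c(N * s4^2, cfg$c1)
  Z1 <- convt_fwd(A0m, p$W1, p$b1, dec$idx1, N, cfg$c2)
  A1 <- relu(Z1)
  Z2 <- convt_fwd(A1, p$W2, p$b2, dec$idx2, N, 1L)
  out <- sigmoid(Z2)
  out_mat <- out
  dim(out_mat) <- c(N, cfg$side^2)
  if (!cache) return(out_mat)
  list(out = out_mat, out_vec = out, Z2 = Z2, A1 = A1, Z1 = Z1,
       A0m = A0m, Z0 = Z0, X = X, X0 = X0, N = N)
}

#' Reconstruct images from decoder inputs
#' @param object a `decoder`.
#' @param newdata N x k input matrix (or N x n_in with an encoder).
#' @param ... unused.
#' @return N x side^2 matrix of reconstructions in row-major pixel order.
#' @export
predict.decoder <- function(object, newdata, ...) {
  decoder_forward(object, as.matrix(newdata), cache = FALSE)
}

decoder_backward <- function(dec, fw, dOut) {
  cfg <- dec$cfg; p <- dec$params
  N <- fw$N
  dZ2 <- as.vector(dOut) * fw$out_vec * (1 - fw$out_vec)
  dim(dZ2) <- c(N * cfg$side^2, 1L)
  b2g <- convt_bwd(dZ2, fw$A1, p$W2, dec$idx2, N, cfg$c2)
  dZ1 <- b2g$dA * (fw$Z1 > 0)
  b1g <- convt_bwd(dZ1, fw$A0m, p$W1, dec$idx1, N, cfg$c1)
  s4 <- cfg$side %/% 4
  dZ0 <- b1g$dA * (as.vector(fw$Z0) > 0)
  dim(dZ0) <- c(N, cfg$c1 * s4^2)
  grads <- list(W0 = crossprod(fw$X, dZ0), b0 = colSums(dZ0),
                W1 = b1g$dWk, b1 = b1g$db,
                W2 = b2g$dWk, b2 = b2g$db)
  if (!is.null(dec$encoder)) {
    dX <- dZ0 %*% t(p$W0)
    grads$We <- crossprod(fw$X0, dX)
    grads$be <- colSums(dX)
  }
  grads
}

adam_init <- function(params) {
  zero_like <- function(x) if (is.list(x)) lapply(x, zero_like) else x * 0
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0L)
}

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    p <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(p = p, m = m, v = v)
  }
  out <- Map(upd, params, grads, state$m, state$v)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"),
                    v = lapply(out, `[[`, "v"), t = state$t))
}

#' Train a reconstruction decoder
#'
#' Minimizes mean squared error between reconstructions and full target
#' images with Adam. Inputs are the masked pixel values (fixed row-major
#' order of the selected coordinates) or, with an encoder attached, the
#' full flattened images.
#'
#' @param dec a `decoder` from [build_decoder()].
#' @param X N x k input matrix (N x n_in with an encoder).
#' @param Y N x side^2 target matrix, row-major pixel order (e.g.
#'   `flatten(ds)$features`).
#' @return List with `decoder` (trained) and `loss_history` (per-epoch
#'   mean training MSE, length = epochs).
#' @export
train_decoder <- function(dec, X, Y) {
  stopifnot(inherits(dec, "decoder"))
  cfg <- dec$cfg
  X <- as.matrix(X); Y <- as.matrix(Y)
  n_in <- if (is.null(dec$encoder)) cfg$k else nrow(dec$encoder$We)
  if (ncol(X) != n_in) {
    stop_input("input has ", ncol(X), " columns; decoder expects ", n_in)
  }
  if (ncol(Y) != cfg$side^2) stop_input("targets must be N x side^2")
  N <- nrow(X)
  all_params <- dec$params
  if (!is.null(dec$encoder)) {
    all_params$We <- dec$encoder$We
    all_params$be <- dec$encoder$be
  }
  state <- dec$adam %||% adam_init(all_params)
  loss_hist <- numeric(cfg$epochs)
  with_seed(derive_seed(cfg$seed, 13), {
    for (ep in seq_len(cfg$epochs)) {
      perm <- sample.int(N)
      tot <- 0
      for (start in seq(1, N, by = cfg$batch_size)) {
        rows <- perm[start:min(start + cfg$batch_size - 1, N)]
        xb <- X[rows, , drop = FALSE]
        yb <- Y[rows, , drop = FALSE]
        fw <- decoder_forward(dec, xb, cache = TRUE)
        err <- fw$out - yb
        loss <- mean(err^2)
        tot <- tot + loss * length(rows)
        dOut <- 2 * err / length(err)
        grads <- decoder_backward(dec, fw, dOut)
        stepped <- adam_step(all_params, grads, state, cfg$lr)
        all_params <- stepped$params
        state <- stepped$state
        dec$params <- all_params[c("W0", "b0", "W1", "b1", "W2", "b2")]
        if (!is.null(dec$encoder)) {
          dec$encoder$We <- all_params$We
          dec$encoder$be <- all_params$be
        }
      }
      loss_hist[ep] <- tot / N
    }
  })
  dec$adam <- state
  list(decoder = dec, loss_history = loss_hist)
}

#' Test-set reconstruction error
#'
#' Pooled mean over all pixels of all images of the squared error between
#' reconstruction and ground truth. Pure function of its arguments.
#'
#' @param dec a trained `decoder`.
#' @param X N x k test inputs.
#' @param Y N x side^2 test targets (row-major).
#' @return Scalar MSE >= 0.
#' @export
evaluate_mse <- function(dec, X, Y) {
  pred <- predict(dec, X)
  mean((pred - as.matrix(Y))^2)
}

#' Extract masked pixel values as decoder inputs
#'
#' Columns follow the fixed row-major order of the selected coordinates
#' (the order of `which(mask == 1)` under the row-major `coord_map`).
#'
#' @param fd a full `flat_dataset`.
#' @param mask binary mask of length n.
#' @return N x k matrix.
#' @export
mask_inputs <- function(fd, mask) {
  stopifnot(inherits(fd, "flat_dataset"))
  assert_binary_mask(mask, ncol(fd$features))
  fd$features[, which(mask == 1), drop = FALSE]
}

#' Sparse-PCA-style feature transform (lightweight stand-in)
#'
#' Rank-k PCA (prcomp, a standard component) with per-component
#' hard-thresholded loadings: only the `floor(keep_frac * n)` largest
#' |loading| entries of each component are kept, then the component is
#' renormalized. No sparse-PCA package is available in this environment;
#' this documented stand-in produces sparse linear features for the
#' benchmark comparator and is never asserted on quantitatively.
#'
#' @param train_features N x n training matrix.
#' @param k number of components.
#' @param keep_frac fraction of loadings kept per component (default 0.1).
#' @return List with `transform(X)` closure, `loadings`, `center`.
#' @export
spca_features <- function(train_features, k, keep_frac = 0.1) {
  pc <- stats::prcomp(train_features, center = TRUE, scale. = FALSE,
                      rank. = k)
  V <- pc$rotation[, seq_len(k), drop = FALSE]
  q <- max(1L, floor(keep_frac * nrow(V)))
  for (c in seq_len(k)) {
    v <- V[, c]
    cut <- sort(abs(v), decreasing = TRUE)[q]
    v[abs(v) < cut] <- 0
    nrm <- sqrt(sum(v^2))
    V[, c] <- if (nrm > 0) v / nrm else v
  }
  center <- pc$center
  list(transform = function(X) sweep(as.matrix(X), 2, center) %*% V,
       loadings = V, center = center)
}
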