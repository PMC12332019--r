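# Independent oracles, kept deliberately naive and separate from the
# package's computation paths.

# plug-in MI by enumerating the full contingency table with base::table()
mi_bruteforce <- function(a, b) {
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab)
  pb <- colSums(tab)
  mi <- 0
  for (r in seq_len(nrow(tab))) {
    for (s in seq_len(ncol(tab))) {
      p <- tab[r, s]
      if (p > 0) mi <- mi + p * log(p / (pa[r] * pb[s]))
    }
  }
  unname(mi)
}

# dense-matrix energy oracle: x' Q x with upper-triangular Q plus offset
qubo_energy_dense <- function(q, x) {
  Q <- matrix(0, q$n, q$n)
  diag(Q) <- q$linear
  if (nrow(q$quad)) Q[cbind(q$quad$i, q$quad$j)] <- q$quad$value
  sum(Q * outer(x, x)) + q$offset
}

# random sparse-ish QUBO instance built with R's RNG (call inside a seed)
random_qubo <- function(n, density = 0.5) {
  pairs <- qubofs:::all_pairs(n)
  keep <- runif(nrow(pairs)) < density
  quad <- if (any(keep)) {
    data.frame(i = pairs[keep, 1], j = pairs[keep, 2],
               value = rnorm(sum(keep)))
  } else NULL
  qubo_problem(n, rnorm(n), quad)
}

# all binary masks of length n as rows (n small)
all_masks <- function(n) {
  as.matrix(expand.grid(rep(list(0:1), n)))[, n:1, drop = FALSE]
}

# brute-force minimum over all masks; returns list(mask, energy)
brute_minimum <- function(q) {
  masks <- all_masks(q$n)
  energies <- apply(masks, 1, function(x) qubo_energy_dense(q, x))
  best <- which.min(energies)
  list(mask = as.integer(masks[best, ]), energy = energies[best])
}

tiny_flat <- function(features, labels) {
  n <- ncol(features)
  structure(list(features = features, labels = as.integer(labels),
                 coord_map = cbind(row = rep(1L, n), col = seq_len(n)),
                 shape = c(1L, n), name = "tiny", split = "train",
                 n_classes = max(labels) + 1L),
            class = "flat_dataset")
}
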