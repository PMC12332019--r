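`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's
#' `.Random.seed` afterwards, so seeded package internals never leak
#' global RNG state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible child seed
#'
#' Deterministic mixing of a master seed with one or more stream indices
#' (Lehmer-style), always returning a positive integer below 2^31 so the
#' result is a valid R seed.
#'
#' @param master integer master seed.
#' @param ... integer stream indices.
#' @return A single integer seed.
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647
  s <- (abs(as.numeric(master)) %% m)
  for (idx in c(...)) {
    s <- (s * 48271 + (abs(as.numeric(idx)) + 1) * 16807) %% m
  }
  as.integer(s %% (m - 1) + 1)
}

stop_input <- function(...) stop(..., call. = FALSE)

assert_binary_mask <- function(x, n) {
  if (length(x) != n) stop_input("mask length ", length(x),
                                 " does not match problem size ", n)
  if (!all(x %in% c(0, 1))) stop_input("mask entries must be 0 or 1")
  invisible(as.integer(x))
}

# cheap content hash for provenance metadata (CRC32 of the serialization)
content_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  crc <- cpp_crc32(raw)  # returned as double (uint32 range)
  sprintf("%04x%04x", as.integer(crc %/% 65536), as.integer(crc %% 65536))
}
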