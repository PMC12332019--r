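# Minimal NPY/NPZ support. NPY is a 10-byte-plus-header binary format; NPZ
# is a zip of NPY members. Reading goes through utils::unzip (handles both
# stored and deflated members); writing emits a stored (method 0) zip so no
# external zip binary is needed.

NPY_MAGIC <- as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59))

npy_dtype_reader <- function(descr) {
  endian <- substring(descr, 1, 1)
  if (!endian %in% c("<", "|", "=")) {
    stop_input("unsupported NPY byte order in dtype '", descr, "'")
  }
  code <- substring(descr, 2)
  switch(code,
    "u1" = list(what = "integer", size = 1L, signed = FALSE, bytes = 1L),
    "i1" = list(what = "integer", size = 1L, signed = TRUE,  bytes = 1L),
    "u2" = list(what = "integer", size = 2L, signed = FALSE, bytes = 2L),
    "i2" = list(what = "integer", size = 2L, signed = TRUE,  bytes = 2L),
    "i4" = list(what = "integer", size = 4L, signed = TRUE,  bytes = 4L),
    "i8" = list(what = "integer", size = 8L, signed = TRUE,  bytes = 8L),
    "f4" = list(what = "double",  size = 4L, signed = TRUE,  bytes = 4L),
    "f8" = list(what = "double",  size = 8L, signed = TRUE,  bytes = 8L),
    stop_input("unsupported NPY dtype '", descr, "'")
  )
}

#' Parse a raw NPY byte vector into an R array
#' @param bytes raw vector with full NPY file contents.
#' @return numeric/integer vector, matrix or array with the NPY shape.
#' @keywords internal
parse_npy <- function(bytes) {
  if (length(bytes) < 10 || !identical(bytes[1:6], NPY_MAGIC)) {
    stop_input("not an NPY stream")
  }
  major <- as.integer(bytes[7])
  if (major == 1L) {
    hlen <- as.integer(bytes[9]) + 256L * as.integer(bytes[10])
    hstart <- 11L
  } else {
    hlen <- sum(as.numeric(bytes[9:12]) * 256^(0:3))
    hstart <- 13L
  }
  header <- rawToChar(bytes[hstart:(hstart + hlen - 1L)])
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_s <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape_s <- gsub("[[:space:]]", "", shape_s)
  shape <- if (nzchar(shape_s)) {
    parts <- strsplit(shape_s, ",")[[1]]
    as.integer(parts[nzchar(parts)])
  } else integer(0)
  rd <- npy_dtype_reader(descr)
  n <- if (length(shape)) prod(shape) else 1L
  data <- bytes[(hstart + hlen):length(bytes)]
  vec <- readBin(data, what = rd$what, n = n, size = rd$size,
                 signed = rd$signed, endian = "little")
  if (length(vec) != n) stop_input("truncated NPY data block")
  if (length(shape) <= 1L) return(vec)
  if (fortran) {
    array(vec, dim = shape)
  } else {
    aperm(array(vec, dim = rev(shape)), rev(seq_along(shape)))
  }
}

#' Read all arrays from an NPZ archive
#'
#' @param path path to an `.npz` file.
#' @return Named list of arrays (names are member names without `.npy`).
#' @export
read_npz <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  exdir <- tempfile("npz")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  files <- utils::unzip(path, exdir = exdir)
  out <- list()
  for (f in files) {
    nm <- sub("\\.npy$", "", basename(f))
    bytes <- readBin(f, "raw", n = file.info(f)$size)
    out[[nm]] <- parse_npy(bytes)
  }
  out
}

npy_serialize <- function(arr) {
  if (is.raw(arr)) {
    descr <- "|u1"; size <- 1L
  } else if (is.integer(arr)) {
    descr <- "<i4"; size <- 4L
  } else if (is.double(arr)) {
    descr <- "<f8"; size <- 8L
  } else {
    stop_input("cannot serialize type '", typeof(arr), "' to NPY")
  }
  d <- dim(arr) %||% length(arr)
  shape_s <- if (length(d) == 1L) paste0(d, ",") else paste(d, collapse = ", ")
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': (%s), }",
                    descr, shape_s)
  pad <- (64L - (10L + nchar(header) + 1L) %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  vec <- if (length(d) > 1L) as.vector(aperm(arr, rev(seq_along(d)))) else
    as.vector(arr)
  c(NPY_MAGIC, as.raw(c(1L, 0L)),
    writeBin(nchar(header), raw(), size = 2L, endian = "little"),
    charToRaw(header),
    if (is.raw(vec)) vec else
      writeBin(vec, raw(), size = size, endian = "little"))
}

le_bytes <- function(x, n) {
  as.raw(floor(x / 256^(0:(n - 1))) %% 256)
}

#' Write arrays to an NPZ archive (stored, uncompressed)
#'
#' @param path output path.
#' @param arrays named list of numeric/integer/raw arrays.
#' @export
write_npz <- function(path, arrays) {
  if (is.null(names(arrays)) || any(!nzchar(names(arrays)))) {
    stop_input("all arrays must be named")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  central <- raw(0)
  offset <- 0
  for (nm in names(arrays)) {
    fname <- charToRaw(paste0(nm, ".npy"))
    data <- npy_serialize(arrays[[nm]])
    crc <- cpp_crc32(data)
    sz <- length(data)
    local_hdr <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)),
                   le_bytes(20, 2), le_bytes(0, 2), le_bytes(0, 2),
                   le_bytes(0, 2), le_bytes(0, 2),
                   le_bytes(crc, 4), le_bytes(sz, 4), le_bytes(sz, 4),
                   le_bytes(length(fname), 2), le_bytes(0, 2), fname)
    writeBin(local_hdr, con)
    writeBin(data, con)
    central <- c(central,
                 as.raw(c(0x50, 0x4b, 0x01, 0x02)),
                 le_bytes(20, 2), le_bytes(20, 2), le_bytes(0, 2),
                 le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 2),
                 le_bytes(crc, 4), le_bytes(sz, 4), le_bytes(sz, 4),
                 le_bytes(length(fname), 2), le_bytes(0, 2), le_bytes(0, 2),
                 le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 4),
                 le_bytes(offset, 4), fname)
    offset <- offset + length(local_hdr) + sz
  }
  writeBin(central, con)
  n_entries <- length(arrays)
  eocd <- c(as.raw(c(0x50, 0x4b, 0x05, 0x06)),
            le_bytes(0, 2), le_bytes(0, 2),
            le_bytes(n_entries, 2), le_bytes(n_entries, 2),
            le_bytes(length(central), 4), le_bytes(offset, 4),
            le_bytes(0, 2))
  writeBin(eocd, con)
  invisible(path)
}
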