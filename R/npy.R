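# Minimal NPY (NumPy binary) matrix IO. Supports the subset this package
# exchanges with embedding providers: 2-D arrays of little-endian float64,
# float32, int32 or int64, C or Fortran order. Written files are always
# '<f8', C-order, NPY format version 1.0.

npy_magic <- as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59))

is_npy_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  identical(readBin(con, "raw", 6L), npy_magic)
}

read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readBin(con, "raw", 6L), npy_magic)) {
    abort(sprintf("%s: not an NPY file (bad magic).", path))
  }
  ver <- readBin(con, "integer", 2L, size = 1L, signed = FALSE)
  hlen <- if (ver[1L] >= 2L) {
    readBin(con, "integer", 1L, size = 4L, endian = "little")
  } else {
    readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = "little")
  }
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_str <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  shape <- shape[!is.na(shape)]
  if (length(shape) != 2L) {
    abort(sprintf("%s: expected a 2-D array, got shape (%s).", path,
                  paste(shape, collapse = ", ")))
  }
  n <- prod(shape)
  vals <- switch(descr,
    "<f8" = readBin(con, "double", n, size = 8L, endian = "little"),
    "<f4" = readBin(con, "double", n, size = 4L, endian = "little"),
    "<i4" = as.double(readBin(con, "integer", n, size = 4L,
                              endian = "little")),
    abort(sprintf("%s: unsupported dtype '%s' (use float64/float32/int32).",
                  path, descr))
  )
  if (length(vals) != n) {
    abort(sprintf("%s: truncated payload (%d of %d values).", path,
                  length(vals), n))
  }
  if (fortran) {
    matrix(vals, nrow = shape[1L], ncol = shape[2L])
  } else {
    t(matrix(vals, nrow = shape[2L], ncol = shape[1L]))
  }
}

write_npy <- function(x, path) {
  x <- as_matrix2d(x, "x")
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': (%d, %d), }",
                    nrow(x), ncol(x))
  # pad so that magic(6) + ver(2) + hlen(2) + header is a multiple of 64
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  if (pad == 64L) pad <- 0L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(npy_magic, con)
  writeBin(as.raw(c(1L, 0L)), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeBin(charToRaw(header), con)
  writeBin(as.vector(t(x)), con, size = 8L, endian = "little")
  invisible(path)
}
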