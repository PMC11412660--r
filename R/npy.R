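#' Minimal NumPy NPY array file support
#'
#' Reads and writes NPY version 1.0 files for numeric arrays, the format
#' used for variable-frame and mask outputs. Supported dtypes:
#' little-endian float32/float64 (`<f4`, `<f8`) and int32/int64 (`<i4`,
#' `<i8`; 64-bit integers are read into doubles and must stay below 2^53).
#' Arrays are written in C order with the stated shape, so other tools see
#' the same axis order.
#'
#' @param x numeric/integer array (or vector).
#' @param path file path.
#' @param dtype one of `"float64"`, `"float32"`, `"int32"`.
#' @export
write_npy <- function(x, path, dtype = c("float64", "float32", "int32")) {
  dtype <- match.arg(dtype)
  descr <- switch(dtype, float64 = "<f8", float32 = "<f4", int32 = "<i4")
  sh <- if (is.null(dim(x))) length(x) else dim(x)
  shape_str <- if (length(sh) == 1L) paste0(sh, ",")
               else paste(sh, collapse = ", ")
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': (%s), }",
                    descr, shape_str)
  # pad with spaces + newline so that 10 + header length is a multiple of 64
  unpadded <- 10L + nchar(header, type = "bytes") + 1L
  pad <- (64L - unpadded %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  # C order: last axis fastest; R stores column-major (first axis fastest)
  v <- if (length(sh) > 1L) as.vector(aperm(x, rev(seq_along(sh))))
       else as.vector(x)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, utf8ToInt("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header, type = "bytes")), con, size = 2,
           endian = "little")
  writeBin(charToRaw(header), con)
  if (dtype == "int32") {
    if (any(v != round(v)))
      stop_validation("int32 NPY output requires integer values")
    writeBin(as.integer(v), con, size = 4, endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = if (dtype == "float32") 4 else 8,
             endian = "little")
  }
  invisible(path)
}

#' @rdname write_npy
#' @return `read_npy()`: the array with its original dimensions (integer
#'   array for integer dtypes).
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(as.integer(magic),
                 c(0x93L, utf8ToInt("NUMPY"))))
    stop_validation("not an NPY file")
  ver <- readBin(con, "raw", 2)
  hlen <- if (as.integer(ver[1]) >= 2L)
    readBin(con, "integer", 1, size = 4, endian = "little")
  else readBin(con, "integer", 1, size = 2, endian = "little",
               signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr'\\s*:\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order'\\s*:\\s*True", header)
  shape_str <- sub(".*'shape'\\s*:\\s*\\(([^)]*)\\).*", "\\1", header)
  sh <- as.integer(strsplit(gsub("[, ]+", " ", trimws(shape_str)),
                            " ")[[1]])
  sh <- sh[!is.na(sh)]
  count <- if (length(sh)) prod(sh) else 1L
  v <- switch(descr,
    "<f8" = , "=f8" = readBin(con, "numeric", count, size = 8,
                              endian = "little"),
    "<f4" = , "=f4" = readBin(con, "numeric", count, size = 4,
                              endian = "little"),
    "<i4" = , "=i4" = readBin(con, "integer", count, size = 4,
                              endian = "little"),
    "<i8" = , "=i8" = read_i8(con, count),
    "<i2" = , "=i2" = readBin(con, "integer", count, size = 2,
                              endian = "little"),
    "|i1" = readBin(con, "integer", count, size = 1, endian = "little"),
    "|u1" = readBin(con, "integer", count, size = 1, endian = "little",
                    signed = FALSE),
    stop_validation(sprintf("unsupported NPY dtype '%s'", descr)))
  if (length(sh) <= 1L) return(v)
  if (fortran) array(v, dim = sh)
  else aperm(array(v, dim = rev(sh)), rev(seq_along(sh)))
}

# int64 via 32-bit halves (exact up to 2^53)
read_i8 <- function(con, count) {
  w <- readBin(con, "integer", 2 * count, size = 4, endian = "little")
  lo <- w[seq(1, 2 * count, 2)]
  hi <- w[seq(2, 2 * count, 2)]
  lo_u <- ifelse(lo < 0, lo + 2^32, lo)
  hi * 2^32 + lo_u
}
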