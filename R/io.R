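#' Write a raster matrix as an ESRI ASCII grid
#'
#' Plain-text raster exchange format (`.asc`): a six-line header
#' (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value) followed by one
#' line of values per row, top row first. Row 1 of the matrix is the top
#' (northernmost) row.
#'
#' @param x Numeric or integer matrix.
#' @param path Output file path.
#' @param cellsize Cell size in metres.
#' @param xll,yll Lower-left corner coordinates.
#' @param nodata NODATA sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(x, path, cellsize = 10, xll = 0, yll = 0,
                             nodata = -9999) {
  stopifnot(is.matrix(x))
  hdr <- c(
    sprintf("ncols %d", ncol(x)),
    sprintf("nrows %d", nrow(x)),
    sprintf("xllcorner %.10g", xll),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", cellsize),
    sprintf("NODATA_value %.10g", nodata)
  )
  v <- x
  v[is.na(v)] <- nodata
  rows <- apply(v, 1L, function(r) paste(format(r, trim = TRUE, digits = 15),
                                         collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid into a matrix
#'
#' @param path File written by [write_ascii_grid()] (or any `.asc` raster).
#' @return Matrix with attributes `cellsize`, `xllcorner`, `yllcorner`;
#'   NODATA cells become `NA`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(body) != nr * nc)
    stop("ASCII grid body has ", length(body), " values, expected ", nr * nc)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == vals[["nodata_value"]]] <- NA
  attr(m, "cellsize") <- vals[["cellsize"]]
  attr(m, "xllcorner") <- vals[["xllcorner"]]
  attr(m, "yllcorner") <- vals[["yllcorner"]]
  m
}
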