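#' Read a categorical landscape raster
#'
#' Supported formats, chosen by extension: ESRI ASCII grid (`.asc`, `.txt`;
#' the `cellsize` header is honoured) and plain single-band TIFF (`.tif`,
#' `.tiff`; 8-bit unsigned codes, no georeferencing tags, so `cell_size`
#' must be supplied). Every decoded value must be a scheme code or the
#' scheme's nodata code; unknown codes raise an error naming them.
#'
#' @param path input file.
#' @param scheme a [class_scheme()].
#' @param year calendar year of the map.
#' @param baseline_edge seawall edge, see [landscape_grid()].
#' @param cell_size cell size in metres; for ASCII grids the header value
#'   wins and this argument is checked against it if given.
#' @return a [landscape_grid()].
#' @export
read_grid <- function(path, scheme, year, baseline_edge = "west",
                      cell_size = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (is.null(cell_size))
      stop("'cell_size' is required for TIFF input (no geo-tags)")
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) != 2L)
      stop("expected a single-band TIFF, got ", length(dim(img)), " dims")
    vals <- matrix(as.integer(round(img)), nrow(img), ncol(img))
  } else {
    hd <- read_asc_header(path)
    vals <- matrix(scan(path, what = numeric(), skip = hd$n_header,
                        quiet = TRUE),
                   nrow = hd$nrows, ncol = hd$ncols, byrow = TRUE)
    if (any(vals != round(vals)))
      stop("ASCII grid contains non-integer values")
    if (!is.na(hd$nodata))
      vals[vals == hd$nodata] <- nodata_code(scheme)
    if (!is.null(cell_size) && abs(cell_size - hd$cellsize) > 1e-9)
      stop("cell_size argument (", cell_size, ") disagrees with header (",
           hd$cellsize, ")")
    cell_size <- hd$cellsize
    storage.mode(vals) <- "integer"
  }
  landscape_grid(vals, cell_size = cell_size, year = year,
                 baseline_edge = baseline_edge, scheme = scheme)
}

read_asc_header <- function(path) {
  lines <- readLines(path, n = 8L)
  hd <- list(nodata = NA_real_)
  n <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- tolower(tok[1])
    if (!key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                    "xllcenter", "yllcenter", "cellsize", "nodata_value"))
      break
    n <- n + 1L
    val <- as.numeric(tok[2])
    if (key == "ncols") hd$ncols <- as.integer(val)
    if (key == "nrows") hd$nrows <- as.integer(val)
    if (key == "cellsize") hd$cellsize <- val
    if (key == "nodata_value") hd$nodata <- val
  }
  if (is.null(hd$ncols) || is.null(hd$nrows) || is.null(hd$cellsize))
    stop("malformed ESRI ASCII header in ", path)
  hd$n_header <- n
  hd
}

#' Write a landscape grid to disk
#'
#' @param grid a [landscape_grid()].
#' @param path output file.
#' @param format `"ascii"` (ESRI ASCII grid) or `"tiff"` (plain 8-bit
#'   single-band TIFF; class codes must fit in 0..255). Defaults from the
#'   file extension.
#' @return `path`, invisibly. The file round-trips through [read_grid()]
#'   cell-for-cell.
#' @export
write_grid <- function(grid, path, format = c("auto", "ascii", "tiff")) {
  stopifnot(inherits(grid, "landscape_grid"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) %in% c("tif", "tiff"))
      "tiff" else "ascii"
  if (format == "tiff") {
    v <- grid$values
    if (any(v < 0L) || any(v > 255L))
      stop("TIFF output supports codes 0..255 only")
    tiff::writeTIFF(matrix(v / 255, nrow(v), ncol(v)), path,
                    bits.per.sample = 8L)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    v <- grid$values
    writeLines(c(paste("ncols", ncol(v)),
                 paste("nrows", nrow(v)),
                 "xllcorner 0",
                 "yllcorner 0",
                 paste("cellsize", format(grid$cell_size, scientific = FALSE)),
                 paste("NODATA_value", nodata_code(grid$scheme))),
               con)
    utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
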