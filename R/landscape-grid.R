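#' Construct a dated categorical landscape grid
#'
#' The central container: an integer lattice of class codes with a cell
#' size, an acquisition year, a class scheme, and the edge of the raster
#' that represents the seawall baseline. All zonation distances are
#' measured perpendicular to that edge, increasing seaward, from cell
#' centres: a cell `i` rows from the baseline lies at `(i + 0.5) * cell_size`
#' metres.
#'
#' @param values integer matrix of class codes (row 1 is the top of the
#'   raster).
#' @param cell_size cell edge length in metres (> 0); the default 30 m cell
#'   covers exactly 0.09 ha.
#' @param year integer calendar year the map represents.
#' @param baseline_edge which raster edge is the seawall baseline:
#'   `"west"`, `"east"`, `"north"` or `"south"`.
#' @param scheme a [class_scheme()]; every lattice value must be one of its
#'   codes or the nodata code.
#' @return a `landscape_grid` object.
#' @examples
#' sch <- class_scheme(1:2, c("marsh", "mudflat"), c(TRUE, TRUE))
#' g <- landscape_grid(matrix(1L, 4, 5), cell_size = 30, year = 1985,
#'                     baseline_edge = "north", scheme = sch)
#' class_areas(g)
#' @export
landscape_grid <- function(values, cell_size = 30, year,
                           baseline_edge = c("west", "east", "north", "south"),
                           scheme) {
  baseline_edge <- match.arg(baseline_edge)
  if (!is.matrix(values)) stop("'values' must be a matrix")
  storage.mode(values) <- "integer"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("'cell_size' must be a single positive number")
  if (missing(year) || !is.finite(year))
    stop("'year' is required")
  if (!inherits(scheme, "class_scheme"))
    stop("'scheme' must be a class_scheme")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("grid must have at least one row and one column")
  ok <- c(scheme$code, nodata_code(scheme))
  bad <- setdiff(unique(as.vector(values)), ok)
  if (length(bad))
    stop("grid contains codes not in the class scheme: ",
         paste(sort(bad), collapse = ", "))
  structure(list(values = values, cell_size = as.numeric(cell_size),
                 year = as.integer(year), baseline_edge = baseline_edge,
                 scheme = scheme),
            class = "landscape_grid")
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf("<landscape_grid> %d x %d cells, %g m, year %d, baseline %s\n",
              nrow(x$values), ncol(x$values), x$cell_size, x$year,
              x$baseline_edge))
  tab <- class_areas(x)
  cat("areas (ha):", paste(sprintf("%s=%.2f", names(tab), tab), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
dim.landscape_grid <- function(x) dim(x$values)

# cell area in hectares
cell_area_ha <- function(grid) grid$cell_size^2 / 1e4

# stop unless two grids share shape and cell size
check_same_frame <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)))
    stop("grids differ in shape: ", paste(dim(a$values), collapse = "x"),
         " vs ", paste(dim(b$values), collapse = "x"))
  if (a$cell_size != b$cell_size)
    stop("grids differ in cell size: ", a$cell_size, " vs ", b$cell_size)
  invisible(TRUE)
}

# Rotate the lattice so the baseline edge becomes the top: in the returned
# matrix, row index increases seaward and row r (1-based) is at distance
# (r - 0.5) * cell_size from the baseline.
oriented_values <- function(grid) {
  v <- grid$values
  switch(grid$baseline_edge,
         north = v,
         south = v[rev(seq_len(nrow(v))), , drop = FALSE],
         west  = t(v),
         east  = t(v)[rev(seq_len(ncol(v))), , drop = FALSE])
}

#' Class areas of a landscape grid
#'
#' Counts cells per class and converts to hectares
#' (`cell_size^2 / 10000` ha per cell). Nodata cells are excluded.
#'
#' @param grid a [landscape_grid()].
#' @return named numeric vector of hectares, one entry per scheme class
#'   (zero for absent classes), names = class names.
#' @export
class_areas <- function(grid) {
  stopifnot(inherits(grid, "landscape_grid"))
  sch <- grid$scheme
  counts <- vapply(sch$code, function(cd) sum(grid$values == cd), numeric(1))
  stats::setNames(counts * cell_area_ha(grid), sch$name)
}
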