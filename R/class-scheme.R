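#' Define a landscape class scheme
#'
#' A class scheme lists the categorical classes a landscape raster may
#' contain: an integer code, a human-readable name, and a `dynamic` flag
#' marking classes that take part in Markov transitions and CA allocation
#' (vegetation belts and mudflat), as opposed to frozen classes (water,
#' roads, aquaculture ponds).
#'
#' @param codes integer vector of unique, non-negative class codes.
#' @param names character vector of class names, same length as `codes`.
#' @param dynamic logical vector flagging dynamic classes; at least one
#'   class must be dynamic.
#' @param nodata_code integer nodata sentinel, distinct from all class codes.
#' @return A `class_scheme` object: a data frame with columns `code`,
#'   `name`, `dynamic` and attribute `nodata_code`.
#' @examples
#' sch <- class_scheme(1:3, c("phragmites", "suaeda", "mudflat"),
#'                     dynamic = c(TRUE, TRUE, TRUE))
#' dynamic_codes(sch)
#' @export
class_scheme <- function(codes, names, dynamic, nodata_code = -9999L) {
  codes <- as.integer(codes)
  nodata_code <- as.integer(nodata_code)
  if (anyNA(codes) || any(codes < 0L))
    stop("class codes must be non-negative integers")
  if (anyDuplicated(codes))
    stop("class codes must be unique")
  if (length(names) != length(codes) || length(dynamic) != length(codes))
    stop("'codes', 'names' and 'dynamic' must have equal length")
  if (nodata_code %in% codes)
    stop("nodata_code must not be one of the class codes")
  if (!any(dynamic))
    stop("at least one class must be dynamic")
  out <- data.frame(code = codes, name = as.character(names),
                    dynamic = as.logical(dynamic),
                    stringsAsFactors = FALSE)
  attr(out, "nodata_code") <- nodata_code
  class(out) <- c("class_scheme", "data.frame")
  out
}

#' @export
print.class_scheme <- function(x, ...) {
  cat("<class_scheme> ", nrow(x), " classes, nodata = ",
      nodata_code(x), "\n", sep = "")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Scheme accessors
#'
#' @param scheme a [class_scheme()].
#' @return `dynamic_codes()` / `static_codes()` return integer code vectors;
#'   `nodata_code()` the nodata sentinel.
#' @export
dynamic_codes <- function(scheme) scheme$code[scheme$dynamic]

#' @rdname dynamic_codes
#' @export
static_codes <- function(scheme) scheme$code[!scheme$dynamic]

#' @rdname dynamic_codes
#' @export
nodata_code <- function(scheme) attr(scheme, "nodata_code")

#' Read / write a class scheme as YAML or JSON
#'
#' The file holds a `nodata` scalar and a `classes` list of
#' `{code, name, dynamic}` records; format is chosen by extension
#' (`.yaml`/`.yml` or `.json`).
#'
#' @param path file path.
#' @return `read_class_scheme()` returns a [class_scheme()].
#' @export
read_class_scheme <- function(path) {
  if (!file.exists(path)) stop("scheme file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg_spec <- if (ext == "json") jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
          else yaml::read_yaml(path)
  cl <- cfg_spec$classes
  class_scheme(codes  = vapply(cl, function(x) as.integer(x$code), integer(1)),
               names  = vapply(cl, function(x) as.character(x$name), character(1)),
               dynamic = vapply(cl, function(x) isTRUE(x$dynamic), logical(1)),
               nodata_code = cfg_spec$nodata)
}

#' @rdname read_class_scheme
#' @param scheme a [class_scheme()] to serialize.
#' @export
write_class_scheme <- function(scheme, path) {
  cfg_spec <- list(
    nodata = nodata_code(scheme),
    classes = lapply(seq_len(nrow(scheme)), function(i)
      list(code = scheme$code[i], name = scheme$name[i],
           dynamic = scheme$dynamic[i])))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") jsonlite::write_json(cfg_spec, path, auto_unbox = TRUE, pretty = TRUE)
  else yaml::write_yaml(cfg_spec, path)
  invisible(path)
}

#' The Yancheng coastal wetland class scheme
#'
#' Seven landscape classes of the Yancheng coastal natural wetlands.
#' The three shore-parallel succession belts (P. australis marsh,
#' S. salsa marsh, mudflat) are dynamic; S. alterniflora, water,
#' aquaculture ponds and roads are static. Classes may have zero area in
#' any given year (aquaculture ponds appear only from 2000).
#'
#' @return a [class_scheme()].
#' @export
yancheng_scheme <- function() {
  class_scheme(
    codes = 1:7,
    names = c("phragmites", "suaeda", "spartina", "mudflat",
              "water", "pond", "road"),
    dynamic = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
    nodata_code = 0L)
}
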