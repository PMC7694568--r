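#' Cross-tabulate two landscape maps
#'
#' Agreement between a reference and a comparison map on the same frame:
#' K x K confusion matrix (reference in rows, comparison in columns, over
#' all scheme classes), overall accuracy (trace / total), Cohen's kappa
#' `(p_o - p_e) / (1 - p_e)` with `p_e` from the row/column marginals, and
#' the confusion counts converted to hectares. Cells where either map is
#' nodata are excluded.
#'
#' In the degenerate case `p_e = 1` (both maps constant), kappa is defined
#' as 1 when the maps agree and 0 otherwise, with a warning.
#'
#' @param reference,comparison [landscape_grid()]s sharing shape, cell
#'   size and scheme codes.
#' @return an `agreement_report`: list with `confusion`,
#'   `overall_accuracy`, `kappa`, `transition_areas` (hectares), `n_cells`.
#' @examples
#' sch <- class_scheme(1:2, c("a", "b"), c(TRUE, TRUE))
#' g <- landscape_grid(matrix(1:2, 4, 4), 30, 2000, "north", sch)
#' cross_tabulate(g, g)$kappa  # 1
#' @export
cross_tabulate <- function(reference, comparison) {
  stopifnot(inherits(reference, "landscape_grid"),
            inherits(comparison, "landscape_grid"))
  check_same_frame(reference, comparison)
  codes <- reference$scheme$code
  if (!setequal(codes, comparison$scheme$code))
    stop("schemes differ between maps")
  a <- as.vector(reference$values)
  b <- as.vector(comparison$values)
  keep <- a != nodata_code(reference$scheme) &
          b != nodata_code(comparison$scheme)
  n <- sum(keep)
  if (n == 0L) stop("no jointly valid (non-nodata) cells")
  conf <- table(factor(a[keep], levels = codes),
                factor(b[keep], levels = codes))
  conf <- matrix(as.numeric(conf), length(codes), length(codes),
                 dimnames = list(reference = reference$scheme$name,
                                 comparison = reference$scheme$name))
  p_o <- sum(diag(conf)) / n
  p_e <- sum(rowSums(conf) * colSums(conf)) / n^2
  if (1 - p_e < 1e-12) {
    warning("degenerate marginals (p_e = 1); kappa set by convention")
    kappa <- if (p_o >= 1 - 1e-12) 1 else 0
  } else {
    kappa <- (p_o - p_e) / (1 - p_e)
  }
  structure(list(confusion = conf,
                 overall_accuracy = p_o,
                 kappa = kappa,
                 transition_areas = conf * cell_area_ha(reference),
                 n_cells = n),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d cells, accuracy = %.4f, kappa = %.4f\n",
              x$n_cells, x$overall_accuracy, x$kappa))
  invisible(x)
}

#' Transition areas between two dated maps
#'
#' Hectares moving from class i (earlier map, rows) to class j (later map,
#' columns); the diagonal is persistence. Row sums equal [class_areas()]
#' of the earlier map and column sums those of the later map (restricted
#' to jointly valid cells).
#'
#' @param observed_a,observed_b [landscape_grid()]s on the same frame.
#' @return K x K numeric matrix of hectares.
#' @export
transition_matrix_between <- function(observed_a, observed_b) {
  cross_tabulate(observed_a, observed_b)$transition_areas
}

#' Write an agreement report to disk
#'
#' Confusion counts and transition areas as CSV, plus a JSON summary
#' `{accuracy, kappa, n_cells}`. Reference map = rows in both CSVs.
#'
#' @param report an `agreement_report`.
#' @param prefix path prefix; writes `<prefix>_confusion.csv`,
#'   `<prefix>_transition_areas_ha.csv`, `<prefix>_summary.json`.
#' @export
write_agreement_report <- function(report, prefix) {
  utils::write.csv(report$confusion, paste0(prefix, "_confusion.csv"))
  utils::write.csv(report$transition_areas,
                   paste0(prefix, "_transition_areas_ha.csv"))
  jsonlite::write_json(list(accuracy = report$overall_accuracy,
                            kappa = report$kappa,
                            n_cells = report$n_cells),
                       paste0(prefix, "_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
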