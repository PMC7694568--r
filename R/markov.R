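#' Construct a class-transition probability matrix
#'
#' A row-stochastic K x K matrix `P[i, j]` of probabilities that a cell of
#' class `i` becomes class `j` after `step_years` years. Published matrices
#' often carry printing round-off (a row summing to 0.9999); rows off by at
#' most `renorm_tol` are renormalized with a warning, larger deviations are
#' an error.
#'
#' @param probs numeric K x K matrix; entries in `[0, 1]`.
#' @param step_years positive time step in years.
#' @param class_codes integer codes of the K dynamic classes, in row/column
#'   order.
#' @param renorm_tol maximum tolerated row-sum deviation that is silently
#'   fixable by renormalization (default 0.01).
#' @return a `transition_matrix` object (matrix with attributes
#'   `step_years` and `class_codes`).
#' @export
transition_matrix <- function(probs, step_years = 1, class_codes,
                              renorm_tol = 0.01) {
  probs <- as.matrix(probs)
  k <- nrow(probs)
  if (ncol(probs) != k) stop("'probs' must be square")
  if (missing(class_codes)) class_codes <- seq_len(k)
  class_codes <- as.integer(class_codes)
  if (length(class_codes) != k) stop("'class_codes' must have length ", k)
  if (any(probs < -1e-12) || any(probs > 1 + 1e-12))
    stop("transition probabilities must lie in [0, 1]")
  probs[probs < 0] <- 0
  probs[probs > 1] <- 1
  if (!is.numeric(step_years) || step_years <= 0)
    stop("'step_years' must be positive")
  rs <- rowSums(probs)
  off <- abs(rs - 1)
  if (any(off > renorm_tol))
    stop("row sums deviate from 1 by more than ", renorm_tol, ": ",
         paste(format(rs[off > renorm_tol]), collapse = ", "))
  if (any(off > 1e-9)) {
    warning("renormalizing ", sum(off > 1e-9),
            " row(s) with sums off by up to ", format(max(off)))
    probs <- probs / rs
  }
  dimnames(probs) <- list(class_codes, class_codes)
  structure(probs, step_years = as.numeric(step_years),
            class_codes = class_codes,
            class = c("transition_matrix", "matrix", "array"))
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d classes, step %g yr\n",
              nrow(x), attr(x, "step_years")))
  print(unclass_tm(x))
  invisible(x)
}

unclass_tm <- function(m) {
  attr(m, "step_years") <- NULL
  attr(m, "class_codes") <- NULL
  attr(m, "residual") <- NULL
  class(m) <- NULL
  m
}

#' Estimate a transition matrix from a dated pair of maps
#'
#' `P[i, j]` is the fraction of cells that are class `i` at the earlier
#' date and class `j` at the later date, counted over cells whose class is
#' dynamic at both dates. A class with no source cells gets an identity
#' row, so the matrix is always exactly row-stochastic.
#'
#' @param grid_a,grid_b [landscape_grid()]s sharing shape and cell size,
#'   with `grid_b$year > grid_a$year`.
#' @param dynamic_codes codes of the transitioning classes; defaults to the
#'   scheme's dynamic classes.
#' @return a [transition_matrix()] with `step_years = grid_b$year - grid_a$year`.
#' @export
estimate_transitions <- function(grid_a, grid_b,
                                 dynamic_codes = NULL) {
  check_same_frame(grid_a, grid_b)
  if (grid_b$year <= grid_a$year)
    stop("grid_b must be later than grid_a")
  if (is.null(dynamic_codes)) dynamic_codes <- dynamic_codes(grid_a$scheme)
  dynamic_codes <- as.integer(dynamic_codes)
  k <- length(dynamic_codes)
  a <- as.vector(grid_a$values)
  b <- as.vector(grid_b$values)
  keep <- a %in% dynamic_codes & b %in% dynamic_codes
  if (!any(keep)) stop("no cells are dynamic at both dates")
  fa <- factor(a[keep], levels = dynamic_codes)
  fb <- factor(b[keep], levels = dynamic_codes)
  counts <- table(fa, fb)
  probs <- matrix(0, k, k)
  n_src <- rowSums(counts)
  for (i in seq_len(k)) {
    if (n_src[i] > 0) probs[i, ] <- counts[i, ] / n_src[i]
    else probs[i, i] <- 1
  }
  m <- transition_matrix(probs, step_years = grid_b$year - grid_a$year,
                         class_codes = dynamic_codes)
  attr(m, "source_counts") <- as.vector(n_src)
  m
}

#' Convert a transition matrix to a shorter time step
#'
#' Computes the k-th matrix root by eigendecomposition, where
#' `k = step_years / target_step` must be a positive integer. Negative
#' entries of the real root are clipped to zero and rows renormalized; the
#' Frobenius reconstruction residual `||A^k - P||_F` is attached as
#' attribute `"residual"` (zero when the root is exactly embeddable).
#'
#' @param matrix a [transition_matrix()].
#' @param target_step desired step in years (divides `step_years`).
#' @param imag_tol maximum tolerated imaginary magnitude in the root
#'   before erroring (default 1e-6).
#' @return an annualized [transition_matrix()] with attribute `"residual"`.
#' @export
annualize <- function(matrix, target_step = 1, imag_tol = 1e-6) {
  stopifnot(inherits(matrix, "transition_matrix"))
  s <- attr(matrix, "step_years")
  k <- s / target_step
  if (abs(k - round(k)) > 1e-9 || k < 1)
    stop("step_years / target_step must be a positive integer, got ", k)
  k <- as.integer(round(k))
  P <- unclass_tm(matrix)
  if (k == 1L) {
    out <- transition_matrix(P, step_years = target_step,
                             class_codes = attr(matrix, "class_codes"))
    attr(out, "residual") <- 0
    return(out)
  }
  e <- eigen(P)
  v_inv <- tryCatch(solve(e$vectors), error = function(err)
    stop("matrix is not diagonalizable within tolerance"))
  root_vals <- as.complex(e$values)^(1 / k)
  A <- e$vectors %*% diag(root_vals, nrow(P)) %*% v_inv
  if (max(abs(Im(A))) > imag_tol)
    stop("matrix root has imaginary magnitude ", format(max(abs(Im(A)))),
         " above tolerance ", imag_tol)
  A <- Re(A)
  A[A < 0] <- 0
  A <- A / rowSums(A)
  out <- transition_matrix(A, step_years = target_step,
                           class_codes = attr(matrix, "class_codes"))
  Ak <- matrix_power(unclass_tm(out), k)
  attr(out, "residual") <- sqrt(sum((Ak - P)^2))
  out
}

matrix_power <- function(m, k) {
  out <- diag(nrow(m))
  for (i in seq_len(k)) out <- out %*% m
  out
}

#' Project class areas forward under a Markov chain
#'
#' Applies `a <- a %*% P` for `n_steps` steps. Total area is conserved
#' because `P` is row-stochastic.
#'
#' @param areas named numeric vector of areas (hectares), names = class
#'   codes of `matrix` (order-insensitive).
#' @param matrix a [transition_matrix()].
#' @param n_steps non-negative integer number of steps.
#' @return named numeric vector of projected areas in the matrix's class
#'   order.
#' @export
project_areas <- function(areas, matrix, n_steps = 1) {
  stopifnot(inherits(matrix, "transition_matrix"))
  codes <- as.character(attr(matrix, "class_codes"))
  if (!setequal(names(areas), codes))
    stop("area names must match matrix class codes: ",
         paste(codes, collapse = ", "))
  if (any(areas < 0)) stop("areas must be non-negative")
  if (n_steps < 0 || n_steps != round(n_steps))
    stop("'n_steps' must be a non-negative integer")
  a <- as.numeric(areas[codes])
  P <- unclass_tm(matrix)
  P <- P / rowSums(P)
  for (i in seq_len(n_steps)) a <- as.vector(a %*% P)
  stats::setNames(a, codes)
}

#' Read / write a transition matrix as CSV
#'
#' CSV layout: header row and first column carry the class codes (or
#' names); cells hold probabilities. `step_years` is not stored in the CSV
#' and must be supplied on read.
#'
#' @param path CSV file.
#' @param step_years time step of the stored matrix.
#' @param class_codes optional integer codes overriding the CSV labels.
#' @return `read_transition_matrix()` returns a [transition_matrix()].
#' @export
read_transition_matrix <- function(path, step_years = 1, class_codes = NULL) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (is.null(class_codes)) {
    class_codes <- suppressWarnings(as.integer(rownames(m)))
    if (anyNA(class_codes)) class_codes <- seq_len(nrow(m))
  }
  transition_matrix(m, step_years = step_years, class_codes = class_codes)
}

#' @rdname read_transition_matrix
#' @param matrix a [transition_matrix()] to serialize.
#' @param labels optional row/column labels (default the class codes).
#' @export
write_transition_matrix <- function(matrix, path, labels = NULL) {
  m <- unclass_tm(matrix)
  if (is.null(labels)) labels <- as.character(attr(matrix, "class_codes"))
  dimnames(m) <- list(labels, labels)
  utils::write.csv(m, path)
  invisible(path)
}
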