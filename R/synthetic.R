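#' Configuration for the synthetic banded-landscape generator
#'
#' Emulates the shore-parallel zonation of a silty coastal wetland:
#' ordered land-to-sea belts of P. australis marsh, S. salsa marsh and
#' mudflat, with an optional invader (S. alterniflora) strip wedged
#' between S. salsa and the mudflat, ragged per-column belt boundaries,
#' and annual per-cell class transitions drawn from a known stochastic
#' matrix mixed with neighbourhood contagion.
#'
#' Defaults mirror the observed 1985 composition of the Yancheng study
#' frame (P. australis 21%, S. salsa 16%, mudflat 60% of the area) on
#' 30 m cells.
#'
#' @param rows,cols lattice size.
#' @param cell_size cell edge in metres (default 30).
#' @param band_fractions ordered land-to-sea depth fractions of the grid
#'   for (phragmites, suaeda, mudflat); positive, sum <= 1. Any remainder
#'   becomes a static water belt at the seaward edge.
#' @param invader_width width of the S. alterniflora strip in cells
#'   (0 = absent), carved out of the landward edge of the mudflat belt.
#' @param boundary_roughness standard deviation, in cells, of the
#'   per-column boundary jitter (a clipped Gaussian random walk along
#'   columns; 0 = straight belts).
#' @param transition_matrix a [transition_matrix()] (1-year step)
#'   governing annual transitions of the dynamic classes in [evolve()].
#' @param contagion_weight mixing weight w in `[0, 1]`: per-cell
#'   transition probabilities are `(1 - w) * P[current, ] + w * local
#'   class frequencies` (3 x 3 neighbourhood). `w = 0` is the exact
#'   cell-independent Markov chain.
#' @param seed integer RNG seed; all outputs are deterministic per seed.
#' @param scheme class scheme (default [yancheng_scheme()]).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(rows = 200, cols = 200, cell_size = 30,
                             band_fractions = c(phragmites = 0.21,
                                                suaeda = 0.16,
                                                mudflat = 0.60),
                             invader_width = 0L,
                             boundary_roughness = 2,
                             transition_matrix = yancheng_transition_matrix(),
                             contagion_weight = 0.25,
                             seed = 1L,
                             scheme = yancheng_scheme()) {
  if (length(band_fractions) != 3L || any(band_fractions <= 0))
    stop("'band_fractions' must be 3 positive land-to-sea fractions")
  if (sum(band_fractions) > 1 + 1e-9)
    stop("'band_fractions' must sum to at most 1")
  if (boundary_roughness < 0) stop("'boundary_roughness' must be >= 0")
  if (contagion_weight < 0 || contagion_weight > 1)
    stop("'contagion_weight' must lie in [0, 1]")
  if (invader_width < 0) stop("'invader_width' must be >= 0")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 cell_size = cell_size,
                 band_fractions = band_fractions,
                 invader_width = as.integer(invader_width),
                 boundary_roughness = boundary_roughness,
                 transition_matrix = transition_matrix,
                 contagion_weight = contagion_weight,
                 seed = as.integer(seed),
                 scheme = scheme),
            class = "synthetic_config")
}

#' The published 1-year Yancheng transition matrix
#'
#' Annual transition probabilities among the three dynamic belts
#' (S. salsa, P. australis, mudflat) of the Yancheng coastal wetlands,
#' estimated from the 1985/1990 map pair. Shipped as a CSV in
#' `inst/extdata`; the mudflat row prints as 0.9999 and is renormalized
#' on load.
#'
#' @param step_years step of the stored matrix (1 year).
#' @return a [transition_matrix()] over codes (suaeda = 2,
#'   phragmites = 1, mudflat = 4) in the order suaeda, phragmites,
#'   mudflat.
#' @export
yancheng_transition_matrix <- function(step_years = 1) {
  path <- system.file("extdata", "yancheng_transition_1yr.csv",
                      package = "camarsh", mustWork = TRUE)
  suppressWarnings(
    read_transition_matrix(path, step_years = step_years,
                           class_codes = c(2L, 1L, 4L)))
}

# Jittered boundary depths (in rows) for each of the `n_bounds` internal
# belt boundaries, one value per column; ordering preserved.
banded_boundaries <- function(base_rows, cols, roughness, max_row) {
  n_b <- length(base_rows)
  jit <- matrix(0, n_b, cols)
  if (roughness > 0 && cols > 1) {
    for (b in seq_len(n_b)) {
      walk <- cumsum(stats::rnorm(cols))
      walk <- walk - mean(walk)
      s <- stats::sd(walk)
      if (s > 0) walk <- walk * roughness / s
      jit[b, ] <- walk
    }
  }
  bounds <- round(sweep(jit, 1, base_rows, "+"))
  # clip to the grid and restore strict ordering down each column
  bounds <- pmin(pmax(bounds, 0L), max_row)
  if (n_b > 1)
    for (b in 2:n_b) bounds[b, ] <- pmax(bounds[b, ], bounds[b - 1, ])
  bounds
}

#' Generate a banded coastal landscape
#'
#' Shore-parallel belts in land-to-sea order phragmites, suaeda,
#' (optional spartina strip), mudflat, with the seawall baseline at the
#' grid's north edge and any depth beyond the stated band fractions
#' filled with static water. Belt boundaries are jittered per column by a
#' seeded clipped Gaussian random walk; belt ordering is never inverted.
#'
#' @param config a [synthetic_config()].
#' @param year calendar year stamped on the map.
#' @return a [landscape_grid()] with `baseline_edge = "north"`.
#' @export
make_banded_grid <- function(config, year = 1985) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  sch <- config$scheme
  code <- stats::setNames(sch$code, sch$name)
  nr <- config$rows; nc <- config$cols
  depth <- round(cumsum(config$band_fractions) * nr)
  if (config$invader_width > 0 && depth[2] + config$invader_width > depth[3])
    stop("invader strip does not fit inside the mudflat belt")
  base_rows <- c(depth[1], depth[2],
                 if (config$invader_width > 0) depth[2] + config$invader_width,
                 depth[3])
  bounds <- banded_boundaries(base_rows, nc, config$boundary_roughness, nr)
  band_codes <- c(code[["phragmites"]], code[["suaeda"]],
                  if (config$invader_width > 0) code[["spartina"]],
                  code[["mudflat"]], code[["water"]])
  v <- matrix(code[["water"]], nr, nc)
  rows_idx <- seq_len(nr)
  for (j in seq_len(nc)) {
    upper <- c(0L, bounds[, j])
    lower <- c(bounds[, j], nr)
    for (b in seq_along(band_codes)) {
      if (lower[b] > upper[b])
        v[rows_idx > upper[b] & rows_idx <= lower[b], j] <- band_codes[b]
    }
  }
  landscape_grid(v, cell_size = config$cell_size, year = year,
                 baseline_edge = "north", scheme = sch)
}

#' Forward-simulate annual succession with known dynamics
#'
#' The ground-truth stochastic process behind the synthetic landscapes:
#' each year, every dynamic cell transitions to class j with probability
#' `(1 - w) * P[current, j] + w * f_j`, where `f_j` is the frequency of j
#' among dynamic cells in the 3 x 3 neighbourhood and `w` the contagion
#' weight. Static and nodata cells are frozen. With `w = 0` this is
#' exactly the cell-independent Markov chain of `P`, so
#' [estimate_transitions()] on consecutive outputs recovers `P`.
#'
#' @param grid starting [landscape_grid()].
#' @param config a [synthetic_config()] (supplies the matrix, contagion
#'   weight and seed).
#' @param n_years number of annual steps.
#' @return list of [landscape_grid()]s for years `year + 1 ... year + n_years`.
#' @export
evolve <- function(grid, config, n_years) {
  stopifnot(inherits(grid, "landscape_grid"),
            inherits(config, "synthetic_config"))
  P <- config$transition_matrix
  codes <- attr(P, "class_codes")
  Pm <- unclass_tm(P)
  Pm <- Pm / rowSums(Pm)
  w <- config$contagion_weight
  set.seed(config$seed)
  out <- vector("list", n_years)
  v <- grid$values
  k <- length(codes)
  for (t in seq_len(n_years)) {
    dyn <- array(v %in% codes, dim = dim(v))
    idx <- which(dyn)
    probs <- Pm[match(v[idx], codes), , drop = FALSE]
    if (w > 0) {
      n_dyn <- box_sum(dyn + 0, 1L)
      freq <- vapply(seq_len(k), function(j) {
        f <- box_sum((v == codes[j]) + 0, 1L)
        ifelse(n_dyn > 0, f / n_dyn, 0)[idx]
      }, numeric(length(idx)))
      freq <- matrix(freq, length(idx), k)
      has_nb <- rowSums(freq) > 0
      probs[has_nb, ] <- (1 - w) * probs[has_nb, , drop = FALSE] +
        w * freq[has_nb, , drop = FALSE]
    }
    # vectorized categorical draw per cell
    cum <- probs %*% upper.tri(diag(k), diag = TRUE)
    u <- stats::runif(length(idx))
    pick <- rowSums(u > cum) + 1L
    pick[pick > k] <- k
    v[idx] <- codes[pick]
    g <- grid
    g$values <- v
    g$year <- grid$year + t
    out[[t]] <- g
  }
  names(out) <- vapply(out, function(x) as.character(x$year), character(1))
  out
}
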