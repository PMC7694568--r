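#' CA-Markov simulation parameters
#'
#' @param step_years simulation time step (years; the transition matrix
#'   must have the same step).
#' @param filter_size odd window edge (>= 3) of the contiguity filter used
#'   to score neighbourhood suitability; default 5 (a 5 x 5 window).
#' @param n_iterations allocation rounds per step (default 20): each
#'   step's class demands are claimed over this many interleaved rounds.
#' @param seed integer RNG seed controlling allocation tie-breaks; equal
#'   seeds give cell-identical simulations.
#' @param dynamic_codes,static_codes optional code sets; default from the
#'   grid scheme at run time. Must be disjoint.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(step_years = 1, filter_size = 5,
                              n_iterations = 20, seed = 1L,
                              dynamic_codes = NULL, static_codes = NULL) {
  if (filter_size < 3 || filter_size %% 2 == 0)
    stop("'filter_size' must be an odd integer >= 3")
  if (n_iterations < 1) stop("'n_iterations' must be positive")
  if (!is.null(dynamic_codes) && !is.null(static_codes) &&
      length(intersect(dynamic_codes, static_codes)))
    stop("dynamic and static code sets must be disjoint")
  structure(list(step_years = step_years,
                 filter_size = as.integer(filter_size),
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed),
                 dynamic_codes = dynamic_codes,
                 static_codes = static_codes),
            class = "simulation_config")
}

# Box-filter count via a summed-area table; window truncated at edges.
box_sum <- function(m, half) {
  nr <- nrow(m); nc <- ncol(m)
  cs <- if (nr > 1L) apply(m, 2L, cumsum) else m
  cs <- matrix(cs, nr, nc)
  if (nc > 1L) cs <- t(apply(cs, 1L, cumsum))
  cs <- matrix(cs, nr, nc)
  sat <- matrix(0, nr + 1L, nc + 1L)
  sat[-1L, -1L] <- cs
  r1 <- pmax(seq_len(nr) - half, 1L); r2 <- pmin(seq_len(nr) + half, nr)
  c1 <- pmax(seq_len(nc) - half, 1L); c2 <- pmin(seq_len(nc) + half, nc)
  sat[r2 + 1L, c2 + 1L, drop = FALSE] - sat[r1, c2 + 1L, drop = FALSE] -
    sat[r2 + 1L, c1, drop = FALSE] + sat[r1, c1, drop = FALSE]
}

#' Neighbourhood suitability stack
#'
#' For every dynamic class `c`, the suitability of a cell is the fraction
#' of `c` among the dynamic cells in the centred
#' `filter_size x filter_size` window (truncated at edges), multiplied by
#' the Markov probability of moving from the cell's current class to `c`.
#' Static and nodata cells get suitability 0 for all classes.
#'
#' @param grid a [landscape_grid()].
#' @param matrix a [transition_matrix()] over the dynamic classes.
#' @param config a [simulation_config()].
#' @return named list (by class code) of suitability matrices in `[0, 1]`.
#' @export
neighborhood_suitability <- function(grid, matrix, config = simulation_config()) {
  stopifnot(inherits(grid, "landscape_grid"),
            inherits(matrix, "transition_matrix"))
  codes <- attr(matrix, "class_codes")
  half <- (config$filter_size - 1L) %/% 2L
  v <- grid$values
  dyn <- array(v %in% codes, dim = dim(v))
  n_dyn <- box_sum(dyn + 0, half)
  P <- unclass_tm(matrix)
  P <- P / rowSums(P)
  # map current class -> row of P (NA for static/nodata)
  row_of <- match(v, codes)
  out <- vector("list", length(codes))
  names(out) <- as.character(codes)
  for (j in seq_along(codes)) {
    frac <- box_sum((v == codes[j]) + 0, half)
    frac <- ifelse(n_dyn > 0, frac / n_dyn, 0)
    pj <- P[, j][row_of]          # P[current -> codes[j]] per cell
    s <- frac * array(pj, dim = dim(v))
    s[!dyn] <- 0
    out[[j]] <- s
  }
  out
}

# Largest-remainder apportionment of fractional demands to whole cells.
largest_remainder <- function(x, total = round(sum(x))) {
  fl <- floor(x)
  short <- as.integer(total - sum(fl))
  if (short > 0) {
    give <- order(x - fl, decreasing = TRUE)[seq_len(short)]
    fl[give] <- fl[give] + 1
  } else if (short < 0) {
    take <- order(x - fl)[seq_len(-short)]
    fl[take] <- fl[take] - 1
  }
  as.integer(fl)
}

# Integerize a real-valued transition-count table so that row sums equal
# `row_tot` and column sums equal `col_tot` exactly (both integer, same
# total). Floors plus per-row largest-remainder top-up, then unit moves
# within rows to repair the column sums; each move shrinks the column
# imbalance, so the loop terminates.
round_transport <- function(T, row_tot, col_tot) {
  k <- nrow(T)
  F <- floor(T)
  for (i in seq_len(k)) {
    need <- row_tot[i] - sum(F[i, ])
    if (need > 0) {
      give <- order(T[i, ] - F[i, ], decreasing = TRUE)[seq_len(need)]
      F[i, give] <- F[i, give] + 1
    }
  }
  repeat {
    excess <- colSums(F) - col_tot
    if (all(excess == 0)) break
    j_over <- which.max(excess)
    j_under <- which.min(excess)
    cand <- which(F[, j_over] > 0)
    i <- cand[which.max(T[cand, j_under] - F[cand, j_under])]
    F[i, j_over] <- F[i, j_over] - 1
    F[i, j_under] <- F[i, j_under] + 1
  }
  storage.mode(F) <- "integer"
  F
}

# Core of one CA-Markov step; assumes the RNG state is already seeded.
#
# Allocation is demand-constrained greedy claiming at the transition
# level: whole-cell quotas T[i, j] (source class i -> class j, consistent
# with both the source counts and the largest-remainder Markov demands)
# are claimed over n_iterations interleaved rounds. Each round every
# transition, in seeded random order, claims its per-round share from the
# still-unassigned cells of class i where class j's neighbourhood
# suitability is highest, ties broken by a seeded uniform key. Claiming
# per transition lets conversions pick the band edge facing the invading
# class while persistence retains the band core, which is what moves the
# belts coherently.
ca_step_core <- function(grid, matrix, config) {
  codes <- attr(matrix, "class_codes")
  k <- length(codes)
  v <- grid$values
  dyn_idx <- which(v %in% codes)
  if (!length(dyn_idx)) stop("no dynamic cells in grid")
  P <- unclass_tm(matrix)
  P <- P / rowSums(P)

  counts <- vapply(codes, function(cd) sum(v[dyn_idx] == cd), integer(1),
                   USE.NAMES = FALSE)
  demand_frac <- as.vector(counts %*% P)
  demand <- largest_remainder(demand_frac, total = length(dyn_idx))
  stopifnot(sum(demand) == length(dyn_idx))
  Tq <- round_transport(counts * P, counts, demand)

  suit <- neighborhood_suitability(grid, matrix, config)
  S <- vapply(suit, function(s) s[dyn_idx], numeric(length(dyn_idx)))
  S <- base::matrix(S, nrow = length(dyn_idx), ncol = k)
  src <- match(v[dyn_idx], codes)

  tie <- stats::runif(length(dyn_idx))
  assigned <- integer(length(dyn_idx))
  remaining <- Tq
  trans <- which(Tq > 0, arr.ind = TRUE)
  for (round_i in seq_len(config$n_iterations)) {
    rounds_left <- config$n_iterations - round_i + 1L
    for (t in sample.int(nrow(trans))) {
      i <- trans[t, 1L]; j <- trans[t, 2L]
      if (remaining[i, j] <= 0L) next
      quota <- min(remaining[i, j], ceiling(remaining[i, j] / rounds_left))
      un <- which(assigned == 0L & src == i)
      if (!length(un)) next
      pick <- un[order(-S[un, j], tie[un])][seq_len(min(quota, length(un)))]
      assigned[pick] <- j
      remaining[i, j] <- remaining[i, j] - length(pick)
    }
  }
  stopifnot(all(assigned > 0L), all(remaining == 0L))

  v_new <- v
  v_new[dyn_idx] <- codes[assigned]
  out <- grid
  out$values <- v_new
  out$year <- grid$year + as.integer(round(config$step_years))
  attr(out, "demand") <- stats::setNames(demand, codes)
  out
}

#' Advance a landscape one CA-Markov step
#'
#' One step: (i) per-class cell demands come from the Markov projection of
#' current class counts, rounded to whole cells by largest-remainder
#' apportionment; (ii) whole-cell transition quotas consistent with both
#' the source counts and those demands are allocated over `n_iterations`
#' interleaved rounds — each round every transition (in seeded random
#' order) claims its per-round share from the still-unassigned source
#' cells where the destination class is most suitable, ties broken by a
#' seeded uniform key; (iii) static and nodata cells are copied
#' unchanged. Output class cell counts equal the demands exactly
#' (attached as attribute `"demand"`).
#'
#' @param grid a [landscape_grid()].
#' @param matrix a [transition_matrix()] whose step matches
#'   `config$step_years`.
#' @param config a [simulation_config()].
#' @return the advanced [landscape_grid()], dated `year + step_years`.
#' @export
ca_step <- function(grid, matrix, config = simulation_config()) {
  stopifnot(inherits(grid, "landscape_grid"),
            inherits(matrix, "transition_matrix"))
  if (abs(attr(matrix, "step_years") - config$step_years) > 1e-9)
    stop("matrix step (", attr(matrix, "step_years"),
         " yr) does not match config step (", config$step_years,
         " yr); annualize first")
  set.seed(config$seed)
  ca_step_core(grid, matrix, config)
}

#' Run a multi-year CA-Markov simulation
#'
#' Applies [ca_step()] `n_years / step_years` times, reseeding once at the
#' start so identical seeds give identical runs.
#'
#' @inheritParams ca_step
#' @param n_years total simulated span in years (>= 1).
#' @return list of [landscape_grid()]s dated `year + step`, `year + 2*step`,
#'   ..., named by year.
#' @export
ca_run <- function(grid, matrix, config = simulation_config(), n_years) {
  if (n_years < 1) stop("'n_years' must be >= 1")
  n_steps <- as.integer(round(n_years / config$step_years))
  set.seed(config$seed)
  out <- vector("list", n_steps)
  g <- grid
  for (i in seq_len(n_steps)) {
    g <- ca_step_core(g, matrix, config)
    out[[i]] <- g
  }
  names(out) <- vapply(out, function(x) as.character(x$year), character(1))
  out
}
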