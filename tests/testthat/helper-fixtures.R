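# Shared fixtures and independent brute-force oracles.

# A minimal all-dynamic scheme with k classes coded 1..k.
toy_scheme <- function(k = 3) {
  class_scheme(seq_len(k), paste0("c", seq_len(k)), rep(TRUE, k))
}

# Random categorical grid over the given codes.
rand_grid <- function(nr, nc, codes, scheme, year = 2000, seed = 1,
                      cell_size = 30, baseline_edge = "north") {
  set.seed(seed)
  landscape_grid(matrix(sample(codes, nr * nc, replace = TRUE), nr, nc),
                 cell_size = cell_size, year = year,
                 baseline_edge = baseline_edge, scheme = scheme)
}

# Random row-stochastic matrix with a dominant diagonal (eigenvalues near
# the positive real axis, so principal matrix roots are well behaved).
rand_stochastic <- function(k, diag_weight = 0.7) {
  m <- matrix(stats::runif(k * k), k, k)
  m <- m / rowSums(m) * (1 - diag_weight)
  diag(m) <- diag(m) + diag_weight
  m / rowSums(m)
}

# Naive double-loop suitability oracle: fraction of class `code` among
# dynamic cells in the truncated window, times P[current -> code].
naive_suitability <- function(grid, P, codes, code, filter_size) {
  half <- (filter_size - 1) %/% 2
  v <- grid$values
  out <- matrix(0, nrow(v), ncol(v))
  j_col <- match(code, codes)
  for (r in seq_len(nrow(v))) for (c in seq_len(ncol(v))) {
    cur <- match(v[r, c], codes)
    if (is.na(cur)) next
    rs <- max(1, r - half):min(nrow(v), r + half)
    cs <- max(1, c - half):min(ncol(v), c + half)
    win <- v[rs, cs]
    n_dyn <- sum(win %in% codes)
    if (n_dyn > 0)
      out[r, c] <- sum(win == code) / n_dyn * P[cur, j_col]
  }
  out
}

# Naive per-column boundary scan implementing L = S / D directly.
naive_profile <- function(grid, code) {
  v <- grid$values  # fixtures use baseline_edge = "north": rows = distance
  cs <- grid$cell_size
  near <- c(); far <- c()
  for (j in seq_len(ncol(v))) {
    rows <- which(v[, j] == code)
    if (length(rows)) {
      near <- c(near, (min(rows) - 0.5) * cs)
      far <- c(far, (max(rows) - 0.5) * cs)
    }
  }
  D <- length(near) * cs
  list(L_near = sum(near * cs) / D, L_far = sum(far * cs) / D,
       D = D, S_near = sum(near * cs), S_far = sum(far * cs))
}

# Independent largest-remainder apportionment.
naive_apportion <- function(x, total) {
  base <- floor(x)
  rem <- x - base
  need <- total - sum(base)
  if (need > 0) {
    extra <- order(rem, decreasing = TRUE)[seq_len(need)]
    base[extra] <- base[extra] + 1
  }
  base
}

# Grid pair realizing a given 2x2 confusion matrix (classes 1, 2).
grids_from_confusion <- function(conf, scheme = toy_scheme(2)) {
  ref <- rep(c(1L, 1L, 2L, 2L), times = as.vector(t(conf)))
  cmp <- rep(c(1L, 2L, 1L, 2L), times = as.vector(t(conf)))
  n <- length(ref)
  list(ref = landscape_grid(matrix(ref, 1, n), 30, 2000, "north", scheme),
       cmp = landscape_grid(matrix(cmp, 1, n), 30, 2001, "north", scheme))
}

# Published Yancheng inputs shipped with the package.
yancheng_areas <- function() {
  utils::read.csv(system.file("extdata", "yancheng_landscape_areas_ha.csv",
                              package = "camarsh"), check.names = FALSE)
}

yancheng_centroids <- function() {
  utils::read.csv(system.file("extdata", "yancheng_centroid_distances_m.csv",
                              package = "camarsh"))
}

yancheng_stats <- function() {
  df <- utils::read.csv(system.file("extdata", "yancheng_summary_stats.csv",
                                    package = "camarsh"))
  stats::setNames(df$value, df$key)
}
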