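#' Baseline-referenced zonation profile of one class
#'
#' Implements the mean-boundary-distance statistic L = S / D for a
#' shore-parallel vegetation belt. For every baseline-parallel column that
#' contains the class, the nearest and farthest class-cell centres define
#' per-column boundary distances from the seawall baseline; D is the
#' projected length of the boundary on the baseline (number of occupied
#' columns x cell size), S the enclosed area (sum of per-column boundary
#' distance x cell size), and L = S / D — i.e. the mean per-column
#' boundary standoff. The centroid distance is the area-weighted mean
#' perpendicular distance over all class cells (a 1-D centroid).
#'
#' @param grid a [landscape_grid()].
#' @param class_code code of the class to profile; must be present.
#' @return a `zonation_profile`: list with `class_code`, `year`,
#'   `mean_distance_nearest` (L_near, m), `mean_distance_farthest` (L_far,
#'   m), `centroid_distance` (m), `band_width` (L_far - L_near, m),
#'   `projected_length` (D, m), `enclosed_area_nearest` and
#'   `enclosed_area_farthest` (S, m^2), `n_cells`.
#' @examples
#' sch <- class_scheme(1:2, c("marsh", "mud"), c(TRUE, TRUE))
#' v <- matrix(2L, 20, 10); v[6:10, ] <- 1L
#' g <- landscape_grid(v, 30, 1985, "north", sch)
#' boundary_profile(g, 1L)$mean_distance_nearest  # (5 + 0.5) * 30
#' @export
boundary_profile <- function(grid, class_code) {
  stopifnot(inherits(grid, "landscape_grid"))
  v <- oriented_values(grid)
  cs <- grid$cell_size
  hit <- v == class_code
  if (!any(hit))
    stop("class ", class_code, " is absent from the grid")
  cols <- which(colSums(hit) > 0)
  near <- vapply(cols, function(j) min(which(hit[, j])), numeric(1))
  far  <- vapply(cols, function(j) max(which(hit[, j])), numeric(1))
  near_d <- (near - 0.5) * cs
  far_d  <- (far - 0.5) * cs
  D <- length(cols) * cs
  S_near <- sum(near_d) * cs
  S_far  <- sum(far_d) * cs
  rows_hit <- row(v)[hit]
  zonation_profile(class_code = class_code, year = grid$year,
                   mean_distance_nearest = S_near / D,
                   mean_distance_farthest = S_far / D,
                   centroid_distance = mean((rows_hit - 0.5) * cs),
                   projected_length = D,
                   enclosed_area_nearest = S_near,
                   enclosed_area_farthest = S_far,
                   n_cells = sum(hit))
}

#' @rdname boundary_profile
#' @param year calendar year of the profile.
#' @param mean_distance_nearest,mean_distance_farthest,centroid_distance
#'   distances from the baseline in metres (NA when unknown, e.g. when
#'   building a profile from a published centroid series).
#' @param projected_length,enclosed_area_nearest,enclosed_area_farthest,n_cells
#'   optional geometry bookkeeping.
#' @export
zonation_profile <- function(class_code, year,
                             mean_distance_nearest = NA_real_,
                             mean_distance_farthest = NA_real_,
                             centroid_distance = NA_real_,
                             projected_length = NA_real_,
                             enclosed_area_nearest = NA_real_,
                             enclosed_area_farthest = NA_real_,
                             n_cells = NA_integer_) {
  structure(list(class_code = class_code, year = as.integer(year),
                 mean_distance_nearest = mean_distance_nearest,
                 mean_distance_farthest = mean_distance_farthest,
                 centroid_distance = centroid_distance,
                 band_width = mean_distance_farthest - mean_distance_nearest,
                 projected_length = projected_length,
                 enclosed_area_nearest = enclosed_area_nearest,
                 enclosed_area_farthest = enclosed_area_farthest,
                 n_cells = n_cells),
            class = "zonation_profile")
}

#' @export
print.zonation_profile <- function(x, ...) {
  cat(sprintf(
    "<zonation_profile> class %s, %d: L_near %.1f m, L_far %.1f m, centroid %.1f m, width %.1f m\n",
    x$class_code, x$year, x$mean_distance_nearest, x$mean_distance_farthest,
    x$centroid_distance, x$band_width))
  invisible(x)
}

#' Seaward movement between two zonation profiles
#'
#' Displacement and annual rate of the centroid, nearest boundary,
#' farthest boundary and band width between two dates of the same class.
#' Seaward movement is positive, landward negative.
#'
#' @param profile_a,profile_b [zonation_profile()]s of the same class,
#'   `profile_b` later.
#' @return data frame with one row per available quantity
#'   (`centroid`, `nearest`, `farthest`, `width`): columns `class_code`,
#'   `which`, `year_a`, `year_b`, `displacement_m` (seaward positive),
#'   `rate_m_per_yr`.
#' @export
movement <- function(profile_a, profile_b) {
  stopifnot(inherits(profile_a, "zonation_profile"),
            inherits(profile_b, "zonation_profile"))
  if (!identical(profile_a$class_code, profile_b$class_code))
    stop("profiles describe different classes")
  dt <- profile_b$year - profile_a$year
  if (dt <= 0) stop("profile_b must be later than profile_a")
  fields <- c(centroid = "centroid_distance",
              nearest = "mean_distance_nearest",
              farthest = "mean_distance_farthest",
              width = "band_width")
  rows <- lapply(names(fields), function(w) {
    va <- profile_a[[fields[[w]]]]
    vb <- profile_b[[fields[[w]]]]
    if (is.na(va) || is.na(vb)) return(NULL)
    data.frame(class_code = profile_a$class_code, which = w,
               year_a = profile_a$year, year_b = profile_b$year,
               displacement_m = vb - va,
               rate_m_per_yr = (vb - va) / dt)
  })
  do.call(rbind, rows)
}

#' Area and proportion time series over dated maps
#'
#' Per date: hectares and percentage of total non-nodata area per class.
#' Between every ordered pair of dates: absolute change, percent change
#' relative to the earlier date, and the later/earlier ratio.
#'
#' @param grids list of [landscape_grid()]s with a common scheme.
#' @return list with `by_date` (long data frame: `year`, `class_code`,
#'   `name`, `area_ha`, `proportion_pct`) and `changes` (`class_code`,
#'   `name`, `year_a`, `year_b`, `change_ha`, `percent_change`, `ratio`;
#'   percent/ratio are NA when the earlier area is zero).
#' @export
area_series <- function(grids) {
  if (!length(grids)) stop("need at least one grid")
  sch <- grids[[1]]$scheme
  for (g in grids)
    if (!identical(as.data.frame(g$scheme), as.data.frame(sch)))
      stop("grids use different class schemes")
  years <- unname(vapply(grids, function(g) g$year, integer(1)))
  grids <- grids[order(years)]
  years <- sort(years)
  by_date <- do.call(rbind, lapply(grids, function(g) {
    a <- class_areas(g)
    data.frame(year = g$year, class_code = sch$code, name = sch$name,
               area_ha = as.numeric(a),
               proportion_pct = 100 * as.numeric(a) / sum(a))
  }))
  pairs <- which(outer(years, years, "<"), arr.ind = TRUE)
  changes <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    ia <- pairs[r, 1]; ib <- pairs[r, 2]
    ch <- area_change(class_areas(grids[[ia]]), class_areas(grids[[ib]]))
    cbind(data.frame(class_code = sch$code, name = sch$name,
                     year_a = years[ia], year_b = years[ib]),
          ch)
  }))
  list(by_date = by_date, changes = changes)
}

#' Change statistics between two sets of class areas
#'
#' Absolute change, percent change relative to the earlier value, and the
#' later/earlier ratio; percent and ratio are NA where the earlier area
#' is zero. Vectorized over classes.
#'
#' @param area_a,area_b numeric areas (hectares) at the earlier and later
#'   date.
#' @return data frame with columns `change_ha`, `percent_change`, `ratio`.
#' @examples
#' area_change(514.53, 3925.46)$percent_change  # 662.92
#' @export
area_change <- function(area_a, area_b) {
  area_a <- unname(area_a); area_b <- unname(area_b)
  data.frame(change_ha = as.numeric(area_b - area_a),
             percent_change = ifelse(area_a > 0,
                                     100 * (area_b - area_a) / area_a,
                                     NA_real_),
             ratio = ifelse(area_a > 0, as.numeric(area_b / area_a),
                            NA_real_))
}
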