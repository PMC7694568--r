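test_that("straight bands give the closed-form boundary distances", {
  sch <- toy_scheme(2)
  v <- matrix(2L, 20, 10)
  v[6:10, ] <- 1L  # band occupying rows 6..10 (0-based nearest row 5)
  g <- landscape_grid(v, 30, 1985, "north", sch)
  p <- boundary_profile(g, 1L)
  expect_equal(p$mean_distance_nearest, (5 + 0.5) * 30)
  expect_equal(p$mean_distance_farthest, (9 + 0.5) * 30)
  expect_equal(p$band_width, 4 * 30)
  expect_equal(p$projected_length, 10 * 30)
  expect_equal(p$centroid_distance,
               (p$mean_distance_nearest + p$mean_distance_farthest) / 2)
  # L = S / D holds exactly by construction
  expect_equal(p$enclosed_area_nearest / p$projected_length,
               p$mean_distance_nearest)
  # band spanning 0-based rows 10..19: width (19 - 10) * 30 = 270 m
  v2 <- matrix(2L, 30, 8); v2[11:20, ] <- 1L
  p2 <- boundary_profile(landscape_grid(v2, 30, 1985, "north", sch), 1L)
  expect_equal(p2$band_width, 270)
})

test_that("a staircase boundary matches the hand-summed S / D", {
  sch <- toy_scheme(2)
  v <- matrix(2L, 12, 10)
  for (j in 1:10) v[(2 + j):12, j] <- 1L  # nearest row deepens by column
  g <- landscape_grid(v, 30, 1990, "north", sch)
  p <- boundary_profile(g, 1L)
  near_rows <- (2 + 1:10)        # 1-based nearest rows per column
  expect_equal(p$mean_distance_nearest, mean((near_rows - 0.5) * 30))
  expect_equal(p$mean_distance_farthest, (12 - 0.5) * 30)
})

test_that("boundary_profile agrees with the per-column brute-force oracle", {
  sch <- toy_scheme(3)
  for (s in 1:10) {
    cfg <- synthetic_config(rows = 40, cols = 30, boundary_roughness = 3,
                            seed = 300 + s)
    g <- make_banded_grid(cfg, 1990)
    for (cd in c(1L, 2L, 4L)) {
      p <- boundary_profile(g, cd)
      o <- naive_profile(g, cd)
      expect_equal(p$mean_distance_nearest, o$L_near, tolerance = 1e-13)
      expect_equal(p$mean_distance_farthest, o$L_far, tolerance = 1e-13)
      expect_equal(p$projected_length, o$D)
      expect_true(p$mean_distance_nearest <= p$centroid_distance)
      expect_true(p$centroid_distance <= p$mean_distance_farthest)
    }
  }
})

test_that("profiles respect the baseline edge orientation", {
  sch <- toy_scheme(2)
  v <- matrix(2L, 20, 10); v[6:10, ] <- 1L
  for (edge in c("north", "south", "west", "east")) {
    vv <- switch(edge, north = v, south = v[20:1, ], west = t(v),
                 east = t(v[20:1, , drop = FALSE]))
    g <- landscape_grid(vv, 30, 1985, edge, sch)
    p <- boundary_profile(g, 1L)
    expect_equal(p$mean_distance_nearest, 165, info = edge)
  }
})

test_that("translating a band seaward shifts distances by exactly m cells", {
  sch <- toy_scheme(2)
  v <- matrix(2L, 30, 12); v[6:10, ] <- 1L
  g <- landscape_grid(v, 30, 1985, "north", sch)
  m <- 7
  v2 <- matrix(2L, 30, 12); v2[(6 + m):(10 + m), ] <- 1L
  g2 <- landscape_grid(v2, 30, 1990, "north", sch)
  pa <- boundary_profile(g, 1L); pb <- boundary_profile(g2, 1L)
  expect_equal(pb$mean_distance_nearest - pa$mean_distance_nearest, m * 30)
  expect_equal(pb$mean_distance_farthest - pa$mean_distance_farthest, m * 30)
  expect_equal(pb$centroid_distance - pa$centroid_distance, m * 30)
  expect_equal(pb$band_width, pa$band_width)
  mv <- movement(pa, pb)
  expect_equal(mv$displacement_m[mv$which == "centroid"], m * 30)
  expect_equal(mv$rate_m_per_yr[mv$which == "centroid"], m * 30 / 5)
  expect_equal(mv$displacement_m[mv$which == "width"], 0)
})

test_that("an absent class raises an explicit error, not NaN", {
  sch <- toy_scheme(2)
  g <- landscape_grid(matrix(1L, 5, 5), 30, 2000, "north", sch)
  expect_error(boundary_profile(g, 2L), "absent")
})

test_that("published centroid series reproduce the printed movements", {
  cen <- yancheng_centroids()
  prof <- function(col, yr)
    zonation_profile(class_code = 1, year = yr,
                     centroid_distance = cen[[col]][cen$year == yr])
  mv_p <- movement(prof("phragmites", 1995), prof("phragmites", 2017))
  expect_equal(mv_p$displacement_m[mv_p$which == "centroid"], 877.50)
  expect_equal(mv_p$rate_m_per_yr[mv_p$which == "centroid"], 39.89,
               tolerance = 5e-4)
  mv_s <- movement(prof("suaeda", 1995), prof("suaeda", 2017))
  expect_equal(mv_s$displacement_m[mv_s$which == "centroid"], 1281.10)
  expect_equal(mv_s$rate_m_per_yr[mv_s$which == "centroid"], 58.23,
               tolerance = 5e-4)
  # movement over a reversed pair is the negation (antisymmetry)
  mv_rev <- movement(prof("phragmites", 1995),
                     zonation_profile(1, 2039,
                       centroid_distance = 2 * cen$phragmites[cen$year == 1995] -
                         cen$phragmites[cen$year == 2017]))
  expect_equal(mv_rev$displacement_m, -mv_p$displacement_m)
  # identical profiles move nowhere
  mv0 <- movement(prof("suaeda", 1995),
                  zonation_profile(1, 1996,
                    centroid_distance = cen$suaeda[cen$year == 1995]))
  expect_equal(mv0$displacement_m, 0)
  expect_equal(mv0$rate_m_per_yr, 0)
})

test_that("area series proportions and changes behave as documented", {
  sch <- toy_scheme(2)
  mk <- function(n1, yr) {
    v <- matrix(2L, 10, 10); if (n1 > 0) v[seq_len(n1)] <- 1L
    landscape_grid(v, 30, yr, "north", sch)
  }
  ser <- area_series(list(mk(20, 1985), mk(50, 1990)))
  by85 <- ser$by_date[ser$by_date$year == 1985, ]
  expect_equal(sum(by85$proportion_pct), 100, tolerance = 1e-9)
  expect_equal(by85$proportion_pct[by85$class_code == 1], 20)
  ch <- ser$changes[ser$changes$class_code == 1, ]
  expect_equal(ch$percent_change, 150)   # 20 -> 50 cells
  expect_equal(ch$ratio, 2.5)
  # one class covering everything: proportion 100%
  ser1 <- area_series(list(mk(100, 1985)))
  expect_equal(ser1$by_date$proportion_pct[ser1$by_date$class_code == 1], 100)
  expect_null(ser1$changes)
})

test_that("published area inputs give the printed percent changes", {
  st <- yancheng_stats()
  sp <- area_change(st[["spartina_area_1985_ha"]],
                    st[["spartina_area_2017_ha"]])
  expect_equal(sp$percent_change, 662.92, tolerance = 1e-4)
  ph <- area_change(st[["phragmites_area_1985_ha"]],
                    st[["phragmites_area_2017_ha"]])
  expect_equal(ph$ratio, 1.74, tolerance = 5e-3)
  su <- area_change(st[["suaeda_area_2017_simulated_ha"]],
                    st[["suaeda_area_2017_observed_ha"]])
  expect_equal(-su$percent_change, 82.47, tolerance = 1e-4)
})
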