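test_that("chessboard segmentation tiles the raster with truncated edges", {
  g <- dsm_grid(matrix(100, 20, 20), pixel_size = 0.5)
  tiles <- chessboard_segment(g, 1)
  expect_equal(tiles$nt_r * tiles$nt_c, 100)
  expect_true(all(tiles$n == 4))  # 2x2 px per 1 m2 tile
  g2 <- dsm_grid(matrix(100, 100, 103), pixel_size = 0.1)  # 10 x 10.3 m
  t2 <- chessboard_segment(g2, 1)
  expect_equal(t2$nt_c, 11)
  expect_equal(sum(t2$n[, 11]), 100 * 3)  # last column 0.3 m wide
  expect_error(chessboard_segment(g2, 0.01), "smaller than one pixel")
})

test_that("tile classification uses a strict population-SD threshold", {
  # one 2x2-px tile per case, population SD computed by hand
  vals <- c(100.0, 100.0, 100.5, 102.0)
  pop_sd <- sqrt(mean((vals - mean(vals))^2))
  expect_equal(pop_sd, 0.8197, tolerance = 1e-4)
  g <- dsm_grid(cbind(matrix(vals, 2, 2),          # SD 0.82 -> tree
                      matrix(100, 2, 2),           # SD 0    -> soil
                      matrix(c(-0.1, 0.1, -0.1, 0.1), 2, 2)),  # SD exactly 0.10
                pixel_size = 0.5)
  tiles <- coarse_classify(chessboard_segment(g, 1))
  expect_equal(as.vector(tiles$label), c("tree", "bare_soil", "bare_soil"))
  # all-nodata tile -> bare soil
  m <- matrix(NA_real_, 2, 2)
  gn <- dsm_grid(cbind(matrix(vals, 2, 2), m), pixel_size = 0.5)
  tn <- coarse_classify(chessboard_segment(gn, 1))
  expect_equal(as.vector(tn$label), c("tree", "bare_soil"))
})

test_that("raising the SD threshold never increases tree tiles", {
  terr <- generate_terrain(24, 24, 0.1, roughness_sd = 0.2,
                           roughness_scale_m = 2, seed = 8)
  tiles <- chessboard_segment(terr, 1)
  counts <- vapply(seq(0, 0.4, by = 0.05), function(th)
    sum(coarse_classify(tiles, th)$label == "tree"), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("border pixels follow the nearest-class-mean rule with ties to soil", {
  one <- matrix(1, 1, 1)
  rule <- function(z, mu_t, mu_s)
    orchardcanopy:::nearest_mean_assign(matrix(z, 1, 1), one > 0,
                                        matrix(mu_t, 1, 1), one,
                                        matrix(mu_s, 1, 1), one)[1, 1]
  expect_equal(rule(102, 103, 100), 1L)   # closer to the tree mean
  expect_equal(rule(100, 103, 100), 0L)   # at the soil mean
  expect_equal(rule(101.5, 103, 100), 0L) # exactly midway -> bare soil
  # empty-class fallbacks
  zero <- matrix(0, 1, 1)
  expect_equal(orchardcanopy:::nearest_mean_assign(matrix(102, 1, 1), one > 0,
                                                   matrix(103, 1, 1), one,
                                                   zero, zero)[1, 1], 1L)
  expect_equal(orchardcanopy:::nearest_mean_assign(matrix(102, 1, 1), one > 0,
                                                   zero, zero,
                                                   matrix(100, 1, 1), one)[1, 1], 0L)
})

test_that("flat terrain yields an empty tree mask, not an error", {
  sc <- multilayer_scene(flat_terrain(12, 12, 0.1))
  mask <- delineate(sc)
  expect_equal(mask$n_trees, 0)
  expect_true(all(mask$labels == 0L))
})

test_that("a single isolated crown is recovered with accurate extent", {
  terr <- flat_terrain(20, 20)
  sc <- multilayer_scene(render_dsm(terr, one_crown(x = 10, y = 10)))
  mask <- delineate(sc)
  expect_equal(mask$n_trees, 1)
  area <- sum(mask$labels == 1L) * mask$pixel_size^2
  expect_lt(abs(area - pi * 2 * 2) / (pi * 2 * 2), 0.05)
  # labels partition the raster: every pixel 0 or a contiguous tree label
  expect_setequal(unique(as.vector(mask$labels)), c(0L, 1L))
})

test_that("delineation labels are contiguous and components 8-connected", {
  s <- small_series(n_rows = 2, n_cols = 2, seed = 6)
  mask <- delineate(s$sim$dates$date1$scene)
  expect_equal(mask$n_trees, 4)
  expect_setequal(unique(as.vector(mask$labels)), 0:4)
  for (k in seq_len(mask$n_trees)) {
    comp <- orchardcanopy:::cc_label(mask$labels == k, TRUE)
    expect_equal(attr(comp, "n"), 1L)
  }
})

test_that("small noise components are discarded by the minimum-area filter", {
  terr <- flat_terrain(12, 12, 0.1)
  elev <- terr$elev
  elev[60, 60] <- 103  # a single-pixel spike (0.01 m2)
  sc <- multilayer_scene(dsm_grid(elev, 0.1, terr$xmin, terr$ymax))
  expect_equal(delineate(sc)$n_trees, 0)
  expect_equal(delineate(sc, min_tree_area_m2 = 0.01)$n_trees, 1)
})

test_that("delineation is deterministic (identical output on identical input)", {
  s <- small_series(n_rows = 1, n_cols = 2, seed = 4)
  m1 <- delineate(s$sim$dates$date1$scene)
  m2 <- delineate(s$sim$dates$date1$scene)
  expect_identical(m1$labels, m2$labels)
})

test_that("crowns separated by narrow soil corridors stay distinct trees", {
  # 1 m corridor between footprints along the row axis
  s <- small_series(n_rows = 1, n_cols = 3, seed = 2,
                    crown_params = list(a_mean = 1.5, a_sd = 0,
                                        a_range = c(1.5, 1.5)))
  mask <- delineate(s$sim$dates$date1$scene)
  expect_equal(mask$n_trees, 3)
})

test_that("nodata pixels are excluded and never labeled as tree", {
  terr <- flat_terrain(16, 16)
  r <- render_dsm(terr, one_crown(h_base = 0.6, h_apex = 4))
  elev <- r$elev
  elev[1:40, 1:40] <- NA
  sc <- multilayer_scene(dsm_grid(elev, r$pixel_size, r$xmin, r$ymax))
  mask <- delineate(sc)
  expect_equal(mask$n_trees, 1)
  expect_true(all(mask$labels[1:40, 1:40] == 0L))
})
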