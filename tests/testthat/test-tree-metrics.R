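# Hand-built mask/DSM pair: a 5x5-px tree block centred in a 30x30 raster.
toy_tree <- function(px = 0.2, soil = 100, tree_top = 104.1) {
  lab <- matrix(0L, 30, 30)
  lab[13:17, 13:17] <- 1L
  elev <- matrix(soil, 30, 30)
  elev[13:17, 13:17] <- tree_top
  g <- dsm_grid(elev, px)
  list(mask = tree_mask(lab, g), dsm = g)
}

test_that("ground reference is the buffer-ring soil mean, widened on demand", {
  t <- toy_tree()
  expect_equal(compute_ground_reference(t$mask, t$dsm, 1, buffer_m = 1), 100)
  # two-level soil split symmetrically around the tree -> mean halfway
  t2 <- toy_tree()
  e <- t2$dsm$elev
  e[, 1:15][t2$mask$labels[, 1:15] == 0L] <- 100
  e[, 16:30][t2$mask$labels[, 16:30] == 0L] <- 101
  d2 <- dsm_grid(e, 0.2)
  g <- compute_ground_reference(t2$mask, d2, 1)
  expect_equal(g, 100.5, tolerance = 0.02)
  # landlocked: every non-tree pixel belongs to another tree
  lab <- matrix(2L, 30, 30); lab[13:17, 13:17] <- 1L
  landlocked <- tree_mask(lab, t$dsm)
  expect_error(compute_ground_reference(landlocked, t$dsm, 1), "landlocked")
})

test_that("height, area and volume follow their definitions exactly", {
  t <- toy_tree(px = 0.2, tree_top = 104.1)
  expect_equal(compute_height(t$mask, t$dsm, 1, ground_ref = 100), 4.1)
  expect_equal(compute_area(t$mask, 1), 25 * 0.04)
  # one pixel of 0.04 m2 with 2 m height -> 0.08 m3
  lab1 <- matrix(0L, 10, 10); lab1[5, 5] <- 1L
  e1 <- matrix(100, 10, 10); e1[5, 5] <- 102
  g1 <- dsm_grid(e1, 0.2)
  expect_equal(compute_volume(tree_mask(lab1, g1), g1, 1, 100), 0.08)
  # pixels below the ground reference are clamped to zero contribution
  e1[5, 5] <- 99.5
  g2 <- dsm_grid(e1, 0.2)
  expect_equal(compute_volume(tree_mask(lab1, g2), g2, 1, 100), 0)
  # pixel-count arithmetic at the study pixel size
  expect_equal(6152 * 0.05^2, 15.38)
})

test_that("heights recover generator truth on a noiseless crown", {
  terr <- flat_terrain(16, 16)
  sc <- multilayer_scene(render_dsm(terr, one_crown(h_base = 0.6, h_apex = 4)))
  mask <- delineate(sc)
  rec <- extract_features(mask, sc)
  expect_lt(abs(rec$height_m - 4), 0.05)
  expect_true(rec$volume_m3 <= rec$area_m2 * rec$height_m)
})

test_that("grid positions round to the nearest node with duplicate handling", {
  cfg <- orchard_config(origin_xy = c(0, 0))
  node <- grid_node_xy(cfg, 3, 5)
  rec <- data.frame(tree_id = 1:3,
                    x = c(node[1], node[1] + 0.5, grid_node_xy(cfg, 3, 5)[1] + 0.4),
                    y = c(node[2], node[2], node[2] + 0.3),
                    reliable = TRUE, flag = "", stringsAsFactors = FALSE)
  out <- assign_grid_position(rec, cfg)
  expect_equal(out$row, c(3L, 3L, 3L))
  expect_equal(out$column, c(5L, 5L, 5L))
  expect_equal(out$treatment, rep("traditional", 3))
  # the nearest centroid keeps the node, the others are flagged
  expect_true(out$reliable[1])
  expect_false(any(out$reliable[2:3]))
  expect_match(out$flag[2], "duplicate_node")
  # beyond the grid edge by more than half a spacing -> off_grid flag
  edge <- grid_node_xy(cfg, 3, cfg$n_cols)
  far <- data.frame(tree_id = 1L, x = edge[1] + 3, y = edge[2],
                    reliable = TRUE, flag = "", stringsAsFactors = FALSE)
  out_far <- assign_grid_position(far, cfg)
  expect_match(out_far$flag, "off_grid")
  expect_equal(out_far$column, cfg$n_cols)  # clipped into range
})

test_that("features are equivariant under whole-pixel origin shifts", {
  crown <- one_crown(x = 8, y = 8, a = 1.5, b = 1.8, h_base = 0.6, h_apex = 4)
  t1 <- flat_terrain(16, 16)
  t2 <- generate_terrain(16, 16, 0.05, base_elev = 100, xmin = 3.25, ymin = -1.10)
  crown2 <- crown; crown2$x <- crown$x + 3.25; crown2$y <- crown$y - 1.10
  s1 <- multilayer_scene(render_dsm(t1, crown))
  s2 <- multilayer_scene(render_dsm(t2, crown2))
  r1 <- extract_features(delineate(s1), s1)
  r2 <- extract_features(delineate(s2), s2)
  expect_equal(r2$x - r1$x, 3.25, tolerance = 1e-9)
  expect_equal(r2$y - r1$y, -1.10, tolerance = 1e-9)
  expect_equal(r1$area_m2, r2$area_m2)
  expect_equal(r1$height_m, r2$height_m)
  expect_equal(r1$volume_m3, r2$volume_m3)
})

test_that("DSM noise moves mean height estimates by less than 3 sigma", {
  s <- small_series(n_rows = 2, n_cols = 2, seed = 13)
  sc0 <- s$sim$dates$date1$scene
  r0 <- extract_features(delineate(sc0), sc0, s$cfg)
  sigma <- 0.02
  noisy <- multilayer_scene(render_dsm(s$sim$terrain, s$sim$dates$date1$crowns,
                                       noise_sd = sigma, seed = 99), date_label = "date1")
  rn <- extract_features(delineate(noisy), noisy, s$cfg)
  m <- merge(r0, rn, by = c("row", "column"))
  expect_equal(nrow(m), 4)
  expect_lt(abs(mean(m$height_m.y - m$height_m.x)), 3 * sigma)
})

test_that("an empty mask yields an empty record table", {
  sc <- multilayer_scene(flat_terrain(8, 8, 0.1))
  mask <- delineate(sc)
  rec <- extract_features(mask, sc)
  expect_equal(nrow(rec), 0)
  expect_s3_class(rec, "tree_records")
})

test_that("mostly-nodata crowns are flagged unreliable", {
  terr <- flat_terrain(16, 16)
  r <- render_dsm(terr, one_crown(h_base = 0.6, h_apex = 4))
  sc <- multilayer_scene(r)
  mask <- delineate(sc)
  idx <- which(mask$labels == 1L)
  elev <- r$elev
  elev[idx[seq_len(round(0.3 * length(idx)))]] <- NA  # 30% of the crown lost
  sc2 <- multilayer_scene(dsm_grid(elev, r$pixel_size, r$xmin, r$ymax))
  rec <- extract_features(mask, sc2)
  expect_false(rec$reliable)
  expect_match(rec$flag, "nodata")
})
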