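test_that("closed-form crown volume matches the half-ellipsoid formula", {
  expect_equal(crown_volume(2, 2, 0, 3), 2 / 3 * pi * 2 * 2 * 3, tolerance = 1e-12)
  expect_equal(crown_volume(1.5, 2.3, 0, 4), 2 / 3 * pi * 1.5 * 2.3 * 4,
               tolerance = 1e-12)
})

test_that("analytic volume agrees with brute-force integration at 1 cm", {
  cases <- list(
    list(a = 2, b = 2, h_base = 0, h_apex = 3),
    list(a = 1.5, b = 2.35, h_base = 0.6, h_apex = 4.0),
    list(a = 1.5, b = 2.35, h_base = 0.6, h_apex = 4.2, cap = 3.75),
    list(a = 1.4, b = 2.2, h_base = 0.6, h_apex = 4.0, low_cut = 0.7),
    list(a = 1.5, b = 2.3, h_base = 0.6, h_apex = 4.1, gap_frac = 0.25),
    list(a = 1.6, b = 2.4, h_base = 0.6, h_apex = 4.3, cap = 3.6,
         low_cut = 0.7, gap_frac = 0.2))
  for (cs in cases) {
    closed <- do.call(crown_volume, cs)
    brute <- do.call(numeric_crown_volume, cs)
    expect_equal(closed, brute, tolerance = 0.01,
                 label = paste("closed form", paste(unlist(cs), collapse = "/")))
  }
})

test_that("terrain generation is analytic, deterministic and margin-checked", {
  flat <- generate_terrain(10, 10, 0.1, base_elev = 100)
  expect_true(all(flat$elev == 100))
  sl <- generate_terrain(100, 10, 0.1, base_elev = 100, slope = c(0.01, 0))
  expect_equal(max(sl$elev) - min(sl$elev), 0.01 * (100 - 0.1), tolerance = 1e-9)
  r1 <- generate_terrain(20, 20, 0.1, roughness_sd = 0.3, seed = 42)
  r2 <- generate_terrain(20, 20, 0.1, roughness_sd = 0.3, seed = 42)
  expect_identical(r1$elev, r2$elev)
  cfg <- orchard_config(n_rows = 3, n_cols = 3, origin_xy = c(2, 2),
                        treatment_blocks = list(traditional = 1:3))
  expect_error(generate_terrain(10, 10, 0.1, config = cfg), "margin")
})

test_that("orchard generation places one crown per node with exact truth", {
  orch <- generate_orchard(seed = 1)  # default study layout
  expect_equal(nrow(orch$crowns), 648)
  expect_equal(range(orch$crowns$row), c(1, 27))
  expect_equal(range(orch$crowns$column), c(1, 24))
  expect_equal(orch$truth$true_volume_m3,
               crown_volume(orch$crowns$a, orch$crowns$b, orch$crowns$h_base,
                            orch$crowns$h_apex))
  cfg <- orchard_config(n_rows = 2, n_cols = 2,
                        treatment_blocks = list(traditional = 1:2))
  nj <- generate_orchard(cfg, jitter_sd = 0, seed = 3)
  nodes <- grid_node_xy(cfg, nj$crowns$row, nj$crowns$column)
  expect_equal(nj$crowns$x, unname(nodes[, 1]))
  expect_equal(nj$crowns$y, unname(nodes[, 2]))
})

test_that("overlapping crowns are rejected unless explicitly allowed", {
  cfg <- orchard_config(n_rows = 1, n_cols = 2,
                        treatment_blocks = list(traditional = 1))
  big <- list(a_mean = 2.3, a_sd = 0, a_range = c(2.3, 2.3))
  expect_error(generate_orchard(cfg, big, jitter_sd = 0, seed = 1), "overlap")
  expect_silent(generate_orchard(cfg, big, jitter_sd = 0, seed = 1,
                                 allow_overlap = TRUE))
})

test_that("rendering reproduces terrain, apex height and noise determinism", {
  terr <- flat_terrain(10, 10, 0.05)
  expect_identical(render_dsm(terr, one_crown()[0, ])$elev, terr$elev)
  crown <- one_crown(x = 5, y = 5, a = 1.5, b = 1.5, h_apex = 4)
  r <- render_dsm(terr, crown)
  expect_lt(abs(max(r$elev) - 100 - 4), 0.05 / 2)
  n1 <- render_dsm(terr, crown, noise_sd = 0.02, seed = 7)
  n2 <- render_dsm(terr, crown, noise_sd = 0.02, seed = 7)
  expect_identical(n1$elev, n2$elev)
})

test_that("pruning treatments transform geometry and truth exactly", {
  crown <- one_crown(a = 2, b = 2, h_base = 0, h_apex = 4.2)
  mech <- apply_pruning(crown, pruning_spec("mechanical",
                                            top_cut_range = c(3.75, 3.75),
                                            low_cut_height_m = 0.0001))
  expect_equal(mech$truth$true_height_m, 3.75)
  trad <- apply_pruning(one_crown(), pruning_spec("traditional",
                                                  volume_removal_fraction = 0.36))
  expect_equal(trad$truth$true_volume_m3, 25.13274 * (1 - 0.36), tolerance = 1e-4)
  expect_equal(trad$crowns$severity, 0.36, tolerance = 1e-12)
  noop <- apply_pruning(one_crown(), pruning_spec("traditional",
                                                  volume_removal_fraction = 0))
  expect_equal(noop$crowns$a, one_crown()$a)
  expect_error(pruning_spec("traditional", volume_removal_fraction = 1), "\\[0, 1\\)")
  expect_error(apply_pruning(one_crown(a = 0.06, b = 0.06),
                             pruning_spec("traditional", 0.9)), "semi-axes")
})

test_that("pruning never increases truth volume; topping above apex keeps area", {
  set.seed(11)
  for (i in 1:10) {
    cr <- one_crown(a = runif(1, 1.2, 1.8), b = runif(1, 1.9, 2.6),
                    h_base = 0.6, h_apex = runif(1, 3.6, 4.4))
    v0 <- crown_volume(cr$a, cr$b, cr$h_base, cr$h_apex)
    for (tr in c("traditional", "adapted", "mechanical")) {
      pr <- apply_pruning(cr, pruning_spec(tr, volume_removal_fraction = runif(1, 0, 0.6),
                                           seed = i))
      expect_lte(pr$truth$true_volume_m3, v0 + 1e-12)
    }
    high_cut <- apply_pruning(cr, pruning_spec("mechanical",
                                               top_cut_range = c(cr$h_apex + 0.1,
                                                                 cr$h_apex + 0.1),
                                               low_cut_height_m = 0.0001, seed = i))
    expect_equal(high_cut$truth$true_area_m2, crown_area(cr$a, cr$b, cr$h_base, cr$h_apex))
  }
})

test_that("regrowth scales volume by the severity-class fraction", {
  crown <- one_crown()
  crown$severity <- 0.36  # class 30-50%
  grown <- apply_regrowth(crown, c("<10%" = 0, "10-30%" = 0, "30-50%" = 0.60,
                                   ">50%" = 0), noise_sdlog = 0)
  expect_equal(grown$truth$true_volume_m3, crown_volume(2, 2, 0, 3) * 1.60,
               tolerance = 1e-9)
  ident <- apply_regrowth(crown, c("<10%" = 0, "10-30%" = 0, "30-50%" = 0, ">50%" = 0))
  expect_equal(ident$crowns$a, crown$a)
  expect_error(apply_regrowth(crown, c("<10%" = -0.1, "10-30%" = 0,
                                       "30-50%" = 0, ">50%" = 0)), "non-negative")
  g1 <- apply_regrowth(crown, noise_sdlog = 0.1, seed = 5)
  g2 <- apply_regrowth(crown, noise_sdlog = 0.1, seed = 5)
  expect_identical(g1$crowns$a, g2$crowns$a)
})

test_that("artifact injection deletes crowns reproducibly", {
  s <- small_series(seed = 2)
  d1 <- s$sim$dates$date1
  art <- inject_artifacts(d1$scene$dsm, s$sim$terrain, d1$crowns,
                          deletion_fraction = 0.34, n_spikes = 3, seed = 4)
  expect_length(art$deleted_tree_ids, 2)
  sc2 <- multilayer_scene(art$dsm)
  mask <- delineate(sc2)
  expect_equal(mask$n_trees, nrow(d1$crowns) - 2)
})
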