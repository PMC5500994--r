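# Shared fixtures: everything is generated in code at test time.

flat_terrain <- function(width = 16, height = 16, px = 0.05, elev = 100) {
  generate_terrain(width, height, px, base_elev = elev)
}

# One-crown data frame in the layout generate_orchard() produces.
one_crown <- function(x = 8, y = 8, a = 2, b = 2, h_base = 0, h_apex = 3,
                      cap = Inf, low_cut = 0, gap_frac = 0, azimuth_deg = 0,
                      treatment = "traditional") {
  data.frame(tree_id = 1L, row = 1L, column = 1L, x = x, y = y, a = a, b = b,
             h_base = h_base, h_apex = h_apex, cap = cap, low_cut = low_cut,
             gap_frac = gap_frac, azimuth_deg = azimuth_deg,
             treatment = treatment, severity = 0, stringsAsFactors = FALSE)
}

# Numerical-integration oracle for the rendered crown surface volume:
# brute-force sum over a fine grid, independent of the closed form and of
# render_dsm().
numeric_crown_volume <- function(a, b, h_base, h_apex, cap = Inf, low_cut = 0,
                                 gap_frac = 0, step = 0.01) {
  xs <- seq(-a, a, by = step)
  ys <- seq(-b, b, by = step)
  cc <- h_apex - h_base
  t2 <- outer(ys^2 / b^2, xs^2 / a^2, "+")
  v <- pmin(1, pmax(0, (low_cut - h_base) / cc))
  rLsq <- 1 - v^2
  z <- matrix(0, length(ys), length(xs))
  inside <- t2 <= rLsq & t2 > gap_frac^2
  z[inside] <- pmin(h_base + cc * sqrt(pmax(0, 1 - t2[inside])), cap)
  sum(z) * step^2
}

# Small three-date simulation used by several tests.
small_series <- function(n_rows = 2, n_cols = 3, seed = 1, ...) {
  cfg <- orchard_config(n_rows = n_rows, n_cols = n_cols, origin_xy = c(8, 8),
                        treatment_blocks = list(traditional = seq_len(n_rows)))
  list(cfg = cfg,
       sim = simulate_orchard_series(cfg, seed = seed, ...))
}
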