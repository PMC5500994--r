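#' Synthetic orchard simulation
#'
#' Crowns are modelled as half-ellipsoids: the upper sheet of an ellipsoid
#' with horizontal semi-axes `a` (along the within-row axis) and `b` (across
#' rows), rising from a crown base `h_base` meters above ground to an apex
#' `h_apex`.  Because a surface model sees the canopy top from above, the
#' rendered height field inside the footprint is
#' `z(t) = min(h_base + c * sqrt(1 - t), cap)` with `c = h_apex - h_base` and
#' `t` the squared normalized elliptical radius; `cap` is an optional
#' mechanical topping cut.  A `low_cut` trims the footprint to where the sheet
#' clears the cut, and `gap_frac` opens an elliptical core (fraction of the
#' semi-axes) down to the ground, emulating inner-crown removal.
#'
#' All analytic ground-truth formulas below integrate that *rendered surface*,
#' so truth and DSM-derived measurements share one convention.
#'
#' @name synthetic_orchard
NULL

# Truncated-normal draws by inverse-CDF on a clipped uniform.
rtnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lo), hi), n))
  p <- runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  qnorm(p, mean, sd)
}

default_crown_params <- function() {
  list(apex_mean = 4.0, apex_sd = 0.12, apex_range = c(3.6, 4.4),
       a_mean = 1.5, a_sd = 0.07, a_range = c(1.35, 1.70),
       b_mean = 2.35, b_sd = 0.12, b_range = c(2.05, 2.65),
       base_height = 0.6)
}

#' Analytic volume under the rendered crown surface
#'
#' Closed-form integral of the crown surface height over its footprint.  For
#' an untruncated half-ellipsoid with `h_base = 0` this is the classical
#' `(2/3) * pi * a * b * h_apex`; a positive crown base adds the cylindrical
#' column under the canopy rim, a `cap` flattens the top (exact truncated
#' integral), a `low_cut` above the base trims the footprint, and `gap_frac`
#' subtracts the open central core.
#'
#' @param a,b horizontal semi-axes (m).
#' @param h_base,h_apex crown base and apex height above ground (m).
#' @param cap topping-cut height (m above ground, `Inf` for none).
#' @param low_cut low-cut height (m; only effective above `h_base`).
#' @param gap_frac central gap core radius as a fraction of the semi-axes.
#' @return Volume in cubic meters (vectorized over crowns).
#' @export
#' @examples
#' crown_volume(2, 2, 0, 3)  # (2/3) * pi * 2 * 2 * 3 = 25.133
crown_volume <- function(a, b, h_base, h_apex, cap = Inf, low_cut = 0, gap_frac = 0) {
  stopifnot(all(h_apex > h_base), all(h_base >= 0), all(a > 0), all(b > 0))
  cc <- h_apex - h_base
  T <- pmin(cap, h_apex)
  u <- pmin(1, pmax(0, (T - h_base) / cc))
  r0sq <- 1 - u^2
  v <- pmin(1, pmax(0, (low_cut - h_base) / cc))
  rLsq <- 1 - v^2
  vol <- pi * a * b * (r0sq * T + (rLsq - r0sq) * h_base + (2 / 3) * cc * (u^3 - v^3))
  g2 <- pmin(gap_frac^2, rLsq)
  core <- pi * a * b * (pmin(g2, r0sq) * T + pmax(0, g2 - r0sq) * h_base +
                          ifelse(g2 > r0sq, (2 / 3) * cc * (u^3 - (1 - g2)^1.5), 0))
  vol - core
}

#' Analytic projected area of a crown footprint
#'
#' The footprint is the ellipse where the rendered sheet clears the low cut.
#' The central gap is *kept* in the area: the delineation closes enclosed
#' holes when joining tree objects, so the measured projected area includes
#' it, and truth follows the same convention (the gap still contributes zero
#' volume on both sides).
#'
#' @inheritParams crown_volume
#' @return Area in square meters (vectorized).
#' @export
crown_area <- function(a, b, h_base, h_apex, cap = Inf, low_cut = 0, gap_frac = 0) {
  cc <- h_apex - h_base
  v <- pmin(1, pmax(0, (low_cut - h_base) / cc))
  pi * a * b * (1 - v^2)
}

#' Generate smooth synthetic terrain
#'
#' Terrain is a tilted plane plus an optional low-frequency Gaussian random
#' field (coarse white noise bilinearly interpolated to pixel resolution).
#'
#' @param width_m,height_m extent in meters.
#' @param pixel_size meters per pixel.
#' @param base_elev datum elevation (m) at the lower-left corner.
#' @param slope gradient vector `c(dz/dx, dz/dy)` (m per m).
#' @param roughness_sd standard deviation (m) of the low-frequency field.
#' @param roughness_scale_m correlation scale (m) of the field.
#' @param seed integer seed; the field is reproducible for a fixed seed.
#' @param xmin,ymin projected coordinates of the lower-left corner.
#' @param crs CRS label.
#' @param config optional [orchard_config]; when given, the extent must cover
#'   every grid node with at least 5 m to spare.
#' @return A [dsm_grid].
#' @export
generate_terrain <- function(width_m, height_m, pixel_size = 0.05,
                             base_elev = 100, slope = c(0, 0),
                             roughness_sd = 0, roughness_scale_m = 20,
                             seed = 1, xmin = 0, ymin = 0,
                             crs = "synthetic local grid (m)", config = NULL) {
  stopifnot(width_m > 0, height_m > 0, pixel_size > 0)
  if (!is.null(config)) {
    nodes <- grid_node_xy(config, rep(seq_len(config$n_rows), config$n_cols),
                          rep(seq_len(config$n_cols), each = config$n_rows))
    if (min(nodes[, 1]) < xmin + 5 || max(nodes[, 1]) > xmin + width_m - 5 ||
        min(nodes[, 2]) < ymin + 5 || max(nodes[, 2]) > ymin + height_m - 5)
      stop("terrain extent does not cover the plantation grid with a 5 m margin")
  }
  nc <- as.integer(ceiling(width_m / pixel_size))
  nr <- as.integer(ceiling(height_m / pixel_size))
  xs <- xmin + (seq_len(nc) - 0.5) * pixel_size
  ys <- ymin + nr * pixel_size - (seq_len(nr) - 0.5) * pixel_size  # row 1 = top
  z <- base_elev + outer(ys - ymin, xs - xmin, function(y, x) slope[1] * x + slope[2] * y)
  if (roughness_sd > 0) {
    set.seed(seed)
    cx <- seq(xmin - roughness_scale_m, xmin + width_m + roughness_scale_m,
              by = roughness_scale_m)
    cy <- seq(ymin - roughness_scale_m, ymin + height_m + roughness_scale_m,
              by = roughness_scale_m)
    C <- matrix(rnorm(length(cy) * length(cx), 0, roughness_sd),
                length(cy), length(cx))
    M1 <- t(vapply(seq_along(cy), function(i)
      stats::approx(cx, C[i, ], xout = xs, rule = 2)$y, numeric(nc)))
    R <- vapply(seq_len(nc), function(j)
      stats::approx(cy, M1[, j], xout = ys, rule = 2)$y, numeric(nr))
    z <- z + R
  }
  dsm_grid(z, pixel_size, xmin = xmin, ymax = ymin + nr * pixel_size, crs = crs)
}

# Ellipse support radius in direction theta (radians, in the crown frame).
ellipse_radius <- function(a, b, theta) {
  1 / sqrt((cos(theta) / a)^2 + (sin(theta) / b)^2)
}

#' Generate a synthetic orchard of half-ellipsoid crowns
#'
#' Places one crown per plantation grid node, with centers jittered by
#' independent Normal(0, `jitter_sd`^2) offsets per axis and crown dimensions
#' drawn from truncated normal distributions.  Adjacent crowns are checked for
#' overlap along both grid axes using the exact ellipse support radii.
#'
#' @param config an [orchard_config].
#' @param crown_params list overriding any of the defaults: `apex_mean`,
#'   `apex_sd`, `apex_range`, `a_mean`, `a_sd`, `a_range` (within-row
#'   semi-axis), `b_mean`, `b_sd`, `b_range` (across-row semi-axis),
#'   `base_height`.
#' @param jitter_sd center jitter standard deviation (m).
#' @param seed integer seed.
#' @param allow_overlap skip the neighbour-overlap check.
#' @param date_label truth date tag.
#' @return `list(crowns, truth)`: `crowns` is a data frame (one row per tree)
#'   with geometry columns; `truth` the matching ground-truth table with
#'   analytic height/area/volume.
#' @export
generate_orchard <- function(config = orchard_config(), crown_params = list(),
                             jitter_sd = 0.05, seed = 1, allow_overlap = FALSE,
                             date_label = "date1") {
  p <- utils::modifyList(default_crown_params(), crown_params)
  set.seed(seed)
  n <- config$n_rows * config$n_cols
  row <- rep(seq_len(config$n_rows), each = config$n_cols)
  col <- rep(seq_len(config$n_cols), config$n_rows)
  nodes <- grid_node_xy(config, row, col)
  jx <- rnorm(n, 0, jitter_sd); jy <- rnorm(n, 0, jitter_sd)
  crowns <- data.frame(
    tree_id = (row - 1L) * config$n_cols + col,
    row = row, column = col,
    x = nodes[, 1] + jx, y = nodes[, 2] + jy,
    a = rtnorm(n, p$a_mean, p$a_sd, p$a_range[1], p$a_range[2]),
    b = rtnorm(n, p$b_mean, p$b_sd, p$b_range[1], p$b_range[2]),
    h_base = p$base_height,
    h_apex = rtnorm(n, p$apex_mean, p$apex_sd, p$apex_range[1], p$apex_range[2]),
    cap = Inf, low_cut = 0, gap_frac = 0,
    azimuth_deg = config$row_azimuth_deg,
    treatment = treatment_of_row(config, row),
    severity = 0,
    stringsAsFactors = FALSE)
  if (!allow_overlap) check_crown_overlap(crowns, config)
  list(crowns = crowns, truth = orchard_truth(crowns, date_label))
}

check_crown_overlap <- function(crowns, config) {
  az <- config$row_azimuth_deg * pi / 180
  pair_check <- function(i, j) {
    dx <- crowns$x[j] - crowns$x[i]; dy <- crowns$y[j] - crowns$y[i]
    d <- sqrt(dx^2 + dy^2)
    th <- atan2(dy, dx) - az  # direction in the shared crown frame
    ri <- ellipse_radius(crowns$a[i], crowns$b[i], th)
    rj <- ellipse_radius(crowns$a[j], crowns$b[j], th)
    d < ri + rj
  }
  key <- (crowns$row - 1L) * (max(crowns$column) + 1L) + crowns$column
  idx <- order(key)
  for (shift in list(c(0L, 1L), c(1L, 0L))) {
    m <- match(paste(crowns$row + shift[1], crowns$column + shift[2]),
               paste(crowns$row, crowns$column))
    have <- which(!is.na(m))
    for (i in have)
      if (pair_check(i, m[i]))
        stop("adjacent crowns overlap at row ", crowns$row[i], " col ",
             crowns$column[i], "; shrink semi-axes/jitter or set allow_overlap")
  }
  invisible(TRUE)
}

#' Ground-truth table for a crown set
#'
#' @param crowns crown data frame as produced by [generate_orchard()].
#' @param date_label date tag.
#' @return Data frame with analytic `true_height_m`, `true_area_m2`,
#'   `true_volume_m3` per tree.
#' @export
orchard_truth <- function(crowns, date_label = "date1") {
  data.frame(tree_id = crowns$tree_id, row = crowns$row, column = crowns$column,
             x = crowns$x, y = crowns$y,
             true_height_m = pmin(crowns$h_apex, crowns$cap),
             true_area_m2 = crown_area(crowns$a, crowns$b, crowns$h_base,
                                       crowns$h_apex, crowns$cap, crowns$low_cut,
                                       crowns$gap_frac),
             true_volume_m3 = crown_volume(crowns$a, crowns$b, crowns$h_base,
                                           crowns$h_apex, crowns$cap, crowns$low_cut,
                                           crowns$gap_frac),
             treatment = crowns$treatment,
             severity = crowns$severity,
             date_label = date_label,
             stringsAsFactors = FALSE)
}

#' Render crowns onto terrain as a DSM
#'
#' The rendered elevation is `terrain + max over crowns of the crown surface
#' height` (crowns are opaque from above: the DSM sees the canopy top, not the
#' under-canopy gap), plus optional additive Gaussian noise.
#'
#' @param terrain a [dsm_grid].
#' @param crowns crown data frame.
#' @param noise_sd DSM noise standard deviation (m).
#' @param seed seed for the noise.
#' @return A [dsm_grid] of the same geometry as `terrain`.
#' @export
render_dsm <- function(terrain, crowns, noise_sd = 0, seed = 1) {
  stopifnot(inherits(terrain, "dsm_grid"))
  d <- dim(terrain$elev); px <- terrain$pixel_size
  ch <- matrix(0, d[1], d[2])
  for (k in seq_len(nrow(crowns))) {
    cr <- crowns[k, ]
    th <- cr$azimuth_deg * pi / 180
    cc <- cr$h_apex - cr$h_base
    v <- min(1, max(0, (cr$low_cut - cr$h_base) / cc))
    rLsq <- 1 - v^2
    hx <- sqrt((cr$a * cos(th))^2 + (cr$b * sin(th))^2) * sqrt(rLsq)
    hy <- sqrt((cr$a * sin(th))^2 + (cr$b * cos(th))^2) * sqrt(rLsq)
    j1 <- max(1L, floor((cr$x - hx - terrain$xmin) / px) + 1L)
    j2 <- min(d[2], ceiling((cr$x + hx - terrain$xmin) / px))
    i1 <- max(1L, floor((terrain$ymax - (cr$y + hy)) / px) + 1L)
    i2 <- min(d[1], ceiling((terrain$ymax - (cr$y - hy)) / px))
    if (j1 > j2 || i1 > i2) next
    xs <- terrain$xmin + (j1:j2 - 0.5) * px - cr$x
    ys <- terrain$ymax - (i1:i2 - 0.5) * px - cr$y
    DU <- outer(ys * sin(th), xs * cos(th), "+")
    DV <- outer(ys * cos(th), -xs * sin(th), "+")
    t2 <- (DU / cr$a)^2 + (DV / cr$b)^2
    z <- matrix(0, length(ys), length(xs))
    inside <- t2 <= rLsq & t2 > cr$gap_frac^2
    z[inside] <- pmin(cr$h_base + cc * sqrt(pmax(0, 1 - t2[inside])), cr$cap)
    blk <- ch[i1:i2, j1:j2, drop = FALSE]
    ch[i1:i2, j1:j2] <- pmax(blk, z)
  }
  elev <- terrain$elev + ch
  if (noise_sd > 0) {
    set.seed(seed)
    elev <- elev + matrix(rnorm(length(elev), 0, noise_sd), d[1], d[2])
  }
  elev[terrain$nodata] <- NA_real_
  dsm_grid(elev, px, xmin = terrain$xmin, ymax = terrain$ymax, crs = terrain$crs)
}

#' Pruning treatment specification
#'
#' Three treatments are simulated.  *Traditional*: crown thinning removing a
#' set fraction of the crown volume (semi-axes scaled by `sqrt(1 - f)`).
#' *Adapted*: the same fractional removal plus an open central core (gap).
#' *Mechanical*: tractor topping cuts at a per-tree uniform height between
#' `top_cut_range` (default 3.5-4.0 m above terrain) plus a horizontal low
#' cut at 0.7 m.
#'
#' @param treatment `"traditional"`, `"adapted"` or `"mechanical"`.
#' @param volume_removal_fraction fraction of crown volume removed
#'   (traditional/adapted), in `[0, 1)`.
#' @param top_cut_range 2-vector of the mechanical topping height draw (m).
#' @param low_cut_height_m mechanical low-cut height (m).
#' @param gap_frac adapted-pruning central gap radius as a fraction of the
#'   semi-axes.
#' @param seed seed for per-tree cut heights.
#' @return An object of class `pruning_spec`.
#' @export
pruning_spec <- function(treatment = c("traditional", "adapted", "mechanical"),
                         volume_removal_fraction = NULL,
                         top_cut_range = c(3.5, 4.0),
                         low_cut_height_m = 0.7,
                         gap_frac = 0.25, seed = 1) {
  treatment <- match.arg(treatment)
  if (treatment %in% c("traditional", "adapted")) {
    if (is.null(volume_removal_fraction))
      volume_removal_fraction <- if (treatment == "traditional") 0.36 else 0.42
    if (volume_removal_fraction < 0 || volume_removal_fraction >= 1)
      stop("volume_removal_fraction must be in [0, 1)")
  }
  if (diff(top_cut_range) < 0 || top_cut_range[1] <= low_cut_height_m)
    stop("top cut must exceed the low cut")
  structure(list(treatment = treatment,
                 volume_removal_fraction = volume_removal_fraction,
                 top_cut_range = top_cut_range,
                 low_cut_height_m = low_cut_height_m,
                 gap_frac = gap_frac, seed = seed),
            class = "pruning_spec")
}

#' Apply a pruning treatment to crowns
#'
#' Modifies crown geometry according to a [pruning_spec] and records each
#' crown's pruning severity (fraction of its rendered-surface volume removed).
#'
#' @param crowns crown data frame.
#' @param spec a [pruning_spec].
#' @param min_semi_axis_m smallest admissible semi-axis after scaling (m).
#' @param date_label date tag for the returned truth.
#' @return `list(crowns, truth)` with updated geometry and analytic truth.
#' @export
apply_pruning <- function(crowns, spec, min_semi_axis_m = 0.05,
                          date_label = "date2") {
  stopifnot(inherits(spec, "pruning_spec"))
  v0 <- crown_volume(crowns$a, crowns$b, crowns$h_base, crowns$h_apex,
                     crowns$cap, crowns$low_cut, crowns$gap_frac)
  if (spec$treatment == "mechanical") {
    set.seed(spec$seed)
    cuts <- runif(nrow(crowns), spec$top_cut_range[1], spec$top_cut_range[2])
    if (any(cuts <= crowns$h_base))
      stop("mechanical top cut at or below the crown base")
    crowns$cap <- pmin(crowns$cap, cuts)
    crowns$low_cut <- pmax(crowns$low_cut, spec$low_cut_height_m)
  } else {
    s <- sqrt(1 - spec$volume_removal_fraction)
    if (any(crowns$a * s < min_semi_axis_m) || any(crowns$b * s < min_semi_axis_m))
      stop("removal fraction would shrink semi-axes below ", min_semi_axis_m, " m")
    crowns$a <- crowns$a * s
    crowns$b <- crowns$b * s
    if (spec$treatment == "adapted")
      crowns$gap_frac <- pmax(crowns$gap_frac, spec$gap_frac)
  }
  v1 <- crown_volume(crowns$a, crowns$b, crowns$h_base, crowns$h_apex,
                     crowns$cap, crowns$low_cut, crowns$gap_frac)
  crowns$severity <- 1 - v1 / v0
  list(crowns = crowns, truth = orchard_truth(crowns, date_label))
}

#' Severity class labels
#'
#' Left-closed classes of percent crown-volume removal:
#' `[0,10) [10,30) [30,50) [50,Inf)`.
#'
#' @param severity_pct percent of crown volume removed (non-negative).
#' @return Factor with levels `"<10%" "10-30%" "30-50%" ">50%"`.
#' @export
classify_severity <- function(severity_pct) {
  cut(pmax(severity_pct, 0), breaks = c(0, 10, 30, 50, Inf), right = FALSE,
      labels = c("<10%", "10-30%", "30-50%", ">50%"))
}

#' Apply one year of post-pruning regrowth
#'
#' Each crown's horizontal semi-axes are scaled so its volume grows by the
#' fraction looked up from its own pruning-severity class, with per-tree
#' multiplicative lognormal noise (unit mean).  The apex is unchanged: after
#' pruning, trees grow primarily along the horizontal axes.
#'
#' @param crowns crown data frame carrying a `severity` column.
#' @param growth_fraction_by_severity named numeric vector of volume growth
#'   fractions for classes `<10%`, `10-30%`, `30-50%`, `>50%`.
#' @param noise_sdlog sdlog of the per-tree lognormal multiplier.
#' @param seed integer seed.
#' @param date_label date tag for the returned truth.
#' @return `list(crowns, truth)`.
#' @export
apply_regrowth <- function(crowns,
                           growth_fraction_by_severity = c("<10%" = 0.20,
                                                           "10-30%" = 0.35,
                                                           "30-50%" = 0.60,
                                                           ">50%" = 0.80),
                           noise_sdlog = 0, seed = 1, date_label = "date3") {
  growth_fraction_by_severity <- unlist(growth_fraction_by_severity)
  if (any(growth_fraction_by_severity < 0))
    stop("growth fractions must be non-negative")
  cls <- classify_severity(100 * crowns$severity)
  g <- growth_fraction_by_severity[as.character(cls)]
  if (any(is.na(g))) stop("growth_fraction_by_severity must name all four classes")
  set.seed(seed)
  eps <- if (noise_sdlog > 0)
    exp(rnorm(nrow(crowns), -noise_sdlog^2 / 2, noise_sdlog)) else 1
  s <- sqrt((1 + g) * eps)
  crowns$a <- crowns$a * s
  crowns$b <- crowns$b * s
  list(crowns = crowns, truth = orchard_truth(crowns, date_label))
}

#' Simulate a three-date orchard study
#'
#' Builds the full multi-temporal synthetic study: terrain, a crown per
#' plantation node, and three DSM scenes — date 1 before pruning, date 2 after
#' applying each sub-plot's treatment, and date 3 one year later after
#' severity-dependent regrowth.  Exact analytic truth accompanies every date.
#'
#' @param config an [orchard_config].
#' @param pixel_size DSM pixel size (m).
#' @param margin_m bare-soil margin around the outermost grid nodes (m).
#' @param crown_params,jitter_sd passed to [generate_orchard()].
#' @param prune_params named list (per treatment) of [pruning_spec()]
#'   arguments.
#' @param growth_fraction_by_severity,growth_noise_sdlog passed to
#'   [apply_regrowth()].
#' @param noise_sd DSM noise (m) added to every date.
#' @param terrain_args extra arguments for [generate_terrain()]
#'   (e.g. `slope`, `roughness_sd`).
#' @param seed master seed; stage seeds are derived from it.
#' @return List with `config`, `terrain` and `dates` — one entry per date,
#'   each `list(scene, truth, crowns)`.
#' @export
simulate_orchard_series <- function(config = orchard_config(),
                                    pixel_size = 0.05, margin_m = 6,
                                    crown_params = list(), jitter_sd = 0.05,
                                    prune_params = list(),
                                    growth_fraction_by_severity = c("<10%" = 0.20,
                                                                    "10-30%" = 0.35,
                                                                    "30-50%" = 0.60,
                                                                    ">50%" = 0.80),
                                    growth_noise_sdlog = 0.08,
                                    noise_sd = 0, terrain_args = list(),
                                    seed = 1) {
  nodes <- grid_node_xy(config, rep(seq_len(config$n_rows), config$n_cols),
                        rep(seq_len(config$n_cols), each = config$n_rows))
  xmin <- min(nodes[, 1]) - margin_m; ymin <- min(nodes[, 2]) - margin_m
  width <- diff(range(nodes[, 1])) + 2 * margin_m
  height <- diff(range(nodes[, 2])) + 2 * margin_m
  terrain <- do.call(generate_terrain,
                     c(list(width_m = width, height_m = height,
                            pixel_size = pixel_size, xmin = xmin, ymin = ymin,
                            seed = seed %% 2147483000L + 11L, config = config),
                       terrain_args))
  orch <- generate_orchard(config, crown_params, jitter_sd,
                           seed = seed %% 2147483000L + 23L)
  crowns1 <- orch$crowns

  crowns2 <- crowns1[0, ]
  for (tr in names(config$treatment_blocks)) {
    sub <- crowns1[crowns1$treatment == tr, ]
    if (!nrow(sub)) next
    args <- prune_params[[tr]]
    if (is.null(args)) args <- list()
    args$treatment <- tr
    if (is.null(args$seed)) args$seed <- seed %% 2147483000L + 31L
    pr <- apply_pruning(sub, do.call(pruning_spec, args))
    crowns2 <- rbind(crowns2, pr$crowns)
  }
  crowns2 <- crowns2[order(crowns2$tree_id), ]

  crowns3 <- apply_regrowth(crowns2, growth_fraction_by_severity,
                            growth_noise_sdlog,
                            seed = seed %% 2147483000L + 47L)$crowns

  mk <- function(crowns, label, sub_seed) {
    scene <- multilayer_scene(render_dsm(terrain, crowns, noise_sd,
                                         seed = seed %% 2147483000L + sub_seed),
                              date_label = label)
    list(scene = scene, truth = orchard_truth(crowns, label), crowns = crowns)
  }
  list(config = config, terrain = terrain,
       dates = list(date1 = mk(crowns1, "date1", 101L),
                    date2 = mk(crowns2, "date2", 102L),
                    date3 = mk(crowns3, "date3", 103L)))
}

#' Inject photo-reconstruction artifacts (off by default in analyses)
#'
#' Emulates structure-from-motion failures: randomly deletes whole crowns
#' from the rendered DSM (collapsed reconstructions) and inserts narrow
#' elevation spikes.  Intended for robustness experiments only.
#'
#' @param dsm rendered [dsm_grid].
#' @param terrain the underlying terrain grid.
#' @param crowns crown data frame used for the render.
#' @param deletion_fraction fraction of crowns flattened back to terrain.
#' @param n_spikes number of random 1-pixel spikes.
#' @param spike_height_m spike amplitude (m).
#' @param seed integer seed.
#' @return `list(dsm, deleted_tree_ids)`.
#' @export
inject_artifacts <- function(dsm, terrain, crowns, deletion_fraction = 0.1,
                             n_spikes = 0, spike_height_m = 5, seed = 1) {
  set.seed(seed)
  elev <- dsm$elev
  del <- integer(0)
  if (deletion_fraction > 0 && nrow(crowns)) {
    del <- sort(sample(crowns$tree_id, round(deletion_fraction * nrow(crowns))))
    keep <- crowns[!crowns$tree_id %in% del, ]
    elev <- render_dsm(terrain, keep, 0)$elev + (dsm$elev - render_dsm(terrain, crowns, 0)$elev)
  }
  if (n_spikes > 0) {
    idx <- sample(length(elev), n_spikes)
    elev[idx] <- elev[idx] + spike_height_m
  }
  list(dsm = dsm_grid(elev, dsm$pixel_size, dsm$xmin, dsm$ymax, dsm$crs),
       deleted_tree_ids = del)
}
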