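#' Chessboard segmentation of a DSM into square tiles
#'
#' Partitions the raster into a regular grid of square objects of
#' `tile_size_m` ground size, anchored at the raster origin (top-left corner);
#' right/bottom edge tiles are truncated.  Only the height layer informs the
#' downstream classification, so the per-tile population standard deviation of
#' the DSM is computed here (nodata pixels excluded).
#'
#' @param dsm a [dsm_grid].
#' @param tile_size_m tile edge length in meters (default 1, i.e. 1 m2
#'   objects); must be at least one pixel.
#' @return An object of class `tile_grid`: tile dimensions, per-tile valid
#'   pixel count `n`, population SD matrix `sd_dsm`, and `label` matrix
#'   (`"unassigned"` until [coarse_classify()]).
#' @export
chessboard_segment <- function(dsm, tile_size_m = 1) {
  stopifnot(inherits(dsm, "dsm_grid"))
  px <- dsm$pixel_size
  if (tile_size_m < px)
    stop("tile_size_m (", tile_size_m, ") is smaller than one pixel (", px, " m)")
  d <- dim(dsm$elev)
  ti <- as.integer(floor((seq_len(d[1]) - 1) * px / tile_size_m)) + 1L
  tj <- as.integer(floor((seq_len(d[2]) - 1) * px / tile_size_m)) + 1L
  nt_r <- ti[d[1]]; nt_c <- tj[d[2]]
  id <- matrix(ti, d[1], d[2]) + (matrix(tj, d[1], d[2], byrow = TRUE) - 1L) * nt_r
  ntiles <- nt_r * nt_c
  z <- dsm$elev
  valid <- !dsm$nodata
  idv <- id[valid]; zv <- z[valid]
  n <- tabulate(idv, nbins = ntiles)
  s1 <- numeric(ntiles); s2 <- numeric(ntiles)
  if (length(idv)) {
    t1 <- rowsum(zv, idv); s1[as.integer(rownames(t1))] <- t1
    t2 <- rowsum(zv * zv, idv); s2[as.integer(rownames(t2))] <- t2
  }
  mu <- ifelse(n > 0, s1 / n, NA_real_)
  sdv <- ifelse(n > 0, sqrt(pmax(0, s2 / n - mu^2)), NA_real_)
  structure(list(nt_r = nt_r, nt_c = nt_c, tile_size_m = tile_size_m,
                 row_tile = ti, col_tile = tj,
                 n = matrix(n, nt_r, nt_c),
                 mean_dsm = matrix(mu, nt_r, nt_c),
                 sd_dsm = matrix(sdv, nt_r, nt_c),
                 label = matrix("unassigned", nt_r, nt_c)),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid> %d x %d tiles of %g m\n", x$nt_r, x$nt_c, x$tile_size_m))
  cat("  labels:", paste(names(table(x$label)), table(x$label), collapse = ", "), "\n")
  invisible(x)
}

#' Coarse tree / bare-soil classification of tiles
#'
#' Tiles whose DSM population standard deviation is strictly greater than
#' `sd_threshold_m` are classified as tree objects; the rest (including
#' all-nodata tiles) become bare soil.  The inequality is strict, so a tile
#' with SD exactly at the threshold is bare soil.
#'
#' @param tiles a `tile_grid` from [chessboard_segment()].
#' @param sd_threshold_m height-variability threshold in meters (default 0.10).
#' @return The `tile_grid` with `label` set to `"tree"` / `"bare_soil"`.
#' @export
coarse_classify <- function(tiles, sd_threshold_m = 0.10) {
  stopifnot(inherits(tiles, "tile_grid"))
  lab <- matrix("bare_soil", tiles$nt_r, tiles$nt_c)
  lab[!is.na(tiles$sd_dsm) & tiles$sd_dsm > sd_threshold_m] <- "tree"
  tiles$label <- lab
  tiles$sd_threshold_m <- sd_threshold_m
  tiles
}

#' Individual tree mask
#'
#' Integer label raster: 0 = bare soil, `k > 0` = tree `k`; labels are
#' contiguous `1..n_trees` and each tree is one 8-connected component.
#'
#' @param labels integer matrix of component labels.
#' @param dsm the [dsm_grid] the mask refers to (geometry is copied).
#' @return Object of class `tree_mask`.
#' @export
tree_mask <- function(labels, dsm) {
  structure(list(labels = labels, n_trees = max(0L, max(labels)),
                 pixel_size = dsm$pixel_size, xmin = dsm$xmin, ymax = dsm$ymax,
                 crs = dsm$crs),
            class = "tree_mask")
}

#' @export
print.tree_mask <- function(x, ...) {
  cat(sprintf("<tree_mask> %d trees over %d x %d px @ %g m\n",
              x$n_trees, nrow(x$labels), ncol(x$labels), x$pixel_size))
  invisible(x)
}

#' @export
plot.tree_mask <- function(x, ...) {
  d <- dim(x$labels)
  xs <- x$xmin + (seq_len(d[2]) - 0.5) * x$pixel_size
  ys <- x$ymax - (rev(seq_len(d[1])) - 0.5) * x$pixel_size
  m <- x$labels[d[1]:1, , drop = FALSE]
  image(xs, ys, t(m != 0), asp = 1, col = c("white", "forestgreen"),
        xlab = "x (m)", ylab = "y (m)", ...)
  invisible(x)
}

#' Pixel-level refinement of tree borders and tree labeling
#'
#' Tree tiles that share an edge with a bare-soil tile become border objects;
#' their pixels are re-segmented individually and each is classified by the
#' nearest class mean: a pixel is a tree iff `|DSM - mu_tree| < |DSM -
#' mu_soil|` (ties to bare soil), where `mu_tree` and `mu_soil` are the mean
#' DSM of the provisionally tree- and soil-classified pixels inside a circular
#' window of radius `window_radius_m` centred on the pixel.  Windows holding
#' no pixel of one class are widened (radius doubled, up to four times the
#' base) so the comparison sees both surrounding classes; a pixel whose
#' largest window still misses a class falls back to the class present.  The resulting binary map is labeled
#' into 8-connected components; enclosed bare-soil holes are joined into the
#' surrounding tree object, and components smaller than `min_tree_area_m2`
#' are discarded as noise.
#'
#' @param tiles classified `tile_grid` (after [coarse_classify()]).
#' @param dsm the [dsm_grid].
#' @param window_radius_m radius of the class-mean window (m).
#' @param min_tree_area_m2 minimum component area kept (m2).
#' @param connectivity 8 (default) or 4 for component labeling.
#' @param fill_holes join enclosed bare-soil holes into their tree object.
#' @return A [tree_mask].
#' @export
refine_borders <- function(tiles, dsm, window_radius_m = 1,
                           min_tree_area_m2 = 0.5, connectivity = 8,
                           fill_holes = TRUE) {
  stopifnot(inherits(tiles, "tile_grid"), inherits(dsm, "dsm_grid"))
  if (!any(tiles$label == "tree"))
    return(tree_mask(matrix(0L, nrow(dsm$elev), ncol(dsm$elev)), dsm))
  tl <- tiles$label == "tree"
  if (fill_holes) {
    # a bare-soil island fully enclosed by tree tiles cannot be seen by a
    # surface model (crowns are opaque from above); typical causes are flat
    # crown tops (apex, topping-cut plateau) whose within-tile SD falls
    # under the threshold.  Reclassify such tile islands as tree before
    # refining borders, so their high pixels cannot contaminate the soil
    # class mean.
    sc <- cc_label(!tl, eight = FALSE)
    outer_ids <- unique(c(sc[1, ], sc[nrow(sc), ], sc[, 1], sc[, ncol(sc)]))
    enclosed <- sc > 0L & !(sc %in% outer_ids)
    tl[enclosed] <- TRUE
  }
  # edge-adjacency of tree tiles to bare-soil tiles
  shift <- function(m, di, dj, fill = FALSE) {
    out <- matrix(fill, nrow(m), ncol(m))
    si <- seq_len(nrow(m)) - di; sj <- seq_len(ncol(m)) - dj
    ok_i <- si >= 1 & si <= nrow(m); ok_j <- sj >= 1 & sj <= ncol(m)
    out[ok_i, ok_j] <- m[si[ok_i], sj[ok_j], drop = FALSE]
    out
  }
  adjacent4 <- function(m) shift(m, 1, 0) | shift(m, -1, 0) |
    shift(m, 0, 1) | shift(m, 0, -1)
  # expand tile maps to pixel resolution
  exp_px <- function(m) m[tiles$row_tile, tiles$col_tile, drop = FALSE]
  valid <- !dsm$nodata
  z <- dsm$elev; z[!valid] <- 0
  tree_px <- exp_px(tl)
  final <- tree_px & valid
  ntiles <- tiles$nt_r * tiles$nt_c
  tile_id <- matrix(tiles$row_tile, length(tiles$row_tile), length(tiles$col_tile)) +
    (matrix(tiles$col_tile, length(tiles$row_tile), length(tiles$col_tile),
            byrow = TRUE) - 1L) * tiles$nt_r

  # Border tiles are refined pass by pass: a pass may expose bare-soil pixels
  # inside former tree tiles (e.g. the soil corridor between close crowns),
  # making the next ring of tree tiles border tiles.  Each tile is refined at
  # most once, so pixel assignments are never re-eroded.
  refined_tl <- matrix(FALSE, tiles$nt_r, tiles$nt_c)
  repeat {
    soil_cnt <- numeric(ntiles)
    t1 <- rowsum(as.vector(!final & valid) * 1, as.vector(tile_id))
    soil_cnt[as.integer(rownames(t1))] <- t1
    soil_in_tile <- matrix(soil_cnt > 0, tiles$nt_r, tiles$nt_c)
    border_tl <- tl & !refined_tl & adjacent4(soil_in_tile)
    if (!any(border_tl)) break
    border_px <- exp_px(border_tl)
    # class means from the current provisional classes (pixels under
    # examination still count as tree, like the tiles they came from)
    tmask <- final * 1
    smask <- (!final & valid) * 1
    # adaptive window: pixels whose window holds no pixel of one class get
    # the radius doubled (up to 4x) so the comparison always sees both
    # surrounding classes where they exist at all
    scales <- window_radius_m * c(1, 2, 4)
    remaining <- border_px & valid
    assigned <- matrix(NA_integer_, nrow(z), ncol(z))
    for (s in seq_along(scales)) {
      if (!any(remaining)) break
      R <- scales[s] / dsm$pixel_size
      sum_t <- disc_window_sum(z * tmask, R)
      cnt_t <- disc_window_sum(tmask, R)
      sum_s <- disc_window_sum(z * smask, R)
      cnt_s <- disc_window_sum(smask, R)
      a <- nearest_mean_assign(dsm$elev, remaining, sum_t, cnt_t, sum_s, cnt_s)
      take <- if (s == length(scales)) remaining
              else remaining & cnt_t > 0 & cnt_s > 0
      assigned[take] <- a[take]
      remaining <- remaining & !take
    }
    sel <- border_px & valid
    final[sel] <- assigned[sel] == 1L
    refined_tl <- refined_tl | border_tl
  }

  lab <- cc_label(final, connectivity == 8)
  if (fill_holes) lab <- fill_enclosed_holes(lab)

  # drop small components, relabel contiguously
  min_px <- max(1L, as.integer(round(min_tree_area_m2 / dsm$pixel_size^2)))
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(sizes >= min_px)
  remap <- integer(max(lab, 1L))
  remap[keep] <- seq_along(keep)
  pos <- lab > 0L
  lab[pos] <- remap[lab[pos]]
  tree_mask(lab, dsm)
}

# Reassign bare-soil regions fully enclosed by a single tree component to that
# component (4-connectivity for the background, the complement of the
# 8-connected foreground).  Part of joining tree objects into solid trees.
fill_enclosed_holes <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  sc <- cc_label(lab == 0L, eight = FALSE)
  nmax <- max(sc, 0L)
  if (nmax == 0L) return(lab)
  outer_ids <- unique(c(sc[1, ], sc[nr, ], sc[, 1], sc[, nc]))
  is_hole <- rep(TRUE, nmax)
  is_hole[outer_ids[outer_ids > 0L]] <- FALSE
  if (!any(is_hole)) return(lab)
  scv <- as.integer(sc)
  sel <- scv > 0L
  sel[sel] <- is_hole[scv[sel]]
  hole_px <- which(sel)
  rows <- ((hole_px - 1L) %% nr) + 1L
  neigh <- function(p, ok) { v <- integer(length(p)); v[ok] <- lab[p[ok]]; v }
  labs <- c(neigh(hole_px - 1L, rows > 1L),
            neigh(hole_px + 1L, rows < nr),
            neigh(hole_px - nr, hole_px - nr >= 1L),
            neigh(hole_px + nr, hole_px + nr <= nr * nc))
  grp <- rep(scv[hole_px], 4L)
  nz <- labs > 0L
  adj <- split(labs[nz], grp[nz])
  fill_val <- vapply(adj, function(v) {
    u <- unique(v)
    if (length(u) == 1L) u else 0L  # ambiguous holes (several trees) stay soil
  }, integer(1))
  map <- integer(nmax)
  map[as.integer(names(fill_val))] <- fill_val
  target <- map[scv[hole_px]]
  lab[hole_px[target > 0L]] <- target[target > 0L]
  lab
}

#' Full automatic tree delineation of a scene
#'
#' Runs the three segmentation/classification phases in sequence — chessboard
#' segmentation, coarse SD-threshold classification and pixel-level border
#' refinement with component labeling — with no user intervention.
#'
#' @param scene a [multilayer_scene] (only the DSM layer is used).
#' @param tile_size_m chessboard tile size (m).
#' @param sd_threshold_m tile SD threshold (m).
#' @param window_radius_m border-refinement window radius (m).
#' @param min_tree_area_m2 minimum tree component area (m2).
#' @param connectivity component connectivity (8 or 4).
#' @param fill_holes join enclosed holes into tree objects.
#' @return A [tree_mask] with the parameters attached as attribute `params`.
#' @export
#' @examples
#' cfg <- orchard_config(n_rows = 2, n_cols = 2, origin_xy = c(6, 6))
#' terr <- generate_terrain(24, 20, 0.1, config = cfg)
#' orch <- generate_orchard(cfg, seed = 7)
#' sc <- multilayer_scene(render_dsm(terr, orch$crowns))
#' delineate(sc)$n_trees  # 4
delineate <- function(scene, tile_size_m = 1, sd_threshold_m = 0.10,
                      window_radius_m = 1, min_tree_area_m2 = 0.5,
                      connectivity = 8, fill_holes = TRUE) {
  stopifnot(inherits(scene, "multilayer_scene"))
  tiles <- chessboard_segment(scene$dsm, tile_size_m)
  tiles <- coarse_classify(tiles, sd_threshold_m)
  mask <- refine_borders(tiles, scene$dsm, window_radius_m, min_tree_area_m2,
                         connectivity, fill_holes)
  attr(mask, "params") <- list(tile_size_m = tile_size_m,
                               sd_threshold_m = sd_threshold_m,
                               window_radius_m = window_radius_m,
                               min_tree_area_m2 = min_tree_area_m2,
                               connectivity = connectivity,
                               fill_holes = fill_holes)
  mask
}
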