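#' Local ground reference of a tree
#'
#' Mean DSM elevation of the bare-soil pixels within `buffer_m` (Euclidean
#' distance) of the tree's crown, pixels of any tree excluded.  If the buffer
#' contains no bare soil it is widened in 0.5 m steps up to `max_buffer_m`;
#' a tree still without soil ("landlocked") raises an error.
#'
#' @param mask a [tree_mask].
#' @param dsm the [dsm_grid].
#' @param tree_id label of the tree in `mask`.
#' @param buffer_m initial buffer width (m), default 1.
#' @param max_buffer_m maximum widened buffer (m).
#' @return Ground elevation in meters.
#' @export
compute_ground_reference <- function(mask, dsm, tree_id, buffer_m = 1,
                                     max_buffer_m = 3) {
  idx <- which(mask$labels == tree_id)
  if (!length(idx)) stop("tree ", tree_id, " has no pixels")
  g <- ground_ref_crop(mask$labels, dsm$elev, dsm$nodata, idx,
                       dsm$pixel_size, buffer_m, max_buffer_m)
  if (is.na(g))
    stop("landlocked tree ", tree_id, ": no bare soil within ", max_buffer_m, " m")
  g
}

# Shared worker: buffer-ring soil mean around the pixel set idx (linear
# indices into the full raster), computed on a cropped window.
ground_ref_crop <- function(labels, elev, nodata, idx, px, buffer_m, max_buffer_m) {
  nr <- nrow(labels)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  pad <- as.integer(ceiling(max_buffer_m / px)) + 1L
  i1 <- max(1L, min(rows) - pad); i2 <- min(nr, max(rows) + pad)
  j1 <- max(1L, min(cols) - pad); j2 <- min(ncol(labels), max(cols) + pad)
  lab_c <- labels[i1:i2, j1:j2, drop = FALSE]
  z_c <- elev[i1:i2, j1:j2, drop = FALSE]
  ok_c <- !nodata[i1:i2, j1:j2, drop = FALSE]
  this <- matrix(0, nrow(lab_c), ncol(lab_c))
  this[cbind(rows - i1 + 1L, cols - j1 + 1L)] <- 1
  soil <- lab_c == 0L & ok_c
  for (r in seq(buffer_m, max_buffer_m, by = 0.5)) {
    ring <- disc_window_sum(this, r / px) > 0 & this == 0
    sel <- ring & soil
    if (any(sel)) return(mean(z_c[sel]))
  }
  NA_real_
}

#' Tree height from the DSM
#'
#' Height is the maximum DSM value over the tree's pixels minus the ground
#' reference.  `height_quantile < 1` substitutes an upper quantile of the
#' pixel elevations for the raw maximum (robustification for noisy DSMs;
#' the default 1 is the plain maximum).
#'
#' @inheritParams compute_ground_reference
#' @param ground_ref ground elevation (m), from [compute_ground_reference()].
#' @param height_quantile quantile of tree-pixel DSM used as the crown top.
#' @return Height in meters (can be non-positive for degenerate trees; the
#'   feature loop flags those unreliable).
#' @export
compute_height <- function(mask, dsm, tree_id, ground_ref, height_quantile = 1) {
  z <- dsm$elev[mask$labels == tree_id]
  z <- z[!is.na(z)]
  if (!length(z)) return(NA_real_)
  top <- if (height_quantile >= 1) max(z) else quantile(z, height_quantile, names = FALSE)
  top - ground_ref
}

#' Projected canopy area of a tree
#'
#' Pixel count times the pixel area.
#'
#' @inheritParams compute_ground_reference
#' @return Area in square meters.
#' @export
compute_area <- function(mask, tree_id) {
  sum(mask$labels == tree_id) * mask$pixel_size^2
}

#' Crown volume of a tree
#'
#' Sum over the tree's pixels of pixel area times the per-pixel height above
#' the ground reference; per-pixel heights below zero are clamped to zero so
#' noisy soil pixels cannot subtract volume.
#'
#' @inheritParams compute_height
#' @return Volume in cubic meters.
#' @export
compute_volume <- function(mask, dsm, tree_id, ground_ref) {
  z <- dsm$elev[mask$labels == tree_id]
  z <- z[!is.na(z)]
  sum(pmax(0, z - ground_ref)) * mask$pixel_size^2
}

#' Assign plantation-grid (row, column) identity and treatment
#'
#' Transforms each tree centroid into grid coordinates (rotate by minus the
#' row azimuth, translate by the origin, divide by the spacings), rounds to
#' the nearest node, and clips to the grid.  A centroid further than half a
#' spacing from its node is flagged `off_grid`; when two trees round to the
#' same node the nearer centroid keeps it and the other is flagged
#' `duplicate_node` and unreliable.
#'
#' @param records tree-records data frame with `x`, `y` columns.
#' @param config an [orchard_config].
#' @return `records` with `row`, `column`, `treatment` filled in and flags
#'   updated.
#' @export
assign_grid_position <- function(records, config) {
  if (!nrow(records)) return(records)
  gc <- xy_to_grid(config, records$x, records$y)
  row <- round(gc[, "row"]); col <- round(gc[, "col"])
  resid <- pmax(abs(gc[, "row"] - pmin(pmax(row, 1), config$n_rows)),
                abs(gc[, "col"] - pmin(pmax(col, 1), config$n_cols)))
  row <- pmin(pmax(row, 1), config$n_rows)
  col <- pmin(pmax(col, 1), config$n_cols)
  off_grid <- resid > 0.5
  records$row <- as.integer(row)
  records$column <- as.integer(col)
  records$treatment <- treatment_of_row(config, records$row)
  # distance (in node units) from centroid to its assigned node
  d2 <- (gc[, "row"] - row)^2 + (gc[, "col"] - col)^2
  key <- paste(row, col)
  dup <- rep(FALSE, nrow(records))
  for (k in unique(key[duplicated(key)])) {
    at <- which(key == k)
    loser <- at[-which.min(d2[at])]
    dup[loser] <- TRUE
  }
  flag <- records$flag
  if (is.null(flag)) flag <- rep("", nrow(records))
  flag <- ifelse(off_grid, paste0(flag, ";off_grid"), flag)
  flag <- ifelse(dup, paste0(flag, ";duplicate_node"), flag)
  records$flag <- sub("^;", "", flag)
  records$reliable <- records$reliable & !off_grid & !dup
  records
}

#' Per-tree feature extraction loop
#'
#' Phase 4 of the analysis: every labeled tree is individually analyzed —
#' ground reference from the bare-soil buffer, height from the maximum DSM
#' value, projected area from the pixel count, volume from the per-pixel
#' height sum, centroid from the pixel centers — and, when a plantation
#' layout is supplied, the tree's (row, column) identity and treatment.
#'
#' A tree is flagged unreliable when it is landlocked, its crown mask is more
#' than `nodata_unreliable_frac` nodata, its height is non-positive, or it
#' loses a grid-node tie.
#'
#' @param mask a [tree_mask] from [delineate()].
#' @param scene the [multilayer_scene] the mask was derived from.
#' @param config optional [orchard_config] for (row, column) assignment.
#' @param buffer_m,max_buffer_m bare-soil buffer widths (m).
#' @param height_quantile see [compute_height()].
#' @param nodata_unreliable_frac nodata fraction above which a crown is
#'   flagged unreliable.
#' @return A data frame (class `tree_records`) with one row per tree:
#'   `tree_id, row, column, x, y, treatment, date_label, area_m2, height_m,
#'   volume_m3, reliable, flag, mask_label`, sorted by (row, column) when a
#'   config is given.
#' @export
extract_features <- function(mask, scene, config = NULL, buffer_m = 1,
                             max_buffer_m = 3, height_quantile = 1,
                             nodata_unreliable_frac = 0.2) {
  stopifnot(inherits(mask, "tree_mask"), inherits(scene, "multilayer_scene"))
  dsm <- scene$dsm
  n <- mask$n_trees
  empty <- data.frame(tree_id = integer(0), row = integer(0), column = integer(0),
                      x = numeric(0), y = numeric(0), treatment = character(0),
                      date_label = character(0), area_m2 = numeric(0),
                      height_m = numeric(0), volume_m3 = numeric(0),
                      reliable = logical(0), flag = character(0),
                      mask_label = integer(0), stringsAsFactors = FALSE)
  if (n == 0L) return(structure(empty, class = c("tree_records", "data.frame")))
  labv <- mask$labels
  pos <- which(labv > 0L)
  idx_by_tree <- split(pos, labv[pos])
  px <- dsm$pixel_size
  nr <- nrow(labv)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    idx <- idx_by_tree[[as.character(k)]]
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    xy <- px_to_xy(dsm, rows, cols)
    z <- dsm$elev[idx]
    nodata_frac <- mean(is.na(z))
    zv <- z[!is.na(z)]
    flag <- character(0)
    gref <- ground_ref_crop(labv, dsm$elev, dsm$nodata, idx, px,
                            buffer_m, max_buffer_m)
    if (is.na(gref)) flag <- c(flag, "landlocked")
    top <- if (!length(zv)) NA_real_
           else if (height_quantile >= 1) max(zv)
           else quantile(zv, height_quantile, names = FALSE)
    height <- top - gref
    volume <- if (is.na(gref)) NA_real_ else sum(pmax(0, zv - gref)) * px^2
    if (!is.na(height) && height <= 0) flag <- c(flag, "non_positive_height")
    if (nodata_frac > nodata_unreliable_frac) flag <- c(flag, "nodata")
    out[[k]] <- data.frame(
      tree_id = k, row = NA_integer_, column = NA_integer_,
      x = mean(xy[, 1]), y = mean(xy[, 2]),
      treatment = NA_character_, date_label = scene$date_label,
      area_m2 = length(idx) * px^2, height_m = height, volume_m3 = volume,
      reliable = length(flag) == 0L, flag = paste(flag, collapse = ";"),
      mask_label = k, stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, out)
  if (!is.null(config)) {
    rec <- assign_grid_position(rec, config)
    rec <- rec[order(rec$row, rec$column, rec$tree_id), ]
    rec$tree_id <- seq_len(nrow(rec))
  }
  rownames(rec) <- NULL
  structure(rec, class = c("tree_records", "data.frame"))
}

#' @export
print.tree_records <- function(x, ...) {
  cat(sprintf("<tree_records> %d trees (%s reliable), date %s\n",
              nrow(x),
              if (is.null(x$reliable)) "?" else sum(x$reliable),
              paste(unique(x$date_label), collapse = ",")))
  print.data.frame(head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' @export
summary.tree_records <- function(object, ...) {
  ok <- object[object$reliable, ]
  s <- function(v) c(mean = mean(v), sd = sd(v), min = min(v), max = max(v))
  res <- rbind(area_m2 = s(ok$area_m2), height_m = s(ok$height_m),
               volume_m3 = s(ok$volume_m3))
  cat(sprintf("%d trees, %d reliable\n", nrow(object), nrow(ok)))
  print(round(res, 2))
  invisible(res)
}

# Outer boundary polygon of one labeled component, in world coordinates.
component_polygon <- function(mask, tree_id) {
  lab <- mask$labels
  nr <- nrow(lab)
  idx <- which(lab == tree_id)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  i1 <- max(1L, min(rows) - 2L); i2 <- min(nr, max(rows) + 2L)
  j1 <- max(1L, min(cols) - 2L); j2 <- min(ncol(lab), max(cols) + 2L)
  m <- (lab[i1:i2, j1:j2, drop = FALSE] == tree_id) * 1
  m <- rbind(0, cbind(0, m, 0), 0)  # pad so the contour closes
  cl <- contourLines(seq_len(nrow(m)), seq_len(ncol(m)), m, levels = 0.5)
  if (!length(cl)) return(NULL)
  areas <- vapply(cl, function(c0) abs(sum(c0$x * c(c0$y[-1], c0$y[1]) -
                                            c0$y * c(c0$x[-1], c0$x[1])) / 2), 0)
  ring <- cl[[which.max(areas)]]
  grow <- ring$x - 1 + i1 - 1  # back to global fractional row index
  gcol <- ring$y - 1 + j1 - 1
  x <- mask$xmin + (gcol - 0.5) * mask$pixel_size
  y <- mask$ymax - (grow - 0.5) * mask$pixel_size
  cbind(x = c(x, x[1]), y = c(y, y[1]))
}

#' Export per-tree outputs as vector and table files
#'
#' Writes one GeoJSON polygon feature per tree (attributes: tree id, row,
#' column, centroid, area, height, volume, date) and a CSV feature table with
#' one row per tree per date.  Geometric features are formatted with 2
#' decimals in the CSV; coordinates keep full precision.
#'
#' @param records a `tree_records` data frame.
#' @param mask the [tree_mask] the records came from (polygons are traced
#'   from it); may be `NULL` to skip the vector file.
#' @param vector_path GeoJSON output path (or `NULL`).
#' @param table_path CSV output path (or `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_tree_outputs <- function(records, mask = NULL, vector_path = NULL,
                               table_path = NULL) {
  if (!nrow(records)) stop("no tree records to write")
  written <- character(0)
  if (!is.null(table_path)) {
    tab <- as.data.frame(records)
    for (cn in c("area_m2", "height_m", "volume_m3"))
      tab[[cn]] <- sprintf("%.2f", tab[[cn]])
    tryCatch(write.csv(tab, table_path, row.names = FALSE, quote = FALSE),
             error = function(e) stop("cannot write ", table_path, ": ",
                                      conditionMessage(e)))
    written <- c(written, table_path)
  }
  if (!is.null(vector_path)) {
    if (is.null(mask)) stop("a tree_mask is required to write polygons")
    feats <- lapply(seq_len(nrow(records)), function(i) {
      r <- records[i, ]
      ml <- if (!is.null(r$mask_label)) r$mask_label else r$tree_id
      poly <- component_polygon(mask, ml)
      if (is.null(poly)) return(NULL)
      list(type = "Feature",
           properties = list(tree_id = r$tree_id, row = r$row, column = r$column,
                             x = r$x, y = r$y, area_m2 = r$area_m2,
                             height_m = r$height_m, volume_m3 = r$volume_m3,
                             date = r$date_label, treatment = r$treatment,
                             reliable = r$reliable),
           geometry = list(type = "Polygon",
                           coordinates = list(lapply(seq_len(nrow(poly)),
                                                     function(j) unname(poly[j, ])))))
    })
    feats <- feats[!vapply(feats, is.null, TRUE)]
    gj <- list(type = "FeatureCollection",
               crs_label = if (is.na(mask$crs)) NULL else mask$crs,
               features = feats)
    tryCatch(jsonlite::write_json(gj, vector_path, auto_unbox = TRUE, digits = NA,
                                  null = "null"),
             error = function(e) stop("cannot write ", vector_path, ": ",
                                      conditionMessage(e)))
    written <- c(written, vector_path)
  }
  invisible(written)
}

#' Read a tree feature table written by [write_tree_outputs()]
#'
#' @param path CSV path.
#' @return A `tree_records` data frame.
#' @export
read_tree_table <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  structure(rec, class = c("tree_records", "data.frame"))
}
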