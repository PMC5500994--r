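#' Plantation layout configuration
#'
#' Describes a regular single-tree planting grid: where grid node (row 1,
#' column 1) sits in projected coordinates, the azimuth of the within-row
#' axis, the spacings, the grid dimensions and which rows belong to which
#' pruning treatment.  Defaults reproduce an intensive olive layout of
#' 27 rows x 24 trees at 8 x 4 m spacing divided into three 9-row sub-plots
#' (traditional / adapted / mechanical).
#'
#' @param origin_xy projected coordinates (m) of grid node (row 1, col 1).
#' @param row_azimuth_deg orientation of the within-row (column) axis,
#'   degrees counter-clockwise from the +x (east) axis.  Rows are stacked
#'   along the perpendicular axis.
#' @param row_spacing_m meters between adjacent rows (default 8).
#' @param tree_spacing_m meters between adjacent trees within a row (default 4).
#' @param n_rows,n_cols grid dimensions (default 27 x 24).
#' @param treatment_blocks named list mapping treatment name to the integer
#'   row numbers it occupies; must partition `1:n_rows`.
#' @return An object of class `orchard_config`.
#' @export
#' @examples
#' cfg <- orchard_config()
#' cfg$n_rows * cfg$n_cols  # 648 trees
orchard_config <- function(origin_xy = c(10, 10),
                           row_azimuth_deg = 0,
                           row_spacing_m = 8,
                           tree_spacing_m = 4,
                           n_rows = 27,
                           n_cols = 24,
                           treatment_blocks = list(traditional = 1:9,
                                                   adapted = 10:18,
                                                   mechanical = 19:27)) {
  stopifnot(row_spacing_m > 0, tree_spacing_m > 0, n_rows >= 1, n_cols >= 1)
  all_rows <- sort(unlist(treatment_blocks, use.names = FALSE))
  if (!identical(as.integer(all_rows), seq_len(n_rows)))
    stop("treatment_blocks must partition rows 1..n_rows without overlap")
  structure(list(origin_xy = as.numeric(origin_xy),
                 row_azimuth_deg = row_azimuth_deg,
                 row_spacing_m = row_spacing_m,
                 tree_spacing_m = tree_spacing_m,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 treatment_blocks = treatment_blocks),
            class = "orchard_config")
}

#' @export
print.orchard_config <- function(x, ...) {
  cat(sprintf("<orchard_config> %d rows x %d cols, %g x %g m spacing, azimuth %g deg\n",
              x$n_rows, x$n_cols, x$row_spacing_m, x$tree_spacing_m, x$row_azimuth_deg))
  for (tr in names(x$treatment_blocks))
    cat(sprintf("  %-12s rows %s\n", tr,
                paste(range(x$treatment_blocks[[tr]]), collapse = "-")))
  invisible(x)
}

# Unit axes of the grid: u along columns (tree spacing), v along rows.
grid_axes <- function(config) {
  a <- config$row_azimuth_deg * pi / 180
  list(u = c(cos(a), sin(a)), v = c(-sin(a), cos(a)))
}

#' Projected coordinates of plantation grid nodes
#'
#' @param config an [orchard_config].
#' @param row,col 1-based grid indices (vectorized).
#' @return Two-column matrix of x/y coordinates (m).
#' @export
grid_node_xy <- function(config, row, col) {
  ax <- grid_axes(config)
  dx <- (col - 1) * config$tree_spacing_m
  dy <- (row - 1) * config$row_spacing_m
  cbind(x = config$origin_xy[1] + dx * ax$u[1] + dy * ax$v[1],
        y = config$origin_xy[2] + dx * ax$u[2] + dy * ax$v[2])
}

# Fractional (row, col) grid coordinates of projected points.
xy_to_grid <- function(config, x, y) {
  ax <- grid_axes(config)
  dx <- x - config$origin_xy[1]
  dy <- y - config$origin_xy[2]
  cbind(row = (dx * ax$v[1] + dy * ax$v[2]) / config$row_spacing_m + 1,
        col = (dx * ax$u[1] + dy * ax$u[2]) / config$tree_spacing_m + 1)
}

#' Treatment name for given rows
#'
#' @param config an [orchard_config].
#' @param row integer row numbers (vectorized).
#' @return Character vector of treatment names (`NA` for out-of-range rows).
#' @export
treatment_of_row <- function(config, row) {
  out <- rep(NA_character_, length(row))
  for (tr in names(config$treatment_blocks))
    out[row %in% config$treatment_blocks[[tr]]] <- tr
  out
}
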