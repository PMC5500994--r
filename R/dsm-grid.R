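#' Geo-referenced elevation grid
#'
#' A `dsm_grid` holds a single-band digital surface model: a matrix of
#' elevations in meters above datum together with an axis-aligned, north-up
#' affine transform.  Row 1 of the matrix is the northernmost row; pixel
#' centers carry the coordinates, so pixel `(i, j)` is at
#' `x = xmin + (j - 1/2) * pixel_size`, `y = ymax - (i - 1/2) * pixel_size`.
#'
#' @param elevations numeric matrix of elevations (m); `NA` marks nodata.
#' @param pixel_size ground size of one (square) pixel in meters.
#' @param xmin,ymax projected coordinates (m) of the outer corner of the
#'   top-left pixel.
#' @param crs free-text label of the coordinate reference system (e.g.
#'   `"UTM zone 30N / WGS84"`), or `NA` for raw pixel units.
#'
#' @return An object of class `dsm_grid`: a list with elements `elev`,
#'   `pixel_size`, `xmin`, `ymax`, `crs` and `nodata` (logical matrix).
#' @export
#' @examples
#' g <- dsm_grid(matrix(100, 20, 30), pixel_size = 0.5)
#' dim(g$elev); g$pixel_size
dsm_grid <- function(elevations, pixel_size, xmin = 0,
                     ymax = nrow(elevations) * pixel_size, crs = NA_character_) {
  stopifnot(is.matrix(elevations), is.numeric(pixel_size), length(pixel_size) == 1)
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be a positive number of meters")
  nodata <- is.na(elevations)
  if (any(!is.finite(elevations) & !nodata))
    stop("elevations must be finite wherever not nodata")
  structure(list(elev = elevations, pixel_size = pixel_size,
                 xmin = xmin, ymax = ymax, crs = crs, nodata = nodata),
            class = "dsm_grid")
}

#' @export
print.dsm_grid <- function(x, ...) {
  d <- dim(x$elev)
  cat(sprintf("<dsm_grid> %d x %d px @ %.4g m (%.4g x %.4g m)\n",
              d[1], d[2], x$pixel_size, d[2] * x$pixel_size, d[1] * x$pixel_size))
  cat(sprintf("  origin (xmin, ymax): %.3f, %.3f   crs: %s\n", x$xmin, x$ymax,
              ifelse(is.na(x$crs), "<pixel units>", x$crs)))
  rng <- range(x$elev, na.rm = TRUE)
  cat(sprintf("  elevation range: %.3f .. %.3f m   nodata: %d px\n",
              rng[1], rng[2], sum(x$nodata)))
  invisible(x)
}

#' @export
plot.dsm_grid <- function(x, ...) {
  d <- dim(x$elev)
  xs <- x$xmin + (seq_len(d[2]) - 0.5) * x$pixel_size
  ys <- x$ymax - (rev(seq_len(d[1])) - 0.5) * x$pixel_size
  image(xs, ys, t(x$elev[d[1]:1, , drop = FALSE]), asp = 1,
        col = gray(seq(0, 1, length.out = 64)),
        xlab = "x (m)", ylab = "y (m)", ...)
  invisible(x)
}

# Projected coordinates of pixel centers for (row, col) index vectors.
px_to_xy <- function(grid, row, col) {
  cbind(x = grid$xmin + (col - 0.5) * grid$pixel_size,
        y = grid$ymax - (row - 0.5) * grid$pixel_size)
}

# Inverse of px_to_xy: fractional pixel indices of projected points.
xy_to_px <- function(grid, x, y) {
  cbind(row = (grid$ymax - y) / grid$pixel_size + 0.5,
        col = (x - grid$xmin) / grid$pixel_size + 0.5)
}

same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$elev), dim(b$elev)) &&
    abs(a$pixel_size - b$pixel_size) < tol &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol
}

#' Read a DSM raster from an ESRI ASCII Grid file
#'
#' Reads a single-band elevation raster in ESRI ASCII Grid format (`.asc`),
#' the plain-text interchange raster understood by GDAL/QGIS/ArcGIS.  Nodata
#' cells are converted to `NA` and recorded in the nodata mask.  A sidecar
#' `.prj` file, when present, supplies the CRS label; without one a warning is
#' issued and coordinates are interpreted in raw map units.
#'
#' @param path path to the `.asc` file.
#' @return A [dsm_grid].
#' @export
read_dsm <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "r"); on.exit(close(con))
  hdr <- character(0); vals <- list()
  repeat {
    pos <- seek(con)
    line <- readLines(con, n = 1)
    if (!length(line)) stop("truncated ASCII grid: ", path)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 2 && grepl("^[A-Za-z_]", tok[1])) {
      hdr <- c(hdr, tolower(tok[1])); vals[[tolower(tok[1])]] <- as.numeric(tok[2])
    } else { seek(con, pos); break }
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% hdr)) stop("ASCII grid header missing ", paste(setdiff(need, hdr), collapse = ", "))
  nc <- as.integer(vals$ncols); nr <- as.integer(vals$nrows)
  px <- vals$cellsize
  if (!is.null(vals$xllcorner)) xll <- vals$xllcorner
  else if (!is.null(vals$xllcenter)) xll <- vals$xllcenter - px / 2
  else xll <- 0
  if (!is.null(vals$yllcorner)) yll <- vals$yllcorner
  else if (!is.null(vals$yllcenter)) yll <- vals$yllcenter - px / 2
  else yll <- 0
  z <- scan(con, what = double(), n = nr * nc, quiet = TRUE)
  if (length(z) != nr * nc) stop("ASCII grid data shorter than header promises")
  if (!is.null(vals$nodata_value)) z[z == vals$nodata_value] <- NA_real_
  m <- matrix(z, nrow = nr, ncol = nc, byrow = TRUE)
  prj <- paste0(tools::file_path_sans_ext(path), ".prj")
  crs <- if (file.exists(prj)) paste(readLines(prj, warn = FALSE), collapse = " ")
         else NA_character_
  if (is.na(crs))
    warning("no .prj sidecar for ", basename(path), "; proceeding in raw map units")
  dsm_grid(m, pixel_size = px, xmin = xll, ymax = yll + nr * px, crs = crs)
}

#' Write a DSM raster to an ESRI ASCII Grid file
#'
#' Elevations are written with 17 significant digits so a write/read
#' round-trip reproduces them bit-exactly; nodata cells are encoded as -9999.
#' The CRS label, when present, goes to a `.prj` sidecar.
#'
#' @param grid a [dsm_grid].
#' @param path output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_dsm <- function(grid, path) {
  stopifnot(inherits(grid, "dsm_grid"))
  d <- dim(grid$elev)
  hdr <- c(sprintf("ncols %d", d[2]),
           sprintf("nrows %d", d[1]),
           sprintf("xllcorner %.10f", grid$xmin),
           sprintf("yllcorner %.10f", grid$ymax - d[1] * grid$pixel_size),
           sprintf("cellsize %.10f", grid$pixel_size),
           "NODATA_value -9999")
  z <- grid$elev
  z[is.na(z)] <- -9999
  body <- apply(z, 1, function(r) paste(formatC(r, format = "g", digits = 17), collapse = " "))
  ok <- tryCatch({ writeLines(c(hdr, body), path); TRUE },
                 error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)))
  if (!is.na(grid$crs))
    writeLines(grid$crs, paste0(tools::file_path_sans_ext(path), ".prj"))
  invisible(path)
}

#' Multi-layer scene: DSM plus optional co-registered RGB
#'
#' Bundles the height layer with an optional 3-band RGB orthomosaic into the
#' four-layer (R, G, B, height) scene the delineation consumes.  Only the DSM
#' drives segmentation and classification; RGB is carried for visual QC.
#'
#' @param dsm a [dsm_grid].
#' @param rgb optional `nrow x ncol x 3` array with values in `[0, 1]`,
#'   co-registered with `dsm`.
#' @param date_label free-text date tag (e.g. `"date1"`).
#' @return An object of class `multilayer_scene`.
#' @export
multilayer_scene <- function(dsm, rgb = NULL, date_label = "date1") {
  stopifnot(inherits(dsm, "dsm_grid"))
  if (!is.null(rgb)) {
    if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3 ||
        !identical(dim(rgb)[1:2], dim(dsm$elev)))
      stop("rgb is not co-registered with the DSM (shape mismatch)")
  }
  structure(list(dsm = dsm, rgb = rgb, date_label = date_label),
            class = "multilayer_scene")
}

#' @export
print.multilayer_scene <- function(x, ...) {
  cat(sprintf("<multilayer_scene> %s  (%s RGB)\n", x$date_label,
              if (is.null(x$rgb)) "no" else "with"))
  print(x$dsm)
  invisible(x)
}

#' Read a DSM (and optional RGB orthomosaic) into a scene
#'
#' @param dsm_path path to the DSM ASCII grid (`.asc`).
#' @param rgb_path optional path to a 3-band RGB TIFF co-registered with the
#'   DSM (same pixel grid).
#' @param date_label free-text date tag.
#' @return A [multilayer_scene].
#' @export
read_scene <- function(dsm_path, rgb_path = NULL, date_label = "date1") {
  dsm <- read_dsm(dsm_path)
  rgb <- NULL
  if (!is.null(rgb_path)) {
    if (!file.exists(rgb_path)) stop("no such file: ", rgb_path)
    rgb <- tiff::readTIFF(rgb_path)
    if (length(dim(rgb)) != 3 || dim(rgb)[3] < 3)
      stop("RGB raster must have 3 bands")
    rgb <- rgb[, , 1:3, drop = FALSE]
    if (!identical(dim(rgb)[1:2], dim(dsm$elev)))
      stop("RGB and DSM are not co-registered: pixel grids differ (",
           paste(dim(rgb)[1:2], collapse = "x"), " vs ",
           paste(dim(dsm$elev), collapse = "x"), ")")
  }
  multilayer_scene(dsm, rgb, date_label)
}
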