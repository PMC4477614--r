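#' Georeferenced raster grid
#'
#' Lightweight container for single- or multi-band georeferenced imagery on a
#' north-up grid with square pixels.  Bands are numeric matrices (rows = image
#' rows, top first); the transform maps pixel indices to world coordinates in
#' meters on a local planar frame, y increasing northward.  Pixel \code{(1,1)}
#' is the top-left pixel and covers the half-open world square
#' \code{[x0, x0+gsd) x (y0-gsd, y0]}; its center is at
#' \code{(x0 + gsd/2, y0 - gsd/2)}.
#'
#' @param bands a numeric matrix (single band) or named list of matrices with
#'   identical dimensions.  Missing values (\code{NA}) denote nodata.
#' @param x0,y0 world coordinates (m) of the top-left corner of pixel (1,1).
#' @param gsd ground sampling distance, meters per pixel (square pixels).
#' @param band_names optional character vector naming the bands; defaults to
#'   the list names.
#' @return an object of class \code{geogrid}.
#' @export
geogrid <- function(bands, x0 = 0, y0 = 0, gsd = 1, band_names = NULL) {
  if (is.matrix(bands)) bands <- list(bands)
  if (!is.null(band_names)) names(bands) <- band_names
  if (is.null(names(bands)) || any(!nzchar(names(bands))))
    stop("bands must be named")
  dims <- vapply(bands, dim, integer(2))
  if (!all(dims == dims[, 1])) stop("all bands must share dimensions")
  stopifnot(gsd > 0)
  structure(list(bands = bands,
                 transform = list(x0 = unname(x0), y0 = unname(y0),
                                  gsd = unname(gsd))),
            class = "geogrid")
}

#' @export
dim.geogrid <- function(x) c(dim(x$bands[[1]]), length(x$bands))

#' @export
print.geogrid <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<geogrid> %d x %d pixels, %d band(s): %s\n", d[1], d[2], d[3],
              paste(names(x$bands), collapse = ", ")))
  cat(sprintf("  gsd %.4g m/px, top-left corner (%.3f, %.3f)\n",
              x$transform$gsd, x$transform$x0, x$transform$y0))
  invisible(x)
}

#' Band names of a raster
#' @param r a \code{geogrid}.
#' @return character vector of band names.
#' @export
band_names <- function(r) names(r$bands)

#' World coordinates of pixel centers
#'
#' @param r a \code{geogrid}.
#' @return list with numeric vectors \code{x} (per column) and \code{y}
#'   (per row) of pixel-center world coordinates.
#' @export
pixel_centers <- function(r) {
  d <- dim(r$bands[[1]]); tr <- r$transform
  list(x = tr$x0 + (seq_len(d[2]) - 0.5) * tr$gsd,
       y = tr$y0 - (seq_len(d[1]) - 0.5) * tr$gsd)
}

#' Convert world coordinates to (row, col) pixel indices
#'
#' Uses the half-open pixel-area convention: a point on a shared pixel edge
#' belongs to the pixel to its right/below in image axes.
#'
#' @param r a \code{geogrid}.
#' @param x,y world coordinates (m).
#' @return integer matrix with columns \code{row}, \code{col}; indices may lie
#'   outside the grid.
#' @export
world_to_pixel <- function(r, x, y) {
  tr <- r$transform
  cbind(row = as.integer(floor((tr$y0 - y) / tr$gsd)) + 1L,
        col = as.integer(floor((x - tr$x0) / tr$gsd)) + 1L)
}

#' World bounding box of a raster
#' @param r a \code{geogrid}.
#' @return numeric vector \code{c(xmin, ymin, xmax, ymax)} in meters.
#' @export
raster_extent <- function(r) {
  d <- dim(r$bands[[1]]); tr <- r$transform
  c(xmin = tr$x0, ymin = tr$y0 - d[1] * tr$gsd,
    xmax = tr$x0 + d[2] * tr$gsd, ymax = tr$y0)
}

#' Write a raster as TIFF with world-file georeferencing
#'
#' Writes the pixel data as TIFF, the affine transform as an ESRI world file
#' (\code{.tfw}) and band names / storage metadata as a JSON sidecar
#' (\code{.aux.json}).  \code{type = "uint16"} stores integers 0..65535
#' losslessly; \code{type = "float"} stores 32-bit floats, linearly scaled
#' into the unit interval (scale recorded in the sidecar).
#'
#' @param r a \code{geogrid}.
#' @param path output path (\code{.tif}).
#' @param type storage type, \code{"float"} or \code{"uint16"}.
#' @return \code{path}, invisibly.
#' @export
write_raster <- function(r, path, type = c("float", "uint16")) {
  type <- match.arg(type)
  d <- dim(r$bands[[1]])
  arr <- array(unlist(r$bands, use.names = FALSE), c(d[1], d[2], length(r$bands)))
  nas <- is.na(arr)
  if (all(nas)) stop("raster has no valid pixels")
  if (type == "uint16") {
    nodata <- 65535
    arr[nas] <- nodata
    if (any(arr < 0 | arr > 65535)) stop("uint16 values out of range")
    tiff::writeTIFF(arr / 65535, path, bits.per.sample = 16L)
    scale <- 65535; offset <- 0
  } else {
    vals <- arr[!nas]
    lo <- min(vals); hi <- max(vals)
    # nodata sentinel strictly below the data range so it cannot collide
    nodata <- lo - max(1, hi - lo)
    arr[nas] <- nodata
    offset <- min(arr)
    scale <- max(arr) - offset
    if (scale == 0) scale <- 1
    tiff::writeTIFF((arr - offset) / scale, path, bits.per.sample = 32L)
  }
  tfw <- sub("\\.[^.]+$", ".tfw", path)
  tr <- r$transform
  writeLines(formatC(c(tr$gsd, 0, 0, -tr$gsd,
                       tr$x0 + tr$gsd / 2, tr$y0 - tr$gsd / 2),
                     format = "g", digits = 15), tfw)
  meta <- list(band_names = names(r$bands), type = type,
               scale = scale, offset = offset)
  if (any(nas)) meta$nodata <- nodata
  jsonlite::write_json(meta, paste0(path, ".aux.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a raster written by \code{write_raster}
#'
#' @param path path to the \code{.tif} file (expects the \code{.tfw} and
#'   \code{.aux.json} sidecars next to it).
#' @return a \code{geogrid}.
#' @export
read_raster <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".aux.json"), simplifyVector = TRUE)
  # libtiff warns about non-color extra samples on n-band scientific TIFFs
  arr <- suppressWarnings(tiff::readTIFF(path))
  if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1))
  tfw <- as.numeric(readLines(sub("\\.[^.]+$", ".tfw", path)))
  gsd <- tfw[1]
  tol <- if (meta$type == "uint16") 0.5 else 1e-5 * meta$scale
  bands <- lapply(seq_len(dim(arr)[3]), function(k) {
    m <- arr[, , k] * meta$scale + meta$offset
    if (meta$type == "uint16") m <- round(m)
    if (is.numeric(meta$nodata)) m[abs(m - meta$nodata) <= tol] <- NA
    m
  })
  names(bands) <- meta$band_names
  geogrid(bands, x0 = tfw[5] - gsd / 2, y0 = tfw[6] + gsd / 2, gsd = gsd)
}
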