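# Per-row regions of interest and vegetation-only reflectance extraction.

#' Construct a region-of-interest set
#'
#' @param entries data.frame with columns \code{plot_id}, \code{row_index};
#'   optionally \code{veg_threshold} (per-entry NDVI vegetation cutoff).
#' @param polygons list (parallel to \code{entries}) of polygons, each a
#'   matrix/data.frame with columns \code{x}, \code{y} in world meters
#'   (closed or open ring).
#' @param provenance \code{"manual"} or \code{"auto"}.
#' @return an object of class \code{roi_set}.
#' @export
roi_set <- function(entries, polygons, provenance = c("manual", "auto")) {
  provenance <- match.arg(provenance)
  stopifnot(nrow(entries) == length(polygons))
  key <- paste(entries$plot_id, entries$row_index)
  if (anyDuplicated(key))
    stop("duplicate (plot_id, row_index): ", key[duplicated(key)][1])
  polygons <- lapply(seq_along(polygons), function(i) {
    p <- as.matrix(polygons[[i]])[, 1:2, drop = FALSE]
    colnames(p) <- c("x", "y")
    if (nrow(p) < 3) stop("polygon for entry ", key[i], " has < 3 vertices")
    # drop an explicit closing vertex
    if (all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    if (self_intersects(p))
      stop("invalid geometry: self-intersecting polygon for entry ", key[i])
    p
  })
  structure(list(entries = entries, polygons = polygons,
                 provenance = provenance), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d entries over %d plots (provenance: %s)\n",
              nrow(x$entries), length(unique(x$entries$plot_id)),
              x$provenance))
  invisible(x)
}

# O(n^2) segment-pair crossing test; ROIs are small polygons.
self_intersects <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, p[c(2:n, 1), ])
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next
      p1 <- seg[i, 1:2]; p2 <- seg[i, 3:4]; p3 <- seg[j, 1:2]; p4 <- seg[j, 3:4]
      d1 <- cross(p4[1] - p3[1], p4[2] - p3[2], p1[1] - p3[1], p1[2] - p3[2])
      d2 <- cross(p4[1] - p3[1], p4[2] - p3[2], p2[1] - p3[1], p2[2] - p3[2])
      d3 <- cross(p2[1] - p1[1], p2[2] - p1[2], p3[1] - p1[1], p3[2] - p1[2])
      d4 <- cross(p2[1] - p1[1], p2[2] - p1[2], p4[1] - p1[1], p4[2] - p1[2])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Write a region-of-interest set as GeoJSON
#'
#' @param rois an \code{roi_set}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_roi <- function(rois, path) {
  feats <- lapply(seq_len(nrow(rois$entries)), function(i) {
    p <- rois$polygons[[i]]
    ring <- rbind(p, p[1, , drop = FALSE])
    props <- as.list(rois$entries[i, , drop = FALSE])
    props$provenance <- rois$provenance
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(k) unname(ring[k, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a region-of-interest set from GeoJSON
#'
#' @param path a GeoJSON FeatureCollection of polygons with properties
#'   \code{plot_id} and \code{row_index}.
#' @return an \code{roi_set} (provenance taken from the file, default
#'   \code{manual}).
#' @export
load_roi <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  entries <- NULL; polys <- list(); prov <- "manual"
  for (i in seq_along(gj$features)) {
    ft <- gj$features[[i]]
    if (!identical(ft$geometry$type, "Polygon"))
      stop("parse error in feature ", i, ": geometry is not a Polygon")
    ring <- ft$geometry$coordinates[[1]]
    p <- do.call(rbind, lapply(ring, function(v) as.numeric(unlist(v))))
    pr <- ft$properties
    if (is.null(pr$plot_id) || is.null(pr$row_index))
      stop("parse error in feature ", i, ": missing plot_id/row_index")
    row <- data.frame(plot_id = as.character(pr$plot_id),
                      row_index = as.integer(pr$row_index),
                      stringsAsFactors = FALSE)
    if (!is.null(pr$veg_threshold))
      row$veg_threshold <- as.numeric(pr$veg_threshold)
    if (!is.null(pr$provenance)) prov <- as.character(pr$provenance)
    entries <- rbind(entries, row)
    polys[[i]] <- p
  }
  roi_set(entries, polys, provenance = prov)
}

# Otsu threshold on a numeric vector: exhaustive search over histogram bins
# maximizing between-class variance.
otsu_threshold <- function(v, nbins = 256) {
  v <- v[is.finite(v)]
  if (length(v) < 2 || diff(range(v)) == 0) return(stats::median(v))
  br <- seq(min(v), max(v), length.out = nbins + 1)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins)
  w <- cumsum(h); mu <- cumsum(h * seq_len(nbins))
  tot <- w[nbins]; mtot <- mu[nbins]
  between <- (mtot * w - mu * tot)^2 / (w * (tot - w))
  between[!is.finite(between)] <- -Inf
  k <- which.max(between[-nbins])
  (br[k] + br[k + 1]) / 2
}

ndvi_matrix <- function(raster) {
  nir <- raster$bands[["nir"]]; red <- raster$bands[["red"]]
  s <- nir + red
  out <- (nir - red) / s
  out[s == 0] <- NA
  out
}

#' Derive per-row regions of interest from the layout and an NDVI raster
#'
#' Automates the manual center-of-row ROI step.  Each layout row centerline
#' is buffered by \code{buffer} meters into a rectangle, inset by
#' \code{buffer} at both row ends so the ROI stays in the center of the row,
#' clear of edge pixels blurred by demosaicing.  A per-row NDVI vegetation
#' cutoff is estimated by Otsu's method inside a wider strip (half the row
#' spacing on each side of the centerline), which always contains both soil
#' and that row's canopy, so the cutoff adapts to each row's vigor;
#' downstream extraction then keeps canopy and drops soil.  Rows falling
#' outside the raster are dropped with a warning.
#'
#' @param raster a \code{geogrid} with \code{red} and \code{nir} bands (NDVI
#'   is computed internally).
#' @param layout a \code{trial_layout}.
#' @param buffer half-width of the ROI around the row centerline, m (> 0);
#'   the default keeps one interpolated pixel of clearance inside a 0.5 m
#'   crown at 60 mm ground resolution.
#' @return an \code{roi_set} with provenance \code{auto} and a per-entry
#'   \code{veg_threshold} column.
#' @export
auto_rows <- function(raster, layout, buffer = 0.15) {
  if (buffer <= 0) stop("buffer must be positive")
  ndvi <- ndvi_matrix(raster)
  ext <- raster_extent(raster)
  est_half <- max(layout$geometry$row_spacing / 2, buffer)
  entries <- NULL; polys <- list(); k <- 0L
  for (i in seq_len(nrow(layout$rows))) {
    rw <- layout$rows[i, ]
    if (rw$x - buffer < ext[["xmin"]] || rw$x + buffer > ext[["xmax"]] ||
        rw$y0 < ext[["ymin"]] || rw$y1 > ext[["ymax"]]) {
      warning("row ", rw$plot_id, "/", rw$row_index,
              " outside raster; dropped")
      next
    }
    inset <- min(buffer, (rw$y1 - rw$y0) / 4)
    poly <- cbind(x = rw$x + c(-buffer, buffer, buffer, -buffer),
                  y = c(rw$y0 + inset, rw$y0 + inset,
                        rw$y1 - inset, rw$y1 - inset))
    est <- cbind(x = rw$x + c(-est_half, est_half, est_half, -est_half),
                 y = c(rw$y0, rw$y0, rw$y1, rw$y1))
    est[, 1] <- clamp(est[, 1], ext[["xmin"]], ext[["xmax"]])
    vals <- ndvi[polygon_pixels(raster, est)]
    thr <- otsu_threshold(vals)
    k <- k + 1L
    entries <- rbind(entries,
                     data.frame(plot_id = rw$plot_id, row_index = rw$row_index,
                                veg_threshold = thr, stringsAsFactors = FALSE))
    polys[[k]] <- poly
  }
  if (k == 0L) stop("no layout row falls inside the raster")
  roi_set(entries, polys, provenance = "auto")
}

# Linear indices of pixels whose centers lie inside the polygon.
polygon_pixels <- function(raster, poly) {
  ctr <- pixel_centers(raster)
  cx <- range(poly[, 1]); cy <- range(poly[, 2])
  ci <- which(ctr$x >= cx[1] & ctr$x <= cx[2])
  ri <- which(ctr$y >= cy[1] & ctr$y <= cy[2])
  if (!length(ci) || !length(ri)) return(integer(0))
  pts <- cbind(rep(ctr$x[ci], each = length(ri)), rep(ctr$y[ri], length(ci)))
  inside <- mgcv::in.out(rbind(poly, poly[1, , drop = FALSE]), pts)
  nr <- dim(raster)[1]
  (rep(ci, each = length(ri)) - 1L) * nr + rep(ri, length(ci))
}

#' Extract vegetation-only reflectance summaries per plot
#'
#' For each ROI entry, pixels whose centers lie inside the polygon are
#' classified as vegetation when their NDVI meets the threshold (per-entry
#' \code{veg_threshold} when present, else \code{veg_rule}); band means are
#' taken over vegetation pixels only.  Rows are aggregated to plots by
#' pixel-count weighting, which equals pooling all the plot's vegetation
#' pixels.  Plots with no vegetation pixel are flagged and their means set to
#' \code{NA}.
#'
#' @param raster a reflectance \code{geogrid} with bands \code{green},
#'   \code{red}, \code{nir}.
#' @param rois an \code{roi_set}.
#' @param veg_rule default NDVI vegetation threshold (numeric, default 0.3)
#'   or \code{"otsu"} to estimate one cutoff from all ROI pixels pooled.
#' @return data.frame of class \code{roi_spectra}: one row per plot with
#'   \code{r_green}, \code{r_red}, \code{r_nir} (vegetation-mean
#'   reflectances), \code{vegetation_pixel_count}, \code{total_pixel_count},
#'   \code{flagged}.
#' @export
extract_spectra <- function(raster, rois, veg_rule = 0.3) {
  ndvi <- ndvi_matrix(raster)
  if (identical(veg_rule, "otsu")) {
    pooled <- unlist(lapply(rois$polygons,
                            function(p) ndvi[polygon_pixels(raster, p)]))
    veg_rule <- otsu_threshold(pooled)
  }
  stopifnot(is.numeric(veg_rule))
  ent <- rois$entries
  per_row <- lapply(seq_len(nrow(ent)), function(i) {
    idx <- polygon_pixels(raster, rois$polygons[[i]])
    thr <- if (!is.null(ent$veg_threshold)) ent$veg_threshold[i] else veg_rule
    nd <- ndvi[idx]
    veg <- idx[!is.na(nd) & nd >= thr]
    data.frame(plot_id = ent$plot_id[i],
               sum_green = sum(raster$bands[["green"]][veg]),
               sum_red = sum(raster$bands[["red"]][veg]),
               sum_nir = sum(raster$bands[["nir"]][veg]),
               veg_n = length(veg), tot_n = length(idx),
               stringsAsFactors = FALSE)
  })
  rr <- do.call(rbind, per_row)
  agg <- lapply(split(rr, rr$plot_id), function(d) {
    vn <- sum(d$veg_n)
    data.frame(plot_id = d$plot_id[1],
               r_green = if (vn > 0) sum(d$sum_green) / vn else NA_real_,
               r_red = if (vn > 0) sum(d$sum_red) / vn else NA_real_,
               r_nir = if (vn > 0) sum(d$sum_nir) / vn else NA_real_,
               vegetation_pixel_count = vn,
               total_pixel_count = sum(d$tot_n),
               flagged = vn == 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  class(out) <- c("roi_spectra", "data.frame")
  out
}
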