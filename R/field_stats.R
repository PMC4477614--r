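# Spatial field-variability characterization from NDVI rasters.

#' Descriptive field statistics
#'
#' Mean, minimum, maximum, sample (n-1) standard deviation and coefficient of
#' variation (CV = 100 sd/mean) of a collection of NDVI values; missing
#' values excluded.
#'
#' @param values numeric vector (or matrix) of NDVI values; \code{NA} =
#'   nodata.
#' @return list of class \code{field_summary}: \code{mean}, \code{min},
#'   \code{max}, \code{sd}, \code{cv} (%), \code{n}.
#' @export
summarize_field <- function(values) {
  v <- as.vector(values)
  v <- v[!is.na(v)]
  if (length(v) < 2) stop("insufficient data: need at least 2 valid values")
  m <- mean(v); s <- stats::sd(v)
  structure(list(mean = m, min = min(v), max = max(v), sd = s,
                 cv = if (m > 0) 100 * s / m else NA_real_,
                 n = length(v)),
            class = "field_summary")
}

#' @export
print.field_summary <- function(x, ...) {
  cat(sprintf(
    "<field_summary> n=%d  mean %.4f  min %.4f  max %.4f  sd %.4f  CV %.2f%%\n",
    x$n, x$mean, x$min, x$max, x$sd, x$cv))
  invisible(x)
}

# Window sums via integral image, clipping the window at borders.
window_sums <- function(m, half) {
  nr <- nrow(m); nc <- ncol(m)
  cs <- rbind(0, apply(m, 2, cumsum))
  cs <- cbind(0, t(apply(cs, 1, cumsum)))
  r0 <- pmax(seq_len(nr) - half - 1L, 0L); r1 <- pmin(seq_len(nr) + half, nr)
  c0 <- pmax(seq_len(nc) - half - 1L, 0L); c1 <- pmin(seq_len(nc) + half, nc)
  cs[r1 + 1L, c1 + 1L, drop = FALSE] - cs[r0 + 1L, c1 + 1L, drop = FALSE] -
    cs[r1 + 1L, c0 + 1L, drop = FALSE] + cs[r0 + 1L, c0 + 1L, drop = FALSE]
}

#' Moving-window coefficient-of-variation map
#'
#' Per-pixel CV (%) over a centered square window, using the sample (n-1)
#' standard deviation.  Nodata pixels are excluded from the window
#' statistics; border pixels use the valid in-raster subset of their window.
#' Pixels with fewer than 2 valid neighbors or non-positive local mean are
#' nodata in the output.
#'
#' @param raster a \code{geogrid}; the band named \code{ndvi} is used if
#'   present, else the first band.
#' @param window odd window side length in pixels (>= 3).
#' @return a single-band \code{geogrid} (\code{local_cv}) on the same grid.
#' @export
variability_map <- function(raster, window = 15) {
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  b <- if ("ndvi" %in% band_names(raster)) raster$bands[["ndvi"]]
       else raster$bands[[1]]
  if (window > min(dim(b))) stop("window larger than raster")
  half <- (window - 1L) %/% 2L
  valid <- !is.na(b)
  z <- b; z[!valid] <- 0
  n <- window_sums(valid * 1, half)
  s1 <- window_sums(z, half)
  s2 <- window_sums(z * z, half)
  mu <- s1 / n
  varr <- pmax(s2 - s1^2 / n, 0) / pmax(n - 1, 1)
  cv <- 100 * sqrt(varr) / mu
  cv[n < 2 | mu <= 0] <- NA_real_
  geogrid(list(local_cv = cv), x0 = raster$transform$x0,
          y0 = raster$transform$y0, gsd = raster$transform$gsd)
}

# 8-connected component labeling (BFS over a logical matrix).
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start; lab[start] <- nxt
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      r <- (cur - 1L) %% nr + 1L; cc <- (cur - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; c2 <- cc + dc
        ok <- rr >= 1 & rr <= nr & c2 >= 1 & c2 <= nc
        nb <- (c2[ok] - 1L) * nr + rr[ok]
        nb <- nb[mask[nb] & lab[nb] == 0L]
        if (length(nb)) {
          lab[nb] <- nxt
          queue <- c(queue, nb)
        }
      }
      queue <- unique(queue)
    }
  }
  lab
}

#' Flag high-variability zones
#'
#' Connected components (8-connectivity) of pixels whose local CV exceeds the
#' threshold, polygonized in world coordinates.  Useful for excluding highly
#' variable portions of a field from trial layouts.
#'
#' @param cv_raster a \code{local_cv} raster from \code{\link{variability_map}}.
#' @param cv_threshold CV threshold in percent (> 0).
#' @return list of class \code{variability_zones}; each element has
#'   \code{zone_id}, \code{pixel_count}, \code{area_m2} and \code{polygon}
#'   (outer boundary rings, world coordinates, from contour tracing).  Empty
#'   list when no pixel exceeds the threshold.
#' @export
flag_zones <- function(cv_raster, cv_threshold) {
  if (cv_threshold <= 0) stop("threshold must be positive")
  b <- cv_raster$bands[[1]]
  mask <- !is.na(b) & b > cv_threshold
  gsd <- cv_raster$transform$gsd
  lab <- label_components8(mask)
  nz <- max(lab)
  ctr <- pixel_centers(cv_raster)
  zones <- vector("list", nz)
  for (z in seq_len(nz)) {
    zm <- lab == z
    npx <- sum(zm)
    # pad so border-touching zones close; contour at 0.5 in pixel-center space
    pm <- matrix(0, nrow(zm) + 2, ncol(zm) + 2)
    pm[2:(nrow(zm) + 1), 2:(ncol(zm) + 1)] <- zm
    cl <- grDevices::contourLines(x = seq_len(nrow(pm)), y = seq_len(ncol(pm)),
                                  z = pm, levels = 0.5)
    rings <- lapply(cl, function(cc) {
      # contour x = padded row index, y = padded col index -> world
      cbind(x = cv_raster$transform$x0 + (cc$y - 1.5) * gsd,
            y = cv_raster$transform$y0 - (cc$x - 1.5) * gsd)
    })
    zones[[z]] <- list(zone_id = z, pixel_count = npx,
                       area_m2 = npx * gsd^2, polygon = rings)
  }
  structure(zones, class = "variability_zones")
}

#' @export
print.variability_zones <- function(x, ...) {
  cat(sprintf("<variability_zones> %d zone(s), total area %.1f m2\n",
              length(x), sum(vapply(x, `[[`, numeric(1), "area_m2"))))
  invisible(x)
}

#' Write variability zones as GeoJSON
#' @param zones a \code{variability_zones} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_zones <- function(zones, path) {
  feats <- lapply(zones, function(z) {
    list(type = "Feature",
         properties = list(zone_id = z$zone_id, pixel_count = z$pixel_count,
                           area_m2 = z$area_m2),
         geometry = list(
           type = "MultiPolygon",
           coordinates = lapply(z$polygon, function(ring) {
             ring <- rbind(ring, ring[1, , drop = FALSE])
             list(lapply(seq_len(nrow(ring)), function(k) unname(ring[k, ])))
           })))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
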