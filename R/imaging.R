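# Frame preprocessing: CFA demosaicing, radiometric calibration to
# reflectance, and position-only mosaicking.

#' Radiometric calibration model
#'
#' Linear (empirical line) digital-number to reflectance conversion per band:
#' \code{reflectance = (DN - offset) * gain}.
#'
#' @param gain named numeric vector of per-band gains (> 0), reflectance/DN.
#' @param offset named numeric vector of per-band dark offsets, DN.
#' @param source \code{"panel"} (estimated from a reference panel) or
#'   \code{"fixed"}.
#' @return a list of class \code{calibration_model}.
#' @export
calibration_model <- function(gain, offset = setNames(rep(0, length(gain)),
                                                      names(gain)),
                              source = c("fixed", "panel")) {
  source <- match.arg(source)
  if (is.null(names(gain))) stop("gain must be a named vector")
  if (any(gain <= 0)) stop("gains must be positive")
  offset <- offset[names(gain)]
  structure(list(gain = gain, offset = offset, source = source),
            class = "calibration_model")
}

# Bilinear infill of a band sampled on a regular CFA sub-lattice.
# positions: 2-column matrix of (row-phase, col-phase) in {1,2} where the
# band has native sensels on the 2x2 tiling.
demosaic_band <- function(frame, positions) {
  h <- nrow(frame); w <- ncol(frame)
  out <- matrix(NA_real_, h, w)
  for (k in seq_len(nrow(positions))) {
    ri <- seq(positions[k, 1], h, by = 2)
    ci <- seq(positions[k, 2], w, by = 2)
    out[ri, ci] <- frame[ri, ci]
  }
  # reflect-pad by one pixel, then fill missing sites from neighbors
  pad <- matrix(NA_real_, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- out
  pad[1, ] <- pad[3, ]; pad[h + 2, ] <- pad[h, ]
  pad[, 1] <- pad[, 3]; pad[, w + 2] <- pad[, w]
  if (nrow(positions) == 2) {
    # quincunx: every missing site has 4 axial native neighbors
    miss <- which(is.na(out))
    mr <- (miss - 1L) %% h + 2L; mc <- (miss - 1L) %/% h + 2L
    out[miss] <- (pad[cbind(mr - 1L, mc)] + pad[cbind(mr + 1L, mc)] +
                    pad[cbind(mr, mc - 1L)] + pad[cbind(mr, mc + 1L)]) / 4
  } else {
    # single phase: separable linear interpolation, rows then columns
    mid <- pad
    rnat <- which(!is.na(pad[, positions[1, 2] + 1]))
    for (r in setdiff(seq_len(h + 2), rnat)) {
      lo <- max(rnat[rnat < r], -Inf); hi <- min(rnat[rnat > r], Inf)
      if (is.infinite(lo)) mid[r, ] <- pad[hi, ]
      else if (is.infinite(hi)) mid[r, ] <- pad[lo, ]
      else mid[r, ] <- pad[lo, ] + (pad[hi, ] - pad[lo, ]) * (r - lo) / (hi - lo)
    }
    cnat <- which(!is.na(mid[positions[1, 1] + 1, ]))
    res <- mid
    for (cc in setdiff(seq_len(w + 2), cnat)) {
      lo <- max(cnat[cnat < cc], -Inf); hi <- min(cnat[cnat > cc], Inf)
      if (is.infinite(lo)) res[, cc] <- mid[, hi]
      else if (is.infinite(hi)) res[, cc] <- mid[, lo]
      else res[, cc] <- mid[, lo] + (mid[, hi] - mid[, lo]) * (cc - lo) / (hi - lo)
    }
    out <- res[2:(h + 1), 2:(w + 1)]
  }
  out
}

#' Demosaic a color-filter-array frame
#'
#' Reconstructs full-resolution green/red/NIR bands from a single-band CFA
#' mosaic.  At sensel positions native to a band the raw sample is kept;
#' elsewhere values are bilinearly interpolated from the nearest native
#' samples (exact for affine signals at interior pixels), with reflection
#' padding at the edges.
#'
#' @param frame a single-band \code{geogrid} (band \code{cfa}) with even
#'   dimensions, or a plain numeric matrix.
#' @param pattern 2x2 character matrix tiling of band names; must name
#'   exactly \code{green}, \code{red} and \code{nir}, one of them twice
#'   (see \code{\link{cfa_pattern}}).
#' @return a 3-band \code{geogrid} (\code{green}, \code{red}, \code{nir})
#'   on the same grid (matrix input yields a unit-transform grid).
#' @export
demosaic_cfa <- function(frame, pattern = cfa_pattern()) {
  m <- if (inherits(frame, "geogrid")) frame$bands[[1]] else frame
  if (nrow(m) %% 2 != 0 || ncol(m) %% 2 != 0)
    stop("frame dimensions must be even")
  if (!identical(dim(pattern), c(2L, 2L)) ||
      !setequal(pattern, c("green", "red", "nir")))
    stop("invalid pattern: 2x2 tiling must cover green, red, nir")
  bands <- lapply(c("green", "red", "nir"), function(b) {
    pos <- which(pattern == b, arr.ind = TRUE)
    demosaic_band(m, pos)
  })
  names(bands) <- c("green", "red", "nir")
  if (inherits(frame, "geogrid"))
    geogrid(bands, x0 = frame$transform$x0, y0 = frame$transform$y0,
            gsd = frame$transform$gsd)
  else geogrid(bands)
}

#' Convert digital numbers to reflectance
#'
#' Applies \code{reflectance = (DN - offset) * gain} per band and clips to
#' [0, 1.5] (tolerating calibration overshoot); the number of clipped pixels
#' is attached as attribute \code{clipped}.
#'
#' @param frame a \code{geogrid} whose bands are covered by \code{model}.
#' @param model a \code{\link{calibration_model}}.
#' @return a reflectance \code{geogrid} with attribute \code{clipped}.
#' @export
calibrate <- function(frame, model) {
  bn <- band_names(frame)
  if (!all(bn %in% names(model$gain)))
    stop("calibration model does not cover bands: ",
         paste(setdiff(bn, names(model$gain)), collapse = ", "))
  clipped <- 0L
  bands <- lapply(bn, function(b) {
    v <- (frame$bands[[b]] - model$offset[[b]]) * model$gain[[b]]
    clipped <<- clipped + sum(v < 0 | v > 1.5, na.rm = TRUE)
    clamp(v, 0, 1.5)
  })
  names(bands) <- bn
  out <- geogrid(bands, x0 = frame$transform$x0, y0 = frame$transform$y0,
                 gsd = frame$transform$gsd)
  attr(out, "clipped") <- clipped
  out
}

#' Estimate an empirical-line calibration from a reference panel
#'
#' Solves a through-origin empirical line per band from the mean digital
#' number over a reference panel of known reflectance:
#' \code{gain = panel_reflectance / mean(DN - dark_offset)}.
#'
#' @param frame a \code{geogrid} containing the panel.
#' @param panel_roi list with integer vectors \code{rows} and \code{cols}
#'   giving the panel pixel block.
#' @param panel_reflectance named per-band panel reflectance.
#' @param dark_offset per-band dark level in DN (default 0).
#' @return a \code{\link{calibration_model}} with \code{source = "panel"}.
#' @export
estimate_panel_calibration <- function(frame, panel_roi, panel_reflectance,
                                       dark_offset = 0) {
  bn <- band_names(frame)
  stopifnot(all(bn %in% names(panel_reflectance)))
  if (length(panel_roi$rows) == 0 || length(panel_roi$cols) == 0)
    stop("panel ROI is empty")
  dark <- rep_len(dark_offset, length(bn)); names(dark) <- bn
  gain <- vapply(bn, function(b) {
    mdn <- mean(frame$bands[[b]][panel_roi$rows, panel_roi$cols],
                na.rm = TRUE) - dark[[b]]
    if (!is.finite(mdn) || mdn == 0) stop("degenerate panel: zero mean DN")
    panel_reflectance[[b]] / mdn
  }, numeric(1))
  calibration_model(gain = gain, offset = dark, source = "panel")
}

#' Mosaic georeferenced frames by nearest frame center
#'
#' Places frames by their absolute positions only: the output grid is the
#' union bounding box of all frames at the common gsd, and each output pixel
#' takes its value from the frame whose center is nearest to that pixel
#' (hard nearest-center assignment; no feathering, so pixel values are
#' preserved for index arithmetic).  Pixels covered by no frame are nodata.
#'
#' @param frames list of \code{geogrid}s sharing band set and gsd.
#' @return a \code{geogrid} over the union extent.
#' @export
mosaic_frames <- function(frames) {
  stopifnot(length(frames) >= 1)
  gsd <- frames[[1]]$transform$gsd
  bn <- band_names(frames[[1]])
  for (f in frames) {
    if (abs(f$transform$gsd - gsd) > 1e-12)
      stop("resample required: frames have mixed gsd")
    if (!identical(band_names(f), bn)) stop("frames have mixed band sets")
  }
  exts <- vapply(frames, raster_extent,
                 c(xmin = 0, ymin = 0, xmax = 0, ymax = 0))
  x0 <- min(exts["xmin", ]); y0 <- max(exts["ymax", ])
  nc <- round((max(exts["xmax", ]) - x0) / gsd)
  nr <- round((y0 - min(exts["ymin", ])) / gsd)
  out <- lapply(bn, function(b) matrix(NA_real_, nr, nc))
  names(out) <- bn
  best <- matrix(Inf, nr, nc)
  xc <- x0 + (seq_len(nc) - 0.5) * gsd
  yc <- y0 - (seq_len(nr) - 0.5) * gsd
  for (f in frames) {
    e <- raster_extent(f)
    cx <- (e[["xmin"]] + e[["xmax"]]) / 2; cy <- (e[["ymin"]] + e[["ymax"]]) / 2
    d <- dim(f$bands[[1]])
    c0 <- round((e[["xmin"]] - x0) / gsd)
    r0 <- round((y0 - e[["ymax"]]) / gsd)
    rr <- r0 + seq_len(d[1]); cc <- c0 + seq_len(d[2])
    keep_r <- rr >= 1 & rr <= nr; keep_c <- cc >= 1 & cc <= nc
    dist <- outer((yc[rr[keep_r]] - cy)^2, (xc[cc[keep_c]] - cx)^2, "+")
    win <- dist < best[rr[keep_r], cc[keep_c], drop = FALSE]
    for (b in bn) {
      sub <- out[[b]][rr[keep_r], cc[keep_c], drop = FALSE]
      src <- f$bands[[b]][keep_r, keep_c, drop = FALSE]
      sub[win] <- src[win]
      out[[b]][rr[keep_r], cc[keep_c]] <- sub
    }
    bsub <- best[rr[keep_r], cc[keep_c], drop = FALSE]
    bsub[win] <- dist[win]
    best[rr[keep_r], cc[keep_c]] <- bsub
  }
  geogrid(out, x0 = x0, y0 = y0, gsd = gsd)
}
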