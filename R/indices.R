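# Vegetation and stress indices: NDVI, nitrogen stress index, hue-threshold
# green fractions, and the crop senescence index.

#' Normalized Difference Vegetation Index
#'
#' \code{(NIR - Red)/(NIR + Red)}, computed from the camera's broadband NIR
#' and red reflectances (surrogates for the 800 and 670 nm narrowbands).
#'
#' @param r_nir,r_red reflectances (>= 0), vectorized.
#' @return NDVI in [-1, 1]; \code{NA} where both inputs are zero.
#' @export
ndvi <- function(r_nir, r_red) {
  if (any(r_nir < 0 | r_red < 0, na.rm = TRUE))
    stop("reflectances must be non-negative")
  s <- r_nir + r_red
  out <- (r_nir - r_red) / s
  out[s == 0] <- NA_real_
  out
}

#' Nitrogen stress index
#'
#' \code{1 - ndvi_i / ndvi_ref}: a plot's NDVI relative to the mean NDVI at
#' the highest (reference) N rate.  Zero when the plot matches the
#' reference; larger under stronger N stress.
#'
#' @param ndvi_i plot NDVI, vectorized.
#' @param ndvi_ref reference NDVI (> 0), e.g. from
#'   \code{\link{compute_reference}}.
#' @return stress index (<= 1).
#' @export
nitrogen_stress_index <- function(ndvi_i, ndvi_ref) {
  if (any(ndvi_ref <= 0)) stop("invalid reference: ndvi_ref must be positive")
  1 - ndvi_i / ndvi_ref
}

#' Reference NDVI at the reference N rate
#'
#' Arithmetic mean of plot NDVI at the reference rate, pooled over hybrids by
#' default or per hybrid.
#'
#' @param data data.frame with columns \code{ndvi}, \code{n_rate} and (for
#'   per-hybrid mode) \code{hybrid_id}.
#' @param reference_rate N rate used as reference, kg/ha (default 160).
#' @param per_hybrid if TRUE, return a named vector of per-hybrid means.
#' @return numeric scalar, or named vector in per-hybrid mode.
#' @export
compute_reference <- function(data, reference_rate = 160, per_hybrid = FALSE) {
  ref <- data[!is.na(data$ndvi) & data$n_rate == reference_rate, , drop = FALSE]
  if (nrow(ref) == 0)
    stop("missing reference: no plots at rate ", reference_rate)
  if (per_hybrid) tapply(ref$ndvi, ref$hybrid_id, mean)
  else mean(ref$ndvi)
}

#' Hue of RGB pixels
#'
#' Standard hexagonal hue (0 = red, 120 = green, 240 = blue), in degrees.
#' Achromatic pixels (max channel equals min channel) are unclassifiable and
#' return \code{NA}.
#'
#' @param r,g,b channel values in [0, 1], vectorized.
#' @return hue in degrees [0, 360), \code{NA} for achromatic pixels.
#' @export
hue <- function(r, g, b) {
  if (any(c(r, g, b) < 0 | c(r, g, b) > 1, na.rm = TRUE))
    stop("channels must be in [0, 1]")
  hsv <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 1)
  out <- hsv["h", ] * 360
  out[hsv["s", ] == 0] <- NA_real_
  unname(out)
}

#' Green and greener pixel fractions of an RGB image
#'
#' Classifies pixels by hue: green when hue lies in [60, 180] degrees (GF)
#' and greener when in [80, 180] (GGF, excluding yellowish senescing
#' leaves); both bounds inclusive.  Achromatic pixels are unclassifiable and
#' excluded from numerator and denominator.
#'
#' @param img numeric array height x width x 3, RGB in [0, 1].
#' @param mask optional logical matrix (height x width); only TRUE pixels are
#'   considered.
#' @param gf_bounds,ggf_bounds hue intervals in degrees.
#' @return list of class \code{greenness_fractions}: \code{gf}, \code{ggf},
#'   \code{classifiable_pixel_count}, \code{flagged} (TRUE when no pixel is
#'   classifiable, fractions \code{NA}).
#' @export
green_fractions <- function(img, mask = NULL, gf_bounds = c(60, 180),
                            ggf_bounds = c(80, 180)) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  if (!is.null(mask)) {
    keep <- as.logical(mask)
    r <- r[keep]; g <- g[keep]; b <- b[keep]
  }
  h <- hue(as.vector(r), as.vector(g), as.vector(b))
  h <- h[!is.na(h)]
  n <- length(h)
  if (n == 0)
    return(structure(list(gf = NA_real_, ggf = NA_real_,
                          classifiable_pixel_count = 0L, flagged = TRUE),
                     class = "greenness_fractions"))
  gf <- sum(h >= gf_bounds[1] & h <= gf_bounds[2]) / n
  ggf <- sum(h >= ggf_bounds[1] & h <= ggf_bounds[2]) / n
  structure(list(gf = gf, ggf = ggf, classifiable_pixel_count = n,
                 flagged = FALSE),
            class = "greenness_fractions")
}

#' @export
print.greenness_fractions <- function(x, ...) {
  cat(sprintf("<greenness_fractions> GF %.3f, GGF %.3f (%d classifiable px)\n",
              x$gf, x$ggf, x$classifiable_pixel_count))
  invisible(x)
}

#' Crop senescence index
#'
#' \code{100 * (GF - GGF) / GF}: the share (%) of the green-range canopy that
#' is yellowish (senescing).  Undefined (\code{NA}) when GF is zero.
#'
#' @param gf green fraction(s), or a \code{greenness_fractions} object (then
#'   \code{ggf} is ignored).
#' @param ggf greener fraction(s).
#' @return senescence index in [0, 100], \code{NA} where \code{gf} is 0.
#' @export
crop_senescence_index <- function(gf, ggf = NULL) {
  if (inherits(gf, "greenness_fractions")) {
    ggf <- gf$ggf; gf <- gf$gf
  }
  stopifnot(length(gf) == length(ggf))
  out <- 100 * (gf - ggf) / gf
  out[!is.na(gf) & gf == 0] <- NA_real_
  out
}

#' Assemble the per-plot index table
#'
#' Joins reflectance spectra and RGB green fractions on plot id, computes
#' NDVI, the nitrogen stress index (against the mean NDVI at the reference
#' rate) and the crop senescence index.  Missing modalities give \code{NA}
#' fields; rows are never dropped.
#'
#' @param spectra \code{roi_spectra} from \code{\link{extract_spectra}}.
#' @param fractions data.frame with columns \code{plot_id}, \code{gf},
#'   \code{ggf} (may be NULL if no RGB imagery).
#' @param layout a \code{trial_layout}.
#' @param reference_rate N rate of the NSI reference, kg/ha.
#' @param per_hybrid_reference use a per-hybrid NSI reference.
#' @param date acquisition label.
#' @return data.frame of class \code{index_table}: one row per plot with
#'   design columns, \code{ndvi}, \code{nsi}, \code{gf}, \code{ggf},
#'   \code{csi}, counts and \code{flagged}.
#' @export
build_index_table <- function(spectra, fractions = NULL, layout,
                              reference_rate = 160,
                              per_hybrid_reference = FALSE, date = "t1") {
  p <- layout$plots[c("plot_id", "hybrid_id", "tolerance_class", "n_rate",
                      "replicate")]
  out <- merge(p, as.data.frame(spectra), by = "plot_id", all.x = TRUE)
  out$ndvi <- ndvi(out$r_nir, out$r_red)
  ref <- compute_reference(out, reference_rate, per_hybrid_reference)
  out$nsi <- if (per_hybrid_reference)
    nitrogen_stress_index(out$ndvi, unname(ref[out$hybrid_id]))
  else nitrogen_stress_index(out$ndvi, ref)
  if (!is.null(fractions)) {
    out <- merge(out, fractions[c("plot_id", "gf", "ggf")], by = "plot_id",
                 all.x = TRUE)
    out$csi <- crop_senescence_index(out$gf, out$ggf)
  } else {
    out$gf <- out$ggf <- out$csi <- NA_real_
  }
  out$date <- date
  out$flagged <- is.na(out$ndvi)
  out <- out[order(out$plot_id), ]
  rownames(out) <- NULL
  class(out) <- c("index_table", "data.frame")
  out
}
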