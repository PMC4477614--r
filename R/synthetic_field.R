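# Synthetic field-trial generator: layouts, plot-level ground truth, and
# rendered multispectral / RGB imagery with known answers.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Plot geometry of a two-row trial plot
#'
#' Defaults follow a typical maize N-response trial: 2 rows per plot,
#' 75 cm row spacing, 4 m row length, 17 planting stations per row.
#'
#' @param rows_per_plot rows per plot (>= 1).
#' @param row_spacing distance between rows, m.
#' @param row_length row length, m.
#' @param stations_per_row planting stations per row.
#' @param plot_gap_x alley between adjacent plots along the row-perpendicular
#'   axis, m.
#' @param plot_gap_y alley between replicate blocks, m.
#' @return a list of class \code{plot_geometry}.
#' @export
plot_geometry <- function(rows_per_plot = 2, row_spacing = 0.75,
                          row_length = 4, stations_per_row = 17,
                          plot_gap_x = 0.3, plot_gap_y = 1.0) {
  stopifnot(rows_per_plot >= 1, row_spacing > 0, row_length > 0,
            stations_per_row >= 1, plot_gap_x >= 0, plot_gap_y >= 0)
  structure(list(rows_per_plot = rows_per_plot, row_spacing = row_spacing,
                 row_length = row_length, stations_per_row = stations_per_row,
                 plot_gap_x = plot_gap_x, plot_gap_y = plot_gap_y),
            class = "plot_geometry")
}

#' Generate a randomized split-plot trial layout
#'
#' Hybrids are randomized to main plots within each replicate block and N
#' rates are randomized to subplots within each main plot (split-plot design,
#' replicates as complete blocks).  Blocks are stacked southward; main plots
#' and subplots run west to east.  The first \code{ceiling(n_hybrids/2)}
#' hybrids are labelled low-N \code{tolerant}, the rest \code{sensitive}.
#'
#' @param n_hybrids number of hybrids (>= 2).
#' @param rates N application rates, kg/ha of ammonium nitrate; distinct.
#' @param reps number of replicate blocks (>= 1).
#' @param geometry a \code{\link{plot_geometry}}.
#' @param field_origin world coordinates (m) of the north-west field corner.
#' @param seed integer seed; identical seeds give identical layouts.
#' @return an object of class \code{trial_layout}: a list with
#'   \describe{
#'     \item{plots}{data.frame of plot id, hybrid, tolerance class, N rate,
#'       replicate and plot rectangle (xmin/xmax/ymin/ymax, m).}
#'     \item{rows}{data.frame of row centerlines (plot_id, row_index, x, y0,
#'       y1), one vertical segment per planted row.}
#'     \item{geometry, field_origin}{as supplied.}
#'   }
#' @export
generate_layout <- function(n_hybrids = 10, rates = c(0, 10, 20, 40, 80, 160),
                            reps = 3, geometry = plot_geometry(),
                            field_origin = c(0, 0), seed = 1) {
  if (n_hybrids < 2) stop("need at least 2 hybrids")
  if (reps < 1) stop("need at least 1 replicate")
  if (length(rates) == 0 || anyDuplicated(rates))
    stop("invalid design: rates must be non-empty and distinct")
  g <- geometry
  hybrids <- sprintf("H%02d", seq_len(n_hybrids))
  tol <- ifelse(seq_len(n_hybrids) <= ceiling(n_hybrids / 2),
                "tolerant", "sensitive")
  names(tol) <- hybrids
  nr <- length(rates)
  plot_w <- g$rows_per_plot * g$row_spacing
  sub_pitch <- plot_w + g$plot_gap_x
  main_pitch <- nr * sub_pitch + 2 * g$plot_gap_x
  block_pitch <- g$row_length + g$plot_gap_y

  with_seed(seed, {
    recs <- vector("list", reps * n_hybrids * nr)
    k <- 0L
    for (b in seq_len(reps)) {
      ymax <- field_origin[2] - (b - 1) * block_pitch
      main_order <- sample(hybrids)
      for (m in seq_len(n_hybrids)) {
        hy <- main_order[m]
        # sample() on a length-1 numeric would permute 1:x instead
        sub_order <- if (length(rates) > 1) sample(rates) else rates
        for (s in seq_len(nr)) {
          k <- k + 1L
          x0 <- field_origin[1] + (m - 1) * main_pitch + (s - 1) * sub_pitch
          recs[[k]] <- data.frame(
            hybrid_id = hy, tolerance_class = unname(tol[hy]),
            n_rate = sub_order[s], replicate = b,
            xmin = x0, xmax = x0 + plot_w,
            ymin = ymax - g$row_length, ymax = ymax,
            stringsAsFactors = FALSE)
        }
      }
    }
    plots <- do.call(rbind, recs)
  })
  plots <- cbind(plot_id = sprintf("P%03d", seq_len(nrow(plots))), plots,
                 stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(plots)), function(i) {
    p <- plots[i, ]
    data.frame(plot_id = p$plot_id, row_index = seq_len(g$rows_per_plot),
               x = p$xmin + (seq_len(g$rows_per_plot) - 0.5) * g$row_spacing,
               y0 = p$ymin, y1 = p$ymax, stringsAsFactors = FALSE)
  }))
  structure(list(plots = plots, rows = rows, geometry = g,
                 field_origin = field_origin),
            class = "trial_layout")
}

#' @export
print.trial_layout <- function(x, ...) {
  p <- x$plots
  cat(sprintf(
    "<trial_layout> %d plots: %d hybrids x %d N rates x %d replicates\n",
    nrow(p), length(unique(p$hybrid_id)), length(unique(p$n_rate)),
    max(p$replicate)))
  ext <- c(min(p$xmin), min(p$ymin), max(p$xmax), max(p$ymax))
  cat(sprintf("  extent %.1f x %.1f m\n", ext[3] - ext[1], ext[4] - ext[2]))
  invisible(x)
}

#' Nitrogen-response model for the synthetic trial
#'
#' Parameterizes how canopy state responds to N rate: true NDVI saturates
#' with N (Michaelis-Menten in applied N plus a residual soil-N offset, with
#' a class-specific asymptote so tolerant hybrids keep more vigor at any
#' rate); the crop senescence index follows a continuous broken-stick
#' decline in N; the green fraction tracks NDVI; grain yield is linear in
#' true NDVI with noise that grows with N rate (at high N, yield is limited
#' by factors other than canopy vigor, loosening the NDVI-yield coupling).
#'
#' @param ndvi_asymptote named vector, NDVI asymptote per tolerance class
#'   (tolerant >= sensitive).
#' @param ndvi_halfsat half-saturation constant, kg/ha.
#' @param ndvi_soil_n residual plant-available soil N expressed in applied-N
#'   equivalents, kg/ha; keeps NDVI positive at 0 applied N.
#' @param senescence_breakpoint broken-stick breakpoint, kg/ha.
#' @param senescence_slopes named vector \code{c(low=, high=)}, senescence
#'   index change per kg/ha below/above the breakpoint (both <= 0,
#'   |low| > |high|).
#' @param senescence_at_zero senescence index (%) at 0 applied N.
#' @param gf_base,gf_gain green fraction = gf_base + gf_gain * NDVI (clamped).
#' @param yield_base,yield_gain grain yield t/ha = yield_base + yield_gain *
#'   true NDVI (+ noise).
#' @param noise_sd named vector of standard deviations:
#'   \code{ndvi} (NDVI units), \code{gf} (fraction), \code{yield} (t/ha,
#'   baseline), \code{yield_per_n} (extra t/ha of yield noise per kg/ha N).
#' @param soil_reflectance named vector, bare-soil reflectance per band.
#' @param canopy_green,canopy_nir fixed canopy reflectance in the green and
#'   NIR bands; canopy red reflectance is solved from the NDVI identity.
#' @param background_variability named vector \code{c(patch=, amplitude=)}:
#'   patch scale (m) and relative amplitude of the smooth multiplicative
#'   spatial field applied to canopy vigor and soil brightness.
#' @return a list of class \code{response_model}.
#' @export
response_model <- function(
    ndvi_asymptote = c(tolerant = 0.88, sensitive = 0.72),
    ndvi_halfsat = 30, ndvi_soil_n = 15,
    senescence_breakpoint = 40,
    senescence_slopes = c(low = -0.5, high = -0.05),
    senescence_at_zero = 60,
    gf_base = 0.35, gf_gain = 0.5,
    yield_base = 1.0, yield_gain = 12,
    noise_sd = c(ndvi = 0.03, gf = 0.03, yield = 0.3, yield_per_n = 0.006),
    soil_reflectance = c(green = 0.15, red = 0.20, nir = 0.25),
    canopy_green = 0.12, canopy_nir = 0.50,
    background_variability = c(patch = 8, amplitude = 0.08)) {
  stopifnot(ndvi_asymptote[["tolerant"]] >= ndvi_asymptote[["sensitive"]],
            ndvi_halfsat > 0, ndvi_soil_n >= 0,
            senescence_breakpoint > 0,
            senescence_slopes[["low"]] <= 0, senescence_slopes[["high"]] <= 0,
            abs(senescence_slopes[["low"]]) >= abs(senescence_slopes[["high"]]),
            all(noise_sd >= 0), all(soil_reflectance > 0),
            canopy_green > 0, canopy_nir > 0,
            background_variability[["patch"]] > 0,
            background_variability[["amplitude"]] >= 0)
  structure(as.list(environment()), class = "response_model")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

true_ndvi_fn <- function(model, n_rate, class) {
  a <- model$ndvi_asymptote[class]
  unname(a * (n_rate + model$ndvi_soil_n) /
           (n_rate + model$ndvi_soil_n + model$ndvi_halfsat))
}

true_csi_fn <- function(model, n_rate) {
  bp <- model$senescence_breakpoint
  s <- model$senescence_slopes
  clamp(model$senescence_at_zero + s[["low"]] * pmin(n_rate, bp) +
          s[["high"]] * pmax(n_rate - bp, 0), 0, 100)
}

#' Simulate per-plot ground truth
#'
#' Evaluates the response model at each plot's N rate and tolerance class and
#' adds plot-level noise.  With all noise standard deviations zero the
#' returned values follow the model exactly.  The greener fraction is derived
#' from the green fraction and the senescence index, so
#' \code{0 <= true_ggf <= true_gf <= 1} and
#' \code{true_csi = 100 (gf - ggf)/gf} hold by construction.
#'
#' @param layout a \code{\link{generate_layout}} result.
#' @param model a \code{\link{response_model}}.
#' @param seed integer seed.
#' @return data.frame with one row per plot: design columns plus
#'   \code{true_ndvi}, \code{true_gf}, \code{true_ggf}, \code{true_csi} (%),
#'   \code{yield} (t/ha).
#' @export
simulate_plot_truth <- function(layout, model = response_model(), seed = 1) {
  p <- layout$plots
  sd <- model$noise_sd
  with_seed(seed, {
    ndvi <- true_ndvi_fn(model, p$n_rate, p$tolerance_class) +
      rnorm(nrow(p), 0, sd[["ndvi"]])
    ndvi <- clamp(ndvi, 0.02, 0.99)
    csi <- true_csi_fn(model, p$n_rate)
    gf <- clamp(model$gf_base + model$gf_gain * ndvi +
                  rnorm(nrow(p), 0, sd[["gf"]]), 0.05, 1)
    ggf <- gf * (1 - csi / 100)
    yield_sd <- sd[["yield"]] + sd[["yield_per_n"]] * p$n_rate
    yield <- model$yield_base +
      model$yield_gain * true_ndvi_fn(model, p$n_rate, p$tolerance_class) +
      rnorm(nrow(p), 0, 1) * yield_sd
  })
  data.frame(p[c("plot_id", "hybrid_id", "tolerance_class", "n_rate",
                 "replicate")],
             true_ndvi = ndvi, true_gf = gf, true_ggf = ggf, true_csi = csi,
             yield = pmax(yield, 0.1), stringsAsFactors = FALSE)
}

# Smooth multiplicative random field, mean ~1, sd ~amplitude, patch scale in m.
smooth_field <- function(nrow, ncol, gsd, patch, amplitude) {
  if (amplitude <= 0) return(matrix(1, nrow, ncol))
  cn <- max(2L, ceiling(ncol * gsd / patch) + 1L)
  cr <- max(2L, ceiling(nrow * gsd / patch) + 1L)
  coarse <- matrix(rnorm(cr * cn), cr, cn)
  # separable bilinear upsampling
  rows <- seq(1, cr, length.out = nrow)
  cols <- seq(1, cn, length.out = ncol)
  tmp <- apply(coarse, 2, function(v) approx(seq_len(cr), v, rows)$y)
  full <- t(apply(tmp, 1, function(v) approx(seq_len(cn), v, cols)$y))
  1 + amplitude * full / stats::sd(full)
}

#' Default color-filter-array tiling
#'
#' The 2x2 sensel tiling shared between the frame renderer and the
#' demosaicer: green on the diagonal (sampled twice, quincunx), red and NIR
#' once each, analogous to a Bayer pattern with the blue channel replaced by
#' NIR.
#'
#' @return 2x2 character matrix of band names.
#' @export
cfa_pattern <- function() {
  matrix(c("green", "red", "nir", "green"), 2, 2, byrow = TRUE)
}

#' Render multispectral CFA frames over a synthetic field
#'
#' Rasterizes the trial onto a reflectance scene (soil everywhere, canopy
#' ribbons of configurable crown width along each planted row, reflectance
#' consistent with each plot's true NDVI), optionally modulated by a smooth
#' spatial heterogeneity field, then cuts nadir-orthographic camera frames
#' from it on a serpentine grid and encodes each as a single-band CFA mosaic
#' of 16-bit digital numbers.
#'
#' @param layout a \code{trial_layout}.
#' @param truth per-plot truth from \code{\link{simulate_plot_truth}}.
#' @param gsd ground sampling distance, m/pixel.
#' @param frame_size frame dimensions \code{c(width, height)} in pixels; even.
#' @param overlap frame overlap fraction on both axes, in [0, 0.9].
#' @param crown_width canopy ribbon width per row, m.
#' @param margin soil margin around the trial, m.
#' @param model a \code{\link{response_model}} (soil reflectance, canopy
#'   band levels, background variability).
#' @param gain sensor gain: reflectance per digital number.
#' @param pattern CFA tiling, see \code{\link{cfa_pattern}}.
#' @param seed integer seed (heterogeneity field).
#' @return list with \code{frames} (list of single-band \code{cfa} geogrids
#'   of digital numbers), \code{centers} (matrix of frame center world
#'   coordinates), \code{truth_raster} (3-band reflectance \code{geogrid} of
#'   the scene), \code{calibration} (the exact \code{\link{calibration_model}}
#'   that converts frame DN back to reflectance), and \code{canopy_mask}
#'   (logical matrix of the scene's canopy pixels).
#' @export
render_multispectral <- function(layout, truth, gsd = 0.06,
                                 frame_size = c(2048, 1536), overlap = 0.3,
                                 crown_width = 0.5, margin = 2,
                                 model = response_model(), gain = 5e-5,
                                 pattern = cfa_pattern(), seed = 1) {
  stopifnot(gsd > 0, overlap >= 0, overlap < 0.9)
  g <- layout$geometry
  if (g$row_spacing < 2 * gsd)
    stop("resolution error: row spacing below 2 pixels at this gsd")
  p <- layout$plots
  x0 <- floor((min(p$xmin) - margin) / gsd) * gsd
  y0 <- ceiling((max(p$ymax) + margin) / gsd) * gsd
  ncl <- ceiling((max(p$xmax) + margin - x0) / gsd)
  nrw <- ceiling((y0 - (min(p$ymin) - margin)) / gsd)

  bg <- model$background_variability
  field <- with_seed(seed,
    smooth_field(nrw, ncl, gsd, bg[["patch"]], bg[["amplitude"]]))

  # canopy NDVI map (NA = soil)
  ndvi_map <- matrix(NA_real_, nrw, ncl)
  tr_ndvi <- truth$true_ndvi[match(layout$rows$plot_id, truth$plot_id)]
  half <- crown_width / 2
  for (i in seq_len(nrow(layout$rows))) {
    rw <- layout$rows[i, ]
    c0 <- max(1L, floor((rw$x - half - x0) / gsd) + 1L)
    c1 <- min(ncl, ceiling((rw$x + half - x0) / gsd))
    r0 <- max(1L, floor((y0 - rw$y1) / gsd) + 1L)
    r1 <- min(nrw, ceiling((y0 - rw$y0) / gsd))
    # keep pixels whose centers fall within the crown ribbon / row extent
    cols <- c0:c1
    cols <- cols[abs(x0 + (cols - 0.5) * gsd - rw$x) <= half]
    rows <- r0:r1
    yc <- y0 - (rows - 0.5) * gsd
    rows <- rows[yc >= rw$y0 & yc <= rw$y1]
    if (length(rows) && length(cols)) ndvi_map[rows, cols] <- tr_ndvi[i]
  }
  canopy <- !is.na(ndvi_map)
  ndvi_eff <- clamp(ndvi_map * field, 0.05, 0.95)

  sr <- model$soil_reflectance
  green <- sr[["green"]] * field
  red <- sr[["red"]] * field
  nir <- sr[["nir"]] * field
  green[canopy] <- model$canopy_green
  nir[canopy] <- model$canopy_nir
  red[canopy] <- model$canopy_nir *
    (1 - ndvi_eff[canopy]) / (1 + ndvi_eff[canopy])
  truth_raster <- geogrid(list(green = green, red = red, nir = nir),
                          x0 = x0, y0 = y0, gsd = gsd)

  fw <- frame_size[1]; fh <- frame_size[2]
  stopifnot(fw %% 2 == 0, fh %% 2 == 0)
  W <- fw * gsd; H <- fh * gsd
  ext <- raster_extent(truth_raster)
  step_x <- max(W * (1 - overlap), gsd)
  step_y <- max(H * (1 - overlap), gsd)
  cx <- seq(ext[["xmin"]] + W / 2, by = step_x,
            length.out = max(1, ceiling((ext[["xmax"]] - ext[["xmin"]] - W) /
                                          step_x) + 1))
  cy <- seq(ext[["ymax"]] - H / 2, by = -step_y,
            length.out = max(1, ceiling((ext[["ymax"]] - ext[["ymin"]] - H) /
                                          step_y) + 1))
  centers <- do.call(rbind, lapply(seq_along(cy), function(iy) {
    xs <- if (iy %% 2 == 1) cx else rev(cx)   # serpentine track
    cbind(x = xs, y = cy[iy])
  }))

  band_idx <- matrix(match(pattern, c("green", "red", "nir")), 2, 2)
  frames <- vector("list", nrow(centers))
  for (f in seq_len(nrow(centers))) {
    # snap the frame grid onto the scene grid so sampling is exact
    col0 <- round((centers[f, "x"] - W / 2 - x0) / gsd)
    row0 <- round((y0 - (centers[f, "y"] + H / 2)) / gsd)
    rr <- row0 + seq_len(fh); cc <- col0 + seq_len(fw)
    rin <- rr >= 1 & rr <= nrw; cin <- cc >= 1 & cc <= ncl
    sub <- function(m, fill) {
      out <- matrix(fill, fh, fw)
      out[rin, cin] <- m[rr[rin], cc[cin]]
      out
    }
    bands3 <- list(sub(green, sr[["green"]]), sub(red, sr[["red"]]),
                   sub(nir, sr[["nir"]]))
    cfa <- matrix(0, fh, fw)
    for (pr in 1:2) for (pc in 1:2) {
      ri <- seq(pr, fh, by = 2); ci <- seq(pc, fw, by = 2)
      cfa[ri, ci] <- bands3[[band_idx[pr, pc]]][ri, ci]
    }
    dn <- round(cfa / gain)
    frames[[f]] <- geogrid(list(cfa = dn),
                           x0 = x0 + col0 * gsd, y0 = y0 - row0 * gsd,
                           gsd = gsd)
  }
  calib <- calibration_model(
    gain = c(green = gain, red = gain, nir = gain),
    offset = c(green = 0, red = 0, nir = 0), source = "fixed")
  list(frames = frames, centers = centers, truth_raster = truth_raster,
       calibration = calib, canopy_mask = canopy)
}

hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 360) / 60
  c <- v * s
  x <- c * (1 - abs(h %% 2 - 1))
  m <- v - c
  i <- floor(h)
  r <- ifelse(i == 0 | i == 5, c, ifelse(i == 1 | i == 4, x, 0))
  g <- ifelse(i == 1 | i == 2, c, ifelse(i == 0 | i == 3, x, 0))
  b <- ifelse(i == 3 | i == 4, c, ifelse(i == 2 | i == 5, x, 0))
  cbind(r + m, g + m, b + m)
}

#' Render a plot-level RGB canopy image with known green fractions
#'
#' Inverts the hue-threshold classifier: pixels are assigned hues so that the
#' fraction with hue in [60, 180] degrees equals \code{true_gf} and the
#' fraction in [80, 180] equals \code{true_ggf}, up to one-pixel rounding.
#' Fully green pixels draw hue from (82, 178), yellowish-green (senescing
#' canopy) from (62, 78), and the remaining soil/straw pixels from (25, 55)
#' with low saturation; all pixels are chromatic, so every pixel is
#' classifiable.
#'
#' @param truth_row one row of \code{\link{simulate_plot_truth}} output (or
#'   any list with \code{true_gf}, \code{true_ggf}).
#' @param image_size \code{c(width, height)} in pixels.
#' @param seed integer seed.
#' @return numeric array height x width x 3 (RGB in [0, 1]).
#' @export
render_rgb <- function(truth_row, image_size = c(64, 64), seed = 1) {
  gf <- truth_row$true_gf; ggf <- truth_row$true_ggf
  stopifnot(ggf >= 0, gf <= 1, ggf <= gf + 1e-12)
  n <- image_size[1] * image_size[2]
  n_gf <- round(gf * n); n_ggf <- min(round(ggf * n), n_gf)
  with_seed(seed, {
    hue <- c(runif(n_ggf, 82, 178), runif(n_gf - n_ggf, 62, 78),
             runif(n - n_gf, 25, 55))
    sat <- c(runif(n_gf, 0.5, 0.9), runif(n - n_gf, 0.25, 0.5))
    val <- c(runif(n_gf, 0.4, 0.8), runif(n - n_gf, 0.3, 0.6))
    ord <- sample.int(n)
  })
  px <- hsv_to_rgb(hue, sat, val)[ord, , drop = FALSE]
  array(px, c(image_size[2], image_size[1], 3))
}
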