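# Shared fixtures: small zero-noise trials and independent oracles.

noiseless_model <- function(...) {
  args <- list(...)
  if (is.null(args$noise_sd))
    args$noise_sd <- c(ndvi = 0, gf = 0, yield = 0, yield_per_n = 0)
  if (is.null(args$background_variability))
    args$background_variability <- c(patch = 8, amplitude = 0)
  do.call(response_model, args)
}

# Small rendered trial, shared by ROI/pipeline tests (built once per session).
tiny_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      layout <- generate_layout(4, c(0, 40, 160), 2, seed = 11)
      model <- noiseless_model()
      truth <- simulate_plot_truth(layout, model, seed = 12)
      rend <- render_multispectral(layout, truth, gsd = 0.06,
                                   frame_size = c(512, 384), model = model,
                                   seed = 13)
      proc <- lapply(rend$frames,
                     function(f) calibrate(demosaic_cfa(f), rend$calibration))
      cache <<- list(layout = layout, model = model, truth = truth,
                     rend = rend, mosaic = mosaic_frames(proc))
    }
    cache
  }
})

# Independent per-pixel hue classifier (explicit hexagonal formula, no
# grDevices), used as the oracle for green_fractions.
oracle_fractions <- function(img, gf_bounds = c(60, 180),
                             ggf_bounds = c(80, 180)) {
  n_cls <- 0L; n_gf <- 0L; n_ggf <- 0L
  for (i in seq_len(dim(img)[1])) {
    for (j in seq_len(dim(img)[2])) {
      r <- img[i, j, 1]; g <- img[i, j, 2]; b <- img[i, j, 3]
      mx <- max(r, g, b); mn <- min(r, g, b)
      if (mx == mn) next
      h <- if (mx == r) ((g - b) / (mx - mn)) %% 6
           else if (mx == g) (b - r) / (mx - mn) + 2
           else (r - g) / (mx - mn) + 4
      h <- (h * 60) %% 360
      n_cls <- n_cls + 1L
      if (h >= gf_bounds[1] && h <= gf_bounds[2]) n_gf <- n_gf + 1L
      if (h >= ggf_bounds[1] && h <= ggf_bounds[2]) n_ggf <- n_ggf + 1L
    }
  }
  list(gf = n_gf / n_cls, ggf = n_ggf / n_cls, n = n_cls)
}

# Brute-force ROI extraction oracle: per-pixel loop, center-in-rectangle.
oracle_extract_rect <- function(raster, rect, threshold) {
  ctr <- pixel_centers(raster)
  sums <- c(green = 0, red = 0, nir = 0); veg <- 0L; tot <- 0L
  for (i in seq_along(ctr$y)) {
    for (j in seq_along(ctr$x)) {
      if (ctr$x[j] < rect[1] || ctr$x[j] > rect[3] ||
          ctr$y[i] < rect[2] || ctr$y[i] > rect[4]) next
      tot <- tot + 1L
      nir <- raster$bands$nir[i, j]; red <- raster$bands$red[i, j]
      nd <- (nir - red) / (nir + red)
      if (!is.na(nd) && nd >= threshold) {
        veg <- veg + 1L
        sums <- sums + c(raster$bands$green[i, j], red, nir)
      }
    }
  }
  list(means = sums / veg, veg = veg, tot = tot)
}

# Brute-force moving-window CV oracle.
oracle_local_cv <- function(m, window) {
  half <- (window - 1) %/% 2
  out <- matrix(NA_real_, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      ri <- max(1, i - half):min(nrow(m), i + half)
      ci <- max(1, j - half):min(ncol(m), j + half)
      v <- m[ri, ci]
      v <- v[!is.na(v)]
      if (length(v) >= 2 && mean(v) > 0)
        out[i, j] <- 100 * sd(v) / mean(v)
    }
  }
  out
}
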