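rect_poly <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

test_that("roi_set enforces unique keys and valid geometry", {
  ent <- data.frame(plot_id = c("P1", "P1"), row_index = c(1L, 2L))
  polys <- list(rect_poly(0, 0, 1, 1), rect_poly(2, 0, 3, 1))
  rs <- roi_set(ent, polys)
  expect_s3_class(rs, "roi_set")
  expect_error(roi_set(data.frame(plot_id = c("P1", "P1"),
                                  row_index = c(1L, 1L)), polys),
               "duplicate")
  bow <- cbind(x = c(0, 1, 1, 0), y = c(0, 1, 0, 1))   # self-crossing
  expect_error(roi_set(ent[1, ], list(bow)), "self-intersecting")
})

test_that("GeoJSON ROI round trip preserves structure and coordinates", {
  withr::with_tempdir({
    ent <- expand.grid(plot_id = c("P001", "P002"), row_index = 1:2,
                       stringsAsFactors = FALSE)
    polys <- lapply(seq_len(4), function(i)
      rect_poly(i + 0.123456789, -1.987654321, i + 0.9, -0.1))
    rs <- roi_set(ent, polys, provenance = "manual")
    write_roi(rs, "roi.geojson")
    back <- load_roi("roi.geojson")
    expect_equal(nrow(back$entries), 4)
    expect_equal(back$provenance, "manual")
    for (i in 1:4)
      expect_lt(max(abs(back$polygons[[i]] - rs$polygons[[i]])), 1e-9)
  })
})

test_that("auto_rows validates the buffer and produces disjoint row ROIs", {
  sc <- tiny_scene()
  expect_error(auto_rows(sc$mosaic, sc$layout, buffer = 0), "positive")
  rois <- auto_rows(sc$mosaic, sc$layout, buffer = 0.2)
  expect_equal(rois$provenance, "auto")
  expect_equal(nrow(rois$entries), nrow(sc$layout$rows))
  # rows 0.75 m apart with 0.2 m buffer: adjacent row ROIs do not overlap
  by_plot <- split(seq_len(nrow(rois$entries)), rois$entries$plot_id)
  for (ix in by_plot) {
    xr <- t(sapply(rois$polygons[ix], function(p) range(p[, "x"])))
    xr <- xr[order(xr[, 1]), , drop = FALSE]
    if (nrow(xr) > 1) expect_true(all(xr[-1, 1] >= xr[-nrow(xr), 2]))
  }
})

test_that("auto_rows ROIs contain no soil pixels on a zero-noise field", {
  sc <- tiny_scene()
  rois <- auto_rows(sc$mosaic, sc$layout)
  truth <- sc$rend$truth_raster
  canopy <- sc$rend$canopy_mask
  for (i in seq_len(nrow(rois$entries))) {
    idx <- aeropheno:::polygon_pixels(truth, rois$polygons[[i]])
    nd <- (truth$bands$nir[idx] - truth$bands$red[idx]) /
      (truth$bands$nir[idx] + truth$bands$red[idx])
    keep <- nd >= rois$entries$veg_threshold[i]
    expect_true(all(canopy[idx][keep]))
    expect_gt(sum(keep), 0)
  }
})

test_that("extraction matches a brute-force per-pixel oracle", {
  set.seed(31)
  nir <- matrix(runif(300, 0.1, 0.6), 15, 20)
  red <- matrix(runif(300, 0.02, 0.4), 15, 20)
  g <- geogrid(list(green = matrix(runif(300), 15, 20), red = red, nir = nir),
               x0 = 0, y0 = 7.5, gsd = 0.5)
  rect <- c(1.2, 1.1, 8.4, 6.3)
  rois <- roi_set(data.frame(plot_id = "P1", row_index = 1L),
                  list(rect_poly(rect[1], rect[2], rect[3], rect[4])))
  for (thr in c(0.1, 0.3, 0.5)) {
    sp <- extract_spectra(g, rois, veg_rule = thr)
    want <- oracle_extract_rect(g, rect, thr)
    expect_equal(sp$vegetation_pixel_count, want$veg)
    expect_equal(sp$total_pixel_count, want$tot)
    if (want$veg > 0)
      expect_equal(c(sp$r_green, sp$r_red, sp$r_nir), unname(want$means))
  }
})

test_that("vegetation masks behave at thresholds and degenerate ROIs", {
  # uniform canopy above threshold, soil below: exact canopy means
  nir <- matrix(0.05, 10, 10); red <- matrix(0.2, 10, 10)
  nir[3:8, 3:8] <- 0.5; red[3:8, 3:8] <- 0.05
  g <- geogrid(list(green = matrix(0.1, 10, 10), red = red, nir = nir),
               x0 = 0, y0 = 10, gsd = 1)
  rois <- roi_set(data.frame(plot_id = "P1", row_index = 1L),
                  list(rect_poly(2, 2, 8, 8)))
  sp <- extract_spectra(g, rois, veg_rule = 0.3)
  expect_false(sp$flagged)
  expect_equal(c(sp$r_green, sp$r_red, sp$r_nir), c(0.1, 0.05, 0.5))
  expect_equal(sp$vegetation_pixel_count, 36L)
  # no pixel above threshold: flagged, undefined means
  sp2 <- extract_spectra(g, rois, veg_rule = 0.99)
  expect_true(sp2$flagged)
  expect_true(is.na(sp2$r_nir))
  expect_equal(sp2$total_pixel_count, 36L)
  # raising the threshold never increases the vegetation count
  counts <- sapply(seq(-0.2, 0.9, by = 0.1), function(t)
    extract_spectra(g, rois, veg_rule = t)$vegetation_pixel_count)
  expect_true(all(diff(counts) <= 0))
  # ROI fully outside the raster: zero counts, flagged
  far <- roi_set(data.frame(plot_id = "P9", row_index = 1L),
                 list(rect_poly(100, 100, 101, 101)))
  sp3 <- extract_spectra(g, far, veg_rule = 0.3)
  expect_true(sp3$flagged)
  expect_equal(sp3$total_pixel_count, 0L)
})

test_that("half-canopy ROI keeps canopy means and half the pixels", {
  nir <- cbind(matrix(0.45, 6, 5), matrix(0.11, 6, 5))   # NDVI 0.8 | 0.1
  red <- cbind(matrix(0.05, 6, 5), matrix(0.09, 6, 5))
  g <- geogrid(list(green = matrix(0.1, 6, 10), red = red, nir = nir),
               x0 = 0, y0 = 6, gsd = 1)
  rois <- roi_set(data.frame(plot_id = "P1", row_index = 1L),
                  list(rect_poly(0, 0, 10, 6)))
  sp <- extract_spectra(g, rois, veg_rule = 0.3)
  expect_equal(sp$vegetation_pixel_count, sp$total_pixel_count / 2)
  expect_equal(c(sp$r_red, sp$r_nir), c(0.05, 0.45))
})

test_that("per-plot NDVI recovered from the tiny scene matches truth", {
  sc <- tiny_scene()
  rois <- auto_rows(sc$mosaic, sc$layout)
  sp <- extract_spectra(sc$mosaic, rois)
  idx <- build_index_table(sp, NULL, sc$layout, reference_rate = 160)
  cmp <- merge(idx, sc$truth[c("plot_id", "true_ndvi")], by = "plot_id")
  expect_true(all(abs(cmp$ndvi - cmp$true_ndvi) <= 0.02))
})
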