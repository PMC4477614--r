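test_that("the full design yields 180 plots and is balanced", {
  lay <- generate_layout(10, c(0, 10, 20, 40, 80, 160), 3, seed = 4)
  expect_equal(nrow(lay$plots), 180)
  counts <- table(lay$plots$hybrid_id, lay$plots$n_rate)
  expect_true(all(counts == 3))
  # split-plot structure: within a block each hybrid occupies one contiguous
  # main plot holding all six subplot rates
  for (b in 1:3) {
    blk <- lay$plots[lay$plots$replicate == b, ]
    spans <- do.call(rbind, lapply(split(blk, blk$hybrid_id), function(g) {
      expect_setequal(g$n_rate, c(0, 10, 20, 40, 80, 160))
      c(min(g$xmin), max(g$xmax))
    }))
    spans <- spans[order(spans[, 1]), ]
    expect_true(all(spans[-1, 1] >= spans[-nrow(spans), 2]))
  }
})

test_that("design balance holds exhaustively on a 2x2x2 design", {
  lay <- generate_layout(2, c(0, 40), 2, seed = 9)
  tab <- table(lay$plots$hybrid_id, lay$plots$n_rate)
  expect_true(all(tab == 2))
  expect_equal(nrow(lay$plots), 8)
})

test_that("layout generation is deterministic and validates inputs", {
  a <- generate_layout(3, c(0, 80), 2, seed = 21)
  b <- generate_layout(3, c(0, 80), 2, seed = 21)
  expect_identical(a, b)
  c <- generate_layout(3, c(0, 80), 2, seed = 22)
  expect_false(identical(a$plots$hybrid_id, c$plots$hybrid_id))
  expect_error(generate_layout(3, c(40, 40), 2), "distinct")
  expect_error(generate_layout(1, c(0, 40), 2), "hybrids")
})

test_that("plot rectangles are pairwise non-overlapping", {
  lay <- generate_layout(4, c(0, 10, 160), 2, seed = 2)
  p <- lay$plots
  for (i in seq_len(nrow(p) - 1)) {
    for (j in (i + 1):nrow(p)) {
      sep <- p$xmax[i] <= p$xmin[j] || p$xmax[j] <= p$xmin[i] ||
             p$ymax[i] <= p$ymin[j] || p$ymax[j] <= p$ymin[i]
      expect_true(sep)
    }
  }
})

test_that("noiseless truth follows the response model exactly", {
  lay <- generate_layout(4, c(0, 40, 160), 1, seed = 5)
  m <- noiseless_model(senescence_breakpoint = 40,
                       senescence_slopes = c(low = -0.5, high = -0.05),
                       senescence_at_zero = 60)
  tr <- simulate_plot_truth(lay, m, seed = 6)
  # two-segment line evaluated by hand: 60 at 0, 40 at 40, 34 at 160
  expect_equal(tr$true_csi[tr$n_rate == 0], rep(60, 4))
  expect_equal(tr$true_csi[tr$n_rate == 40], rep(40, 4))
  expect_equal(tr$true_csi[tr$n_rate == 160], rep(34, 4))
  # NDVI non-decreasing in rate, tolerant >= sensitive at equal rate
  for (h in unique(tr$hybrid_id)) {
    v <- tr[tr$hybrid_id == h, ]
    v <- v[order(v$n_rate), ]
    expect_true(all(diff(v$true_ndvi) >= 0))
  }
  for (r in unique(tr$n_rate)) {
    v <- tr[tr$n_rate == r, ]
    expect_gte(min(v$true_ndvi[v$tolerance_class == "tolerant"]),
               max(v$true_ndvi[v$tolerance_class == "sensitive"]))
  }
  # fraction invariants hold by construction
  expect_true(all(tr$true_ggf >= 0 & tr$true_ggf <= tr$true_gf &
                    tr$true_gf <= 1))
  expect_equal(tr$true_csi, 100 * (tr$true_gf - tr$true_ggf) / tr$true_gf)
})

test_that("rendered scene geometry matches the imaging configuration", {
  sc <- tiny_scene()
  # row footprint: 4 m rows at 60 mm/px span ~66 pixels along the row axis
  mask <- sc$rend$canopy_mask
  tr <- sc$rend$truth_raster$transform
  j <- floor((sc$layout$rows$x[1] - tr$x0) / tr$gsd) + 1
  runs <- rle(mask[, j])
  lens <- runs$lengths[runs$values]
  expect_true(all(abs(lens - floor(4 / 0.06)) <= 1))
  # frame footprint at full sensor size: 2048 x 1536 px at 0.06 m/px
  expect_equal(2048 * 0.06, 122.88)
  expect_equal(1536 * 0.06, 92.16)
  fr <- sc$rend$frames[[1]]
  e <- raster_extent(fr)
  expect_equal(unname(e[["xmax"]] - e[["xmin"]]), 512 * 0.06)
  # too-coarse resolution is refused
  expect_error(render_multispectral(sc$layout, sc$truth, gsd = 0.4,
                                    frame_size = c(64, 64), model = sc$model),
               "resolution")
})

test_that("zero-amplitude scenes have constant soil and exact canopy", {
  sc <- tiny_scene()
  soil <- !sc$rend$canopy_mask
  for (b in band_names(sc$rend$truth_raster)) {
    v <- sc$rend$truth_raster$bands[[b]][soil]
    expect_equal(max(v) - min(v), 0)
  }
  # rendering is deterministic
  r2 <- render_multispectral(sc$layout, sc$truth, gsd = 0.06,
                             frame_size = c(512, 384), model = sc$model,
                             seed = 13)
  expect_identical(r2$frames[[1]]$bands$cfa, sc$rend$frames[[1]]$bands$cfa)
})

test_that("render_rgb inverts the hue classifier up to one-pixel rounding", {
  img <- render_rgb(list(true_gf = 0.5, true_ggf = 0.4),
                    image_size = c(100, 1), seed = 3)
  fr <- green_fractions(img)
  expect_equal(fr$classifiable_pixel_count, 100)
  expect_equal(fr$gf, 0.5)
  expect_equal(fr$ggf, 0.4)

  img1 <- render_rgb(list(true_gf = 1, true_ggf = 1), c(8, 8), seed = 1)
  fr1 <- green_fractions(img1)
  expect_equal(fr1$gf, 1)
  expect_equal(fr1$ggf, 1)
  expect_equal(crop_senescence_index(fr1), 0)

  img0 <- render_rgb(list(true_gf = 0, true_ggf = 0), c(8, 8), seed = 1)
  fr0 <- green_fractions(img0)
  expect_equal(fr0$gf, 0)
  expect_true(is.na(crop_senescence_index(fr0)))

  expect_identical(render_rgb(list(true_gf = 0.3, true_ggf = 0.1),
                              c(16, 16), seed = 5),
                   render_rgb(list(true_gf = 0.3, true_ggf = 0.1),
                              c(16, 16), seed = 5))
})

test_that("requested fractions are recovered within 1/n over random cases", {
  set.seed(42)
  for (k in 1:20) {
    gf <- runif(1); ggf <- runif(1, 0, gf)
    n <- c(24, 18)
    img <- render_rgb(list(true_gf = gf, true_ggf = ggf), n, seed = k)
    fr <- green_fractions(img)
    expect_lte(abs(fr$gf - gf), 1 / prod(n) + 1e-12)
    expect_lte(abs(fr$ggf - ggf), 1 / prod(n) + 1e-12)
  }
})
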