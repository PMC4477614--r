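# Builds CFA fixtures directly from the tiling so the demosaicer is tested
# against known per-band signals.
make_cfa <- function(fun, h, w, pattern = cfa_pattern()) {
  m <- matrix(0, h, w)
  for (pr in 1:2) for (pc in 1:2) {
    ri <- seq(pr, h, 2); ci <- seq(pc, w, 2)
    for (i in ri) for (j in ci) m[i, j] <- fun(pattern[pr, pc], i, j)
  }
  m
}

test_that("demosaicing reproduces band-constant frames exactly", {
  expect_equal_band <- function(out, vals) {
    for (b in names(vals)) expect_equal(out$bands[[b]],
                                        matrix(vals[[b]], 4, 4))
  }
  # constant frame
  cst <- demosaic_cfa(matrix(7, 4, 4))
  expect_equal_band(cst, list(green = 7, red = 7, nir = 7))
  # distinct per-band constants survive interpolation untouched
  vals <- c(green = 10, red = 20, nir = 30)
  frame <- make_cfa(function(b, i, j) vals[[b]], 4, 4)
  out <- demosaic_cfa(frame)
  expect_equal_band(out, as.list(vals))
})

test_that("bilinear demosaicing is exact for affine signals at interior pixels", {
  f <- function(b, i, j) 2 * i + 3 * j + 5   # affine ramp, all bands
  frame <- make_cfa(f, 10, 12)
  out <- demosaic_cfa(frame)
  interior <- expand.grid(i = 3:8, j = 3:10)
  for (b in c("green", "red", "nir")) {
    got <- out$bands[[b]][cbind(interior$i, interior$j)]
    expect_equal(got, 2 * interior$i + 3 * interior$j + 5)
  }
  # horizontal ramp in the red sensels only
  frame2 <- make_cfa(function(b, i, j) if (b == "red") 4 * j else 0, 8, 8)
  out2 <- demosaic_cfa(frame2)
  expect_equal(out2$bands$red[3:6, 3:6],
               outer(rep(1, 4), 4 * (3:6)))
})

test_that("demosaic rejects bad patterns and odd dimensions", {
  expect_error(demosaic_cfa(matrix(0, 3, 4)), "even")
  bad <- matrix(c("green", "green", "green", "red"), 2, 2)
  expect_error(demosaic_cfa(matrix(0, 4, 4), bad), "invalid pattern")
})

test_that("calibration applies the empirical line and counts clipping", {
  g <- geogrid(list(green = matrix(1000, 2, 2)), gsd = 1)
  ident <- calibration_model(gain = c(green = 1))
  expect_error(calibrate(g, ident), NA)
  m <- calibration_model(gain = c(green = 5e-4), offset = c(green = 100))
  out <- calibrate(g, m)
  expect_equal(out$bands$green, matrix(0.45, 2, 2))
  expect_equal(attr(out, "clipped"), 0L)
  # linearity with zero offset
  g2 <- geogrid(list(green = matrix(c(100, 200, 400, 700), 2, 2)), gsd = 1)
  m2 <- calibration_model(gain = c(green = 1e-3))
  expect_equal(calibrate(g2, m2)$bands$green * 2,
               calibrate(geogrid(list(green = g2$bands$green * 2), gsd = 1),
                         m2)$bands$green)
  # values above 1.5 are clipped and reported
  hot <- geogrid(list(green = matrix(c(10000, 100), 1, 2)), gsd = 1)
  outh <- calibrate(hot, m2)
  expect_equal(outh$bands$green[1, 1], 1.5)
  expect_equal(attr(outh, "clipped"), 1L)
})

test_that("panel calibration closes: panel pixels read panel reflectance", {
  dn <- matrix(500, 8, 8)
  dn[3:6, 3:6] <- 2000                     # the panel block
  frame <- geogrid(list(green = dn, red = dn * 2, nir = dn * 4), gsd = 0.1)
  refl <- c(green = 0.5, red = 0.5, nir = 0.5)
  cal <- estimate_panel_calibration(frame, list(rows = 3:6, cols = 3:6), refl)
  expect_equal(unname(cal$gain[["green"]]), 2.5e-4)
  # equal DN, different reflectance -> gains in the reflectance ratio
  cal2 <- estimate_panel_calibration(
    geogrid(list(green = dn, red = dn), gsd = 0.1),
    list(rows = 3:6, cols = 3:6), c(green = 0.5, red = 0.25))
  expect_equal(unname(cal2$gain[["green"]] / cal2$gain[["red"]]), 2)
  # closure: applying the model back reproduces the panel reflectance
  out <- calibrate(frame, cal)
  for (b in band_names(out))
    expect_lt(max(abs(out$bands[[b]][3:6, 3:6] - 0.5)), 1e-6)
  expect_error(estimate_panel_calibration(frame, list(rows = integer(0),
                                                      cols = 1:2), refl),
               "empty")
})

test_that("mosaicking one frame is the identity", {
  sc <- tiny_scene()
  f <- calibrate(demosaic_cfa(sc$rend$frames[[1]]), sc$rend$calibration)
  m <- mosaic_frames(list(f))
  expect_equal(m$bands, f$bands)
  expect_equal(m$transform, f$transform)
})

test_that("non-overlapping frames keep their own footprints, nodata between", {
  a <- geogrid(list(v = matrix(1, 4, 4)), x0 = 0, y0 = 0, gsd = 1)
  b <- geogrid(list(v = matrix(2, 4, 4)), x0 = 8, y0 = 0, gsd = 1)
  m <- mosaic_frames(list(a, b))
  expect_equal(dim(m)[1:2], c(4L, 12L))
  expect_equal(m$bands$v[, 1:4], matrix(1, 4, 4))
  expect_equal(m$bands$v[, 9:12], matrix(2, 4, 4))
  expect_true(all(is.na(m$bands$v[, 5:8])))
})

test_that("overlap is split by the perpendicular bisector of frame centers", {
  a <- geogrid(list(v = matrix(1, 4, 8)), x0 = 0, y0 = 0, gsd = 1)
  b <- geogrid(list(v = matrix(2, 4, 8)), x0 = 4, y0 = 0, gsd = 1)
  m <- mosaic_frames(list(a, b))
  # brute-force nearest-center oracle
  ctr <- pixel_centers(m)
  for (i in 1:4) for (j in 1:12) {
    da <- (ctr$x[j] - 4)^2; db <- (ctr$x[j] - 8)^2
    want <- if (j <= 4) 1 else if (j > 8) 2 else if (da <= db) 1 else 2
    expect_equal(m$bands$v[i, j], want)
  }
})

test_that("mosaic rejects mixed gsd and conserves pixel values", {
  a <- geogrid(list(v = matrix(1, 2, 2)), gsd = 1)
  b <- geogrid(list(v = matrix(1, 2, 2)), gsd = 0.5)
  expect_error(mosaic_frames(list(a, b)), "resample")
  # conservation: every valid mosaic pixel appears in an input at the same
  # world position
  set.seed(8)
  f1 <- geogrid(list(v = matrix(runif(16), 4, 4)), x0 = 0, y0 = 0, gsd = 1)
  f2 <- geogrid(list(v = matrix(runif(16), 4, 4)), x0 = 2, y0 = -1, gsd = 1)
  m <- mosaic_frames(list(f1, f2))
  ctr <- pixel_centers(m)
  for (i in seq_along(ctr$y)) for (j in seq_along(ctr$x)) {
    v <- m$bands$v[i, j]
    if (is.na(v)) next
    hit <- FALSE
    for (f in list(f1, f2)) {
      px <- world_to_pixel(f, ctr$x[j], ctr$y[i])
      d <- dim(f)[1:2]
      if (px[1] >= 1 && px[1] <= d[1] && px[2] >= 1 && px[2] <= d[2] &&
          isTRUE(all.equal(f$bands$v[px[1], px[2]], v))) hit <- TRUE
    }
    expect_true(hit)
  }
})
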