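test_that("Gaussian smoothing: identity cases and impulse response", {
  img <- RasterImage(matrix(0.4, 10, 10))
  expect_equal(imgData(gaussianSmooth(img, 2)), imgData(img), tolerance = 1e-12)
  rnd <- RasterImage(matrix(runif(100), 10, 10))
  expect_identical(imgData(gaussianSmooth(rnd, 0)), imgData(rnd))
  expect_error(gaussianSmooth(rnd, -1), "sigma")

  # unit impulse: center value equals the peak of the normalized truncated
  # separable kernel (radius 3 for sigma = 1)
  m <- matrix(0, 9, 9); m[5, 5] <- 1
  sm <- imgData(gaussianSmooth(RasterImage(m), 1))[, , 1]
  k <- exp(-(-3:3)^2 / 2); k <- k / sum(k)
  expect_equal(sm[5, 5], k[4]^2, tolerance = 1e-12)
  expect_equal(sm[4, 5], k[3] * k[4], tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-12)  # mass conserved (reflection)
})

test_that("morphological gradient: constant, step edge and offset invariance", {
  cst <- RasterImage(matrix(0.7, 12, 12))
  expect_equal(max(imgData(morphGradient(cst))), 0)

  # vertical step edge, square SE radius 1: brute-force 3x3 window max - min
  m <- matrix(0.2, 10, 12); m[, 7:12] <- 0.6
  g <- imgData(morphGradient(grayRaster(m),
                             structuringElement("square", 1L)))[, , 1]
  oracle <- m
  for (i in 1:10) for (j in 1:12) {
    win <- m[max(1, i - 1):min(10, i + 1), max(1, j - 1):min(12, j + 1)]
    oracle[i, j] <- max(win) - min(win)
  }
  expect_equal(g, oracle, tolerance = 1e-12)
  expect_true(all(g[, c(1:5, 8:12)] == 0))
  expect_equal(g[, 6:7], matrix(0.4, 10, 2), tolerance = 1e-12)

  g2 <- imgData(morphGradient(grayRaster(m + 0.1),
                              structuringElement("square", 1L)))[, , 1]
  expect_equal(g2, g, tolerance = 1e-12)
  expect_error(morphGradient(RasterImage(array(runif(300), c(10, 10, 3)))),
               "luminance")
})

test_that("reconstruction: fixpoint, 1-D example, idempotence, bracketing", {
  msk <- grayRaster(matrix(runif(100), 10, 10))
  expect_equal(imgData(reconstruct(msk, msk, "dilation")), imgData(msk))

  # 1-D profile (scaled into [0,1]): marker peak under the 0.3 bump survives,
  # the disconnected 0.2 bump is not reached
  row <- c(0, 0.2, 0, 0.3, 0, 0, 0, 0)
  mask1 <- grayRaster(matrix(rep(row, each = 8), 8, 8, byrow = FALSE))
  mk <- matrix(0, 8, 8); mk[, 4] <- 0.1
  rec <- imgData(reconstruct(grayRaster(mk), mask1, "dilation"))[, , 1]
  expect_equal(rec[1, ], c(0, 0, 0, 0.1, 0, 0, 0, 0))

  set.seed(99)
  for (i in 1:20) {
    a <- matrix(sample(0:9, 256, TRUE) / 10, 16, 16)
    b <- matrix(sample(0:9, 256, TRUE) / 10, 16, 16)
    mkR <- grayRaster(pmin(a, b)); msR <- grayRaster(pmax(a, b))
    r <- reconstruct(mkR, msR, "dilation")
    expect_true(all(imgData(r) >= imgData(mkR) - 1e-12))
    expect_true(all(imgData(r) <= imgData(msR) + 1e-12))
    r2 <- reconstruct(r, msR, "dilation")
    expect_identical(imgData(r2), imgData(r))  # idempotent
  }
  expect_error(reconstruct(msk, grayRaster(matrix(0, 10, 10)), "dilation"),
               "marker")
})

test_that("reconstruction by erosion is the dual of reconstruction by dilation", {
  set.seed(4)
  a <- matrix(sample(0:9, 144, TRUE) / 10, 12, 12)
  b <- matrix(sample(0:9, 144, TRUE) / 10, 12, 12)
  mk <- pmax(a, b); ms <- pmin(a, b)
  byEro <- imgData(reconstruct(grayRaster(mk), grayRaster(ms), "erosion"))[, , 1]
  dual <- 1 - imgData(reconstruct(grayRaster(1 - mk), grayRaster(1 - ms),
                                  "dilation"))[, , 1]
  expect_equal(byEro, dual, tolerance = 1e-12)
})

test_that("opening/closing by reconstruction: ordering, idempotence, speckle removal", {
  cst <- grayRaster(matrix(0.3, 10, 10))
  expect_equal(imgData(openCloseByReconstruction(cst, which = "opening")),
               imgData(cst))
  expect_equal(imgData(openCloseByReconstruction(cst, which = "closing")),
               imgData(cst))

  set.seed(12)
  img <- grayRaster(matrix(runif(196), 14, 14))
  se <- structuringElement("disk", 1L)
  op <- openCloseByReconstruction(img, se, "opening")
  cl <- openCloseByReconstruction(img, se, "closing")
  expect_true(all(imgData(op) <= imgData(img) + 1e-12))
  expect_true(all(imgData(img) <= imgData(cl) + 1e-12))
  expect_equal(imgData(openCloseByReconstruction(op, se, "opening")),
               imgData(op), tolerance = 1e-12)

  # single bright pixel dies under opening: erosion kills it and
  # reconstruction of a zero marker is zero
  spk <- matrix(0, 9, 9); spk[5, 5] <- 1
  expect_equal(max(imgData(openCloseByReconstruction(grayRaster(spk), se,
                                                     "opening"))), 0)
})

test_that("mmgr equals the explicit per-radius loop and is monotone in r2", {
  set.seed(21)
  g <- grayRaster(matrix(sample(0:20, 256, TRUE) / 20, 16, 16))
  out <- imgData(mmgr(g, 1L, 3L))[, , 1]
  acc <- NULL
  for (r in 1:3) {
    m <- imgData(openCloseByReconstruction(g, structuringElement("disk", r),
                                           "closing"))[, , 1]
    acc <- if (is.null(acc)) m else pmax(acc, m)
  }
  expect_identical(out, acc)

  single <- imgData(mmgr(g, 2L, 2L))[, , 1]
  expect_identical(single,
    imgData(openCloseByReconstruction(g, structuringElement("disk", 2L),
                                      "closing"))[, , 1])
  expect_true(all(imgData(mmgr(g, 1L, 4L)) >= imgData(mmgr(g, 1L, 3L)) - 1e-15))
  expect_true(all(out >= imgData(openCloseByReconstruction(g,
    structuringElement("disk", 1L), "closing"))[, , 1] - 1e-15))
  expect_error(mmgr(g, 3L, 2L), "r1 <= r2")
})

test_that("watershed: constant input, two basins, and the partition property", {
  expect_equal(nRegions(watershedSuperpixels(grayRaster(matrix(0.5, 9, 9)))), 1L)

  p <- c(0, 0.25, 0.5, 0.25, 0, 0, 0, 0, 0)
  g <- matrix(p[col(matrix(0, 8, 9))], 8, 9)
  lm <- watershedSuperpixels(grayRaster(g))
  expect_equal(nRegions(lm), 2L)
  lab <- labelData(lm)
  expect_true(all(lab[, 1:2] == lab[1, 1]))
  expect_true(all(lab[, 4:9] == lab[1, 5]))
  expect_true(lab[1, 1] != lab[1, 5])

  set.seed(8)
  g2 <- grayRaster(matrix(runif(400), 20, 20))
  lm2 <- watershedSuperpixels(g2)
  cnt <- tabulate(labelData(lm2), nRegions(lm2))
  expect_true(all(cnt >= 1L))           # labels 1..n all occur, no gaps
  expect_equal(sum(cnt), 400L)          # true partition
})

test_that("superpixel region count does not increase with the MMGR radius ceiling", {
  ph <- generatePhantom(phantomSpec("consolidation", seed = 2))
  lum <- SPFKMC:::grayImage(SPFKMC:::toLuminance(gaussianSmooth(ph$image, 1)))
  grad <- morphGradient(lum)
  nreg <- vapply(c(1L, 2L, 3L, 5L), function(r2)
    nRegions(watershedSuperpixels(mmgr(grad, 1L, r2))), integer(1))
  expect_true(all(diff(nreg) <= 0L))
  expect_gte(nreg[2], 50L)   # the default r2 = 2 keeps a rich presegmentation
})

test_that("superpixel mean image flattens regions to their means, idempotently", {
  img <- grayRaster(matrix(c(rep(0.2, 32), rep(0.4, 32), rep(0.8, 64)), 8, 16))
  labs <- LabelMap(matrix(rep(c(1L, 1L, 2L), c(4, 4, 8)), 8, 16, byrow = TRUE))
  flat <- superpixelMeanImage(img, labs)
  expect_equal(unique(as.vector(imgData(flat))), c(0.3, 0.8))

  single <- LabelMap(matrix(1L, 8, 16))
  expect_equal(unique(as.vector(imgData(superpixelMeanImage(img, single)))),
               mean(imgData(img)))
  again <- superpixelMeanImage(flat, labs)
  expect_equal(imgData(again), imgData(flat), tolerance = 1e-15)
  expect_error(superpixelMeanImage(img, LabelMap(matrix(1L, 8, 8))), "size")
})
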