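test_that("binary dilation and erosion match brute-force window logic", {
  emp <- BinaryMask(matrix(FALSE, 10, 10))
  expect_equal(sum(maskData(dilateMask(emp))), 0)

  one <- matrix(FALSE, 10, 10); one[5, 5] <- TRUE
  d1 <- dilateMask(BinaryMask(one), structuringElement("square", 1L))
  expect_identical(which(maskData(d1)),
                   which(row(one) %in% 4:6 & col(one) %in% 4:6))

  blk <- matrix(FALSE, 10, 10); blk[4:6, 4:6] <- TRUE
  e1 <- erodeMask(BinaryMask(blk), structuringElement("square", 1L))
  expect_identical(which(maskData(e1)), which(row(blk) == 5 & col(blk) == 5))

  # SE composition: two radius-1 square dilations equal one radius-2
  set.seed(81)
  m <- randomMask(16, 16, 0.2)
  twice <- dilateMask(dilateMask(m, structuringElement("square", 1L)),
                      structuringElement("square", 1L))
  once <- dilateMask(m, structuringElement("square", 2L))
  expect_identical(maskData(twice), maskData(once))
})

test_that("erosion/dilation duality and opening/closing ordering hold", {
  set.seed(82)
  se <- structuringElement("disk", 1L)
  for (i in 1:100) {
    m <- randomMask(16, 16)
    dual <- BinaryMask(!maskData(dilateMask(BinaryMask(!maskData(m)), se)))
    expect_identical(maskData(erodeMask(m, se)), maskData(dual))
  }
  m <- randomMask(20, 20, 0.4)
  op <- dilateMask(erodeMask(m))          # opening
  cl <- erodeMask(dilateMask(m))          # closing
  expect_true(all(maskData(op) <= maskData(m)))
  expect_true(all(maskData(m) <= maskData(cl)))
  op2 <- dilateMask(erodeMask(op))
  expect_identical(maskData(op2), maskData(op))   # idempotent
  expect_identical(maskData(openMask(openMask(m))), maskData(openMask(m)))
})

test_that("boundary extraction yields one-pixel contours", {
  expect_equal(sum(maskData(extractBoundary(BinaryMask(matrix(FALSE, 9, 9))))), 0)

  sq <- matrix(FALSE, 12, 12); sq[4:8, 4:8] <- TRUE
  b <- extractBoundary(BinaryMask(sq))
  expect_equal(sum(maskData(b)), 16)       # perimeter of a 5x5 solid square
  b2 <- extractBoundary(b)
  expect_identical(maskData(b2), maskData(b))   # thin sets are fixed points
})

test_that("color overlay blends only masked pixels", {
  img <- RasterImage(matrix(0.2, 8, 8))
  emp <- BinaryMask(matrix(FALSE, 8, 8))
  same <- applyColorMask(img, emp)
  expect_equal(imgData(same)[, , 1], matrix(0.2, 8, 8))

  full <- BinaryMask(matrix(TRUE, 8, 8))
  red <- applyColorMask(img, full, color = c(1, 0, 0), alpha = 1)
  expect_equal(unique(as.vector(imgData(red)[, , 1])), 1)
  expect_equal(unique(as.vector(imgData(red)[, , 2])), 0)

  one <- matrix(FALSE, 8, 8); one[3, 4] <- TRUE
  half <- applyColorMask(img, BinaryMask(one), color = c(1, 0, 0), alpha = 0.5)
  expect_equal(imgData(half)[3, 4, 1], 0.5 * 0.2 + 0.5 * 1.0)  # blend formula
  expect_equal(imgData(half)[3, 4, 2], 0.1)
  expect_equal(imgData(half)[1, 1, 1], 0.2)
  expect_error(applyColorMask(img, BinaryMask(matrix(TRUE, 9, 9))), "size")
})

test_that("pattern classification maximizes zero-mean correlation", {
  plus <- matrix(0, 9, 9); plus[4:6, 5] <- 1; plus[5, 4:6] <- 1
  corner <- matrix(0, 9, 9); corner[1:3, 1:3] <- 1
  seg <- grayRaster(plus)
  tpl <- list(plus = grayRaster(plus), corner = grayRaster(corner))

  res <- classifyPattern(seg, tpl)
  expect_equal(res$label, "plus")
  expect_equal(res$score, 1, tolerance = 1e-12)
  expect_equal(unname(res$scores["plus"]), cor(as.vector(plus), as.vector(plus)))
  expect_equal(unname(res$scores["corner"]),
               cor(as.vector(plus), as.vector(corner)), tolerance = 1e-12)

  # negative image scores -1
  neg <- grayRaster(1 - plus)
  expect_equal(classifyPattern(neg, tpl["plus"])$score, -1, tolerance = 1e-12)

  # affine intensity rescaling leaves the score unchanged
  resc <- grayRaster(0.2 + 0.5 * plus)
  expect_equal(classifyPattern(resc, tpl)$score, res$score, tolerance = 1e-9)

  # zero-variance input is defined as score 0
  flat <- grayRaster(matrix(0.4, 9, 9))
  expect_equal(classifyPattern(flat, tpl)$scores[["plus"]], 0)
  expect_error(classifyPattern(seg, list()), "template")
})

test_that("template libraries load from labeled files", {
  d <- file.path(tempdir(), "tpl")
  dir.create(d, showWarnings = FALSE)
  writeRaster(grayRaster(matrix(runif(64), 8, 8)), file.path(d, "nodular.png"))
  writeRaster(grayRaster(matrix(runif(64), 8, 8)), file.path(d, "reticular.png"))
  tpl <- loadTemplates(d)
  expect_setequal(names(tpl), c("nodular", "reticular"))
  expect_s4_class(tpl$nodular, "RasterImage")
})
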