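# Two-level discrete wavelet decomposition of selected cluster images,
# coefficient-level fusion and reconstruction.
#
# The 1-D transform follows the standard convolution/decimation scheme with
# half-sample symmetric boundary extension: analysis keeps
# floor((n + p - 1) / 2) coefficients per band (p = filter length), which
# makes the transform perfectly invertible for arbitrary n once the input
# length at each level is recorded.

waveletFilters <- function(name) {
  dec_lo <- switch(name,
    haar = c(1, 1) / sqrt(2),
    db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
            -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
            0.7148465705529157, 0.2303778133088965),
    stop("unsupported wavelet '", name, "' (available: db4, haar)"))
  rec_lo <- rev(dec_lo)
  p <- length(dec_lo)
  dec_hi <- rec_lo * (-1)^seq_len(p)
  list(dec_lo = dec_lo, dec_hi = dec_hi, rec_lo = rec_lo,
       rec_hi = rev(dec_hi), p = p)
}

# analysis along matrix columns (dim 1), both bands
dwtCols <- function(m, f) {
  n <- nrow(m); p <- f$p
  mp <- m[reflectIdx(n, p - 1L), , drop = FALSE]
  len <- n + p - 1L
  a <- matrix(0, len, ncol(m)); d <- a
  for (j in seq_len(p)) {
    sl <- mp[(p - j) + seq_len(len), , drop = FALSE]
    a <- a + f$dec_lo[j] * sl
    d <- d + f$dec_hi[j] * sl
  }
  keep <- seq(2L, len, by = 2L)
  list(a = a[keep, , drop = FALSE], d = d[keep, , drop = FALSE])
}

# synthesis along matrix columns to length n
idwtCols <- function(a, d, n, f) {
  p <- f$p; la <- nrow(a)
  up <- matrix(0, 2L * la + 2L * (p - 1L), ncol(a))
  ud <- up
  rows <- p - 1L + seq(1L, 2L * la, by = 2L)
  up[rows, ] <- a
  ud[rows, ] <- d
  len <- nrow(up) - p + 1L
  y <- matrix(0, len, ncol(a))
  for (j in seq_len(p))
    y <- y + f$rec_lo[j] * up[(p - j) + seq_len(len), , drop = FALSE] +
             f$rec_hi[j] * ud[(p - j) + seq_len(len), , drop = FALSE]
  y[(p - 2L) + seq_len(n), , drop = FALSE]
}

dwt2step <- function(m, f) {
  cols <- dwtCols(m, f)
  aa <- dwtCols(t(cols$a), f)   # operate along original dim 2
  dd <- dwtCols(t(cols$d), f)
  list(a = t(aa$a), h = t(aa$d), v = t(dd$a), d = t(dd$d))
}

idwt2step <- function(bands, size, f) {
  arow <- t(idwtCols(t(bands$a), t(bands$h), size[2], f))
  drow <- t(idwtCols(t(bands$v), t(bands$d), size[2], f))
  idwtCols(arow, drow, size[1], f)
}

#' Multilevel 2-D discrete wavelet decomposition
#'
#' Separable analysis with half-sample symmetric boundary extension.
#' Defaults follow the pipeline's fusion stage: Daubechies-4 (`db4`), two
#' levels. The decomposition is perfectly invertible by [idwt2()] (round
#' trip below 1e-8 absolute error).
#'
#' @param img single-channel [RasterImage-class] or numeric matrix.
#' @param wavelet `"db4"` (default) or `"haar"`.
#' @param levels number of decomposition levels; default 2.
#' @return a [WaveletPyramid-class].
#' @export
dwt2 <- function(img, wavelet = "db4", levels = 2L) {
  m <- if (is(img, "RasterImage")) {
    if (nChannels(img) != 1L) stop("single-channel image required")
    imgData(img)[, , 1]
  } else as.matrix(img)
  f <- waveletFilters(wavelet)
  if (levels < 1L) stop("levels must be >= 1")
  details <- vector("list", levels)
  sizes <- vector("list", levels)
  cur <- m
  for (j in seq_len(levels)) {
    if (min(dim(cur)) < f$p)
      stop("image too small for ", wavelet, " at level ", j,
           " (needs >= ", f$p, " pixels per side, has ", min(dim(cur)), ")")
    sizes[[j]] <- dim(cur)
    st <- dwt2step(cur, f)
    details[[j]] <- st[c("h", "v", "d")]
    cur <- st$a
  }
  new("WaveletPyramid", wavelet = wavelet, levels = as.integer(levels),
      approx = cur, details = details, sizes = sizes)
}

#' Inverse multilevel 2-D wavelet transform
#'
#' @param p a [WaveletPyramid-class].
#' @return the reconstructed image as a numeric matrix (cropped to the
#'   original shape recorded in the pyramid).
#' @export
idwt2 <- function(p) {
  stopifnot(is(p, "WaveletPyramid"))
  f <- waveletFilters(p@wavelet)
  cur <- p@approx
  for (j in rev(seq_len(p@levels))) {
    dl <- p@details[[j]]
    if (!all(dim(dl$h) == dim(cur)))
      stop("corrupted pyramid: band shapes disagree at level ", j)
    cur <- idwt2step(list(a = cur, h = dl$h, v = dl$v, d = dl$d),
                     p@sizes[[j]], f)
  }
  cur
}

#' Fuse two wavelet pyramids coefficient-wise
#'
#' `max_abs` (pixel-level maxima) keeps, at every coefficient of every band,
#' the source coefficient of larger magnitude (ties go to the first
#' pyramid); magnitude rather than signed comparison is used because detail
#' coefficients are signed. `mean` takes the arithmetic mean, which by
#' linearity of the transform reconstructs to the average image.
#'
#' @param pa,pb [WaveletPyramid-class] objects with identical wavelet,
#'   levels and band shapes.
#' @param rule `"max_abs"` (default) or `"mean"`.
#' @return the fused [WaveletPyramid-class].
#' @export
fusePyramids <- function(pa, pb, rule = c("max_abs", "mean")) {
  rule <- match.arg(rule)
  stopifnot(is(pa, "WaveletPyramid"), is(pb, "WaveletPyramid"))
  if (pa@wavelet != pb@wavelet || pa@levels != pb@levels ||
      !all(dim(pa@approx) == dim(pb@approx)))
    stop("pyramids must share wavelet, levels and band shapes")
  comb <- if (rule == "mean") function(a, b) (a + b) / 2
          else function(a, b) ifelse(abs(b) > abs(a), b, a)
  details <- vector("list", pa@levels)
  for (j in seq_len(pa@levels)) {
    da <- pa@details[[j]]; db <- pb@details[[j]]
    if (!all(dim(da$h) == dim(db$h)))
      stop("pyramids must share wavelet, levels and band shapes")
    details[[j]] <- list(h = comb(da$h, db$h), v = comb(da$v, db$v),
                         d = comb(da$d, db$d))
  }
  new("WaveletPyramid", wavelet = pa@wavelet, levels = pa@levels,
      approx = comb(pa@approx, pb@approx), details = details,
      sizes = pa@sizes)
}

#' Fuse selected cluster images into a segmentation mask
#'
#' The fusion answer to multi-cluster belonging: when the object of interest
#' is split across two K-means clusters, their cluster images are decomposed
#' ([dwt2()]), combined band-wise ([fusePyramids()]) and reconstructed
#' ([idwt2()]); the union of the object's parts survives in the fused image.
#' The binary mask keeps pixels above `binarizeThreshold` times the fused
#' maximum. A single image bypasses fusion and is thresholded directly; an
#' all-zero input yields an empty mask.
#'
#' @param images list of 1 or 2 single-channel [RasterImage-class] objects.
#' @param wavelet,levels,rule see [dwt2()] and [fusePyramids()].
#' @param binarizeThreshold fraction of the fused maximum; default 0.5.
#' @return list with elements `fused` ([RasterImage-class]) and `mask`
#'   ([BinaryMask-class]).
#' @export
fuseClusterImages <- function(images, wavelet = "db4", levels = 2L,
                              rule = "max_abs", binarizeThreshold = 0.5) {
  if (!length(images) %in% c(1L, 2L))
    stop("fusion takes exactly 1 or 2 cluster images (got ", length(images), ")")
  if (length(images) == 1L) {
    fm <- imgData(images[[1]])[, , 1]
  } else {
    if (!all(dim(images[[1]]) == dim(images[[2]])))
      stop("cluster images must have equal size")
    pf <- fusePyramids(dwt2(images[[1]], wavelet, levels),
                       dwt2(images[[2]], wavelet, levels), rule)
    fm <- idwt2(pf)
  }
  mx <- max(fm)
  mask <- if (mx <= 0) matrix(FALSE, nrow(fm), ncol(fm))
          else fm > binarizeThreshold * mx
  list(fused = grayImage(fm), mask = BinaryMask(mask))
}
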