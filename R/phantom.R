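# Synthetic ILD slice generator: 240 x 320 lung-field look-alikes carrying
# the five canonical HRCT patterns with known ground-truth masks. This is
# the package's test bed; the geometry and intensity constants are design
# choices (documented in the methods vignette), exposed through PhantomSpec.

BG_INTENSITY <- 0.05
LUNG_INTENSITY <- 0.35

categoryDefaults <- function(category) {
  switch(category,
    healthy       = list(n = 0L, size = 0),
    consolidation = list(n = 2L, size = 22),
    emphysema     = list(n = 4L, size = 11),
    fibrosis      = list(n = 10L, size = 6),
    ground_glass  = list(n = 1L, size = 32),
    micronodules  = list(n = 7L, size = 6))
}

#' Construct a PhantomSpec
#'
#' @param category one of `healthy`, `consolidation`, `emphysema`,
#'   `fibrosis`, `ground_glass`, `micronodules`.
#' @param seed integer random seed; identical specs generate bitwise
#'   identical phantoms.
#' @param height,width image size; default 240 x 320, the pipeline's
#'   working geometry.
#' @param nLesions lesion count; `NA` uses the per-category default
#'   (consolidation 2, emphysema 4, fibrosis 10 strokes, ground glass 1,
#'   micronodules 7).
#' @param lesionSize mean lesion radius/scale in pixels; `NA` for the
#'   category default.
#' @param noiseSigma additive Gaussian noise sd; default 0.02.
#' @param blurLen horizontal motion-blur length in pixels; default 0 (off).
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(category, seed = 0L, height = 240L, width = 320L,
                        nLesions = NA, lesionSize = NA, noiseSigma = 0.02,
                        blurLen = 0L) {
  def <- categoryDefaults(category)
  if (is.null(def)) stop("unknown phantom category: ", category)
  if (is.na(nLesions)) nLesions <- def$n
  if (is.na(lesionSize)) lesionSize <- def$size
  new("PhantomSpec", height = as.integer(height), width = as.integer(width),
      category = category, nLesions = as.integer(nLesions),
      lesionSize = as.numeric(lesionSize), noiseSigma = noiseSigma,
      blurLen = as.integer(blurLen), seed = as.integer(seed))
}

# normalized squared elliptical radius for both lung fields; list of two
# h x w matrices
lungRho2 <- function(h, w, shrink = 0) {
  Y <- matrix(seq_len(h), h, w)
  X <- matrix(seq_len(w), h, w, byrow = TRUE)
  cy <- 0.5 * h
  ry <- 0.37 * h - shrink
  rx <- 0.16 * w - shrink
  lapply(c(0.30, 0.70), function(fx)
    ((Y - cy) / ry)^2 + ((X - fx * w) / rx)^2)
}

diskMask <- function(h, w, cy, cx, r) {
  Y <- matrix(seq_len(h), h, w)
  X <- matrix(seq_len(w), h, w, byrow = TRUE)
  (Y - cy)^2 + (X - cx)^2 <= r^2
}

ellipseMask <- function(h, w, cy, cx, ry, rx, theta) {
  Y <- matrix(seq_len(h), h, w) - cy
  X <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  u <- cos(theta) * X + sin(theta) * Y
  v <- -sin(theta) * X + cos(theta) * Y
  (u / rx)^2 + (v / ry)^2 <= 1
}

# pixels within width/2 of the segment (cy,cx) +- (len/2)*direction
strokeMask <- function(h, w, cy, cx, len, width, theta) {
  Y <- matrix(seq_len(h), h, w) - cy
  X <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  u <- cos(theta) * X + sin(theta) * Y          # along the stroke
  v <- -sin(theta) * X + cos(theta) * Y         # across
  tcl <- pmin(pmax(u, -len / 2), len / 2)
  (u - tcl)^2 + v^2 <= (width / 2)^2
}

#' Generate a synthetic ILD phantom
#'
#' Dark background (0.05), two elliptical lung fields (0.35), and lesions
#' drawn strictly inside the lung fields according to the category:
#' micronodules are small bright disks (0.85), consolidation large dense
#' blobs (0.8), ground glass a +0.2 intensity lift over a smooth region,
#' fibrosis a network of short thick bright strokes (0.75) in the
#' subpleural band, and emphysema dark holes (0.15). Additive Gaussian
#' noise and optional horizontal motion blur are applied last ([corrupt()]).
#' Disk/blob lesions are placed by rejection sampling without overlap; an
#' unplaceable budget aborts after 1000 rejections.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with `image` ([RasterImage-class]), `lesionMask` and
#'   `lungMask` ([BinaryMask-class]) and the echoed `spec`.
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  h <- spec@height; w <- spec@width
  rho <- lungRho2(h, w)
  lung <- rho[[1]] <= 1 | rho[[2]] <= 1
  inner <- lungRho2(h, w, shrink = 3)
  innerM <- inner[[1]] <= 1 | inner[[2]] <= 1   # 3-px safety margin
  img <- matrix(BG_INTENSITY, h, w)
  img[lung] <- LUNG_INTENSITY
  lesion <- matrix(FALSE, h, w)

  withLocalSeed(spec@seed, {
    tries <- 0L
    placeDisks <- function(n, rfun, maskfun) {
      placed <- matrix(FALSE, h, w)
      cand <- which(innerM)
      for (i in seq_len(n)) {
        repeat {
          tries <<- tries + 1L
          if (tries > 1000L)
            stop("phantom generation failed: lesion budget not placeable ",
                 "without overlap after 1000 tries")
          ctr <- cand[sample.int(length(cand), 1L)]
          cy <- (ctr - 1L) %% h + 1L
          cx <- (ctr - 1L) %/% h + 1L
          m <- maskfun(cy, cx, rfun())
          if (!any(m & !innerM) && !any(m & placed) && sum(m) > 0) {
            placed <- placed | m
            break
          }
        }
      }
      placed
    }
    ctg <- spec@category
    n <- spec@nLesions; s <- spec@lesionSize
    if (ctg == "micronodules" && n > 0) {
      lesion <- placeDisks(n, function() max(3, s + stats::runif(1, -1.5, 1.5)),
                           function(cy, cx, r) diskMask(h, w, cy, cx, r))
      img[lesion] <- 0.85
    } else if (ctg == "consolidation" && n > 0) {
      lesion <- placeDisks(n, function() s * stats::runif(1, 0.8, 1.2),
        function(cy, cx, r) ellipseMask(h, w, cy, cx, r,
                                        r * stats::runif(1, 0.7, 1.0),
                                        stats::runif(1, 0, pi)))
      img[lesion] <- 0.8
    } else if (ctg == "emphysema" && n > 0) {
      lesion <- placeDisks(n, function() s * stats::runif(1, 0.8, 1.2),
                           function(cy, cx, r) diskMask(h, w, cy, cx, r))
      img[lesion] <- 0.15
    } else if (ctg == "ground_glass" && n > 0) {
      lesion <- placeDisks(n, function() s * stats::runif(1, 0.9, 1.2),
        function(cy, cx, r) ellipseMask(h, w, cy, cx, r * stats::runif(1, 0.7, 1.0),
                                        r, stats::runif(1, 0, pi)))
      img[lesion] <- img[lesion] + 0.2
    } else if (ctg == "fibrosis" && n > 0) {
      # subpleural band: normalized elliptical radius in [0.45, 0.9]
      band <- ((rho[[1]] >= 0.45^2 & rho[[1]] <= 0.9^2) |
               (rho[[2]] >= 0.45^2 & rho[[2]] <= 0.9^2)) & innerM
      cand <- which(band)
      for (i in seq_len(n)) {
        repeat {
          tries <- tries + 1L
          if (tries > 1000L)
            stop("phantom generation failed: lesion budget not placeable ",
                 "without overlap after 1000 tries")
          ctr <- cand[sample.int(length(cand), 1L)]
          cy <- (ctr - 1L) %% h + 1L
          cx <- (ctr - 1L) %/% h + 1L
          m <- strokeMask(h, w, cy, cx, len = 4 * s,
                          width = s, theta = stats::runif(1, 0, pi))
          if (!any(m & !innerM) && sum(m) > 0) {  # strokes may overlap
            lesion <- lesion | m
            break
          }
        }
      }
      img[lesion] <- 0.75
    }
    img <- corruptMatrix(img, spec@noiseSigma, spec@blurLen)
  })
  list(image = grayImage(img), lesionMask = BinaryMask(lesion),
       lungMask = BinaryMask(lung), spec = spec)
}

corruptMatrix <- function(m, noiseSigma, blurLen) {
  if (blurLen > 1) {
    # horizontal box kernel (right-heavy for even
    # lengths), reflected at the borders; centered for odd lengths
    n <- ncol(m)
    r0 <- (blurLen - 1L) %/% 2L
    r1 <- blurLen - 1L - r0
    r <- max(r0, r1)
    mp <- m[, reflectIdx(n, r), drop = FALSE]  # col t+r = position t
    out <- matrix(0, nrow(m), n)
    for (o in seq.int(-r0, r1))
      out <- out + mp[, seq_len(n) + o + r, drop = FALSE]
    m <- out / blurLen
  }
  if (noiseSigma > 0)
    m <- m + matrix(stats::rnorm(length(m), 0, noiseSigma), nrow(m))
  clip01(m)
}

#' Corrupt an image with motion blur and noise
#'
#' Horizontal box-kernel blur of length `blurLen` (emulating patient-motion
#' artifacts) followed by additive Gaussian noise, clipped to `[0, 1]`.
#' `noiseSigma = 0, blurLen = 0` is the identity.
#'
#' @param image a [RasterImage-class].
#' @param noiseSigma Gaussian noise sd (>= 0).
#' @param blurLen box kernel length in pixels (>= 0; 0/1 = no blur).
#' @param seed integer seed for the noise draw.
#' @return the corrupted [RasterImage-class].
#' @export
corrupt <- function(image, noiseSigma = 0, blurLen = 0L, seed = 0L) {
  stopifnot(is(image, "RasterImage"))
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  if (blurLen < 0) stop("blurLen must be >= 0")
  d <- imgData(image)
  out <- withLocalSeed(seed, {
    for (ch in seq_len(dim(d)[3]))
      d[, , ch] <- corruptMatrix(d[, , ch], noiseSigma, blurLen)
    d
  })
  RasterImage(out, colorspace(image))
}

#' Split-cluster phantom
#'
#' The multi-cluster-belonging scenario: one multifocal lesion with two
#' disjoint components of different density — a dim component (0.50, left
#' lung) whose intensity sits between the lung parenchyma (0.35) and the
#' bright component (0.90, right lung). Hard clustering attaches the dim
#' component to the lung cluster (or gives it a cluster of its own) while
#' the bright component earns the top cluster, so no single cluster
#' contains the whole object: a single-best-cluster segmentation recovers
#' only the bright component, whereas fusing the two object-bearing
#' clusters recovers the union. Run the pipeline with `k = 4` on these
#' phantoms (background, lung and the two lesion densities). The components
#' are kept in different lung fields so their wavelet supports do not
#' interact.
#'
#' @param seed integer seed.
#' @param height,width image size; default 240 x 320.
#' @param noiseSigma additive noise sd; default 0.02.
#' @return list as in [generatePhantom()].
#' @export
splitClusterPhantom <- function(seed = 0L, height = 240L, width = 320L,
                                noiseSigma = 0.02) {
  h <- as.integer(height); w <- as.integer(width)
  rho <- lungRho2(h, w)
  lung <- rho[[1]] <= 1 | rho[[2]] <= 1
  img <- matrix(BG_INTENSITY, h, w)
  img[lung] <- LUNG_INTENSITY
  parts <- withLocalSeed(seed, {
    mk <- function(fx) {
      cy <- 0.5 * h + stats::runif(1, -0.08, 0.08) * h
      cx <- fx * w + stats::runif(1, -0.015, 0.015) * w
      ellipseMask(h, w, cy, cx, ry = 0.12 * h, rx = 0.07 * w,
                  theta = stats::runif(1, -0.3, 0.3))
    }
    list(dim = mk(0.30), bright = mk(0.70))
  })
  img[parts$dim] <- 0.50
  img[parts$bright] <- 0.90
  img <- withLocalSeed(seed + 1L, corruptMatrix(img, noiseSigma, 0L))
  list(image = grayImage(img),
       lesionMask = BinaryMask(parts$dim | parts$bright),
       lungMask = BinaryMask(lung),
       spec = phantomSpec("consolidation", seed = seed, height = h, width = w,
                          nLesions = 2L, lesionSize = 0.12 * h,
                          noiseSigma = noiseSigma))
}
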