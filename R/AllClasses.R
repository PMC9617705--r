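#' @useDynLib SPFKMC, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' RasterImage: a 2-D pixel grid
#'
#' The carrier of every image stage of the pipeline. Pixel values are stored
#' as a `height x width x channels` numeric array in `[0, 1]` (except in Lab
#' space, where L spans `[0, 100]` and a/b are signed), row-major with
#' 0-based pixel-center sampling conventions for geometric operations.
#'
#' @slot data numeric array, `height x width x channels`, channels 1 or 3.
#' @slot colorspace one of `"gray"`, `"sRGB"`, `"Lab"`.
#' @export
setClass("RasterImage",
  representation(data = "array", colorspace = "character"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L) return("data must be a 3-D array (h x w x c)")
    if (d[1] < 8L || d[2] < 8L) return("image must be at least 8 x 8")
    if (!d[3] %in% c(1L, 3L)) return("channels must be 1 or 3")
    if (!all(is.finite(object@data))) return("pixel values must be finite")
    if (!object@colorspace %in% c("gray", "sRGB", "Lab"))
      return("colorspace must be gray, sRGB or Lab")
    if (object@colorspace %in% c("gray", "sRGB")) {
      rng <- range(object@data)
      if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
        return("gray/sRGB pixel values must lie in [0, 1]")
    }
    if (object@colorspace != "gray" && d[3] != 3L)
      return("sRGB/Lab images must have 3 channels")
    TRUE
  })

#' Construct a RasterImage
#'
#' @param data a numeric matrix (single channel) or `h x w x c` array.
#' @param colorspace colorspace tag; defaults to `"gray"` for one channel and
#'   `"sRGB"` for three.
#' @return a [RasterImage-class] object.
#' @examples
#' img <- RasterImage(matrix(runif(64), 8, 8))
#' dim(img)
#' @export
RasterImage <- function(data, colorspace = NULL) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (is.null(colorspace)) colorspace <- if (dim(data)[3] == 1L) "gray" else "sRGB"
  new("RasterImage", data = data, colorspace = colorspace)
}

#' LabelMap: integer region assignment per pixel
#'
#' Watershed superpixels and cluster maps. Labels are contiguous in
#' `1..nRegions` and every label occurs at least once.
#'
#' @slot labels integer matrix of region ids.
#' @slot nRegions number of regions.
#' @export
setClass("LabelMap",
  representation(labels = "matrix", nRegions = "integer"),
  validity = function(object) {
    l <- object@labels
    if (!is.numeric(l)) return("labels must be numeric")
    n <- object@nRegions
    if (n < 1L) return("nRegions must be >= 1")
    if (min(l) < 1L || max(l) > n) return("labels must lie in [1, nRegions]")
    if (length(unique(as.integer(l))) != n)
      return("every label in 1..nRegions must occur")
    TRUE
  })

#' @rdname LabelMap-class
#' @param labels integer matrix of region ids (1-based, contiguous).
#' @export
LabelMap <- function(labels) {
  storage.mode(labels) <- "integer"
  new("LabelMap", labels = labels, nRegions = max(labels))
}

#' BinaryMask: boolean foreground mask
#'
#' @slot data logical matrix; `TRUE` marks foreground.
#' @export
setClass("BinaryMask",
  representation(data = "matrix"),
  validity = function(object) {
    if (!is.logical(object@data)) return("mask data must be logical")
    if (anyNA(object@data)) return("mask must not contain NA")
    TRUE
  })

#' @rdname BinaryMask-class
#' @param data logical (or coercible 0/1 numeric) matrix.
#' @export
BinaryMask <- function(data) {
  if (!is.logical(data)) {
    stopifnot(all(data %in% c(0, 1)))
    d <- dim(data)
    data <- matrix(as.logical(data), d[1], d[2])
  }
  new("BinaryMask", data = data)
}

#' StructuringElement: morphological neighborhood
#'
#' Disk or square structuring element of integer radius r (side `2r + 1`),
#' symmetric about and containing the origin.
#'
#' @slot shape `"disk"` or `"square"`.
#' @slot radius integer radius in pixels, >= 1.
#' @export
setClass("StructuringElement",
  representation(shape = "character", radius = "integer"),
  validity = function(object) {
    if (!object@shape %in% c("disk", "square")) return("shape must be disk or square")
    if (object@radius < 1L) return("radius must be >= 1")
    TRUE
  })

#' @rdname StructuringElement-class
#' @param shape `"disk"` or `"square"`.
#' @param radius integer radius in pixels.
#' @export
structuringElement <- function(shape = c("disk", "square"), radius = 1L) {
  shape <- match.arg(shape)
  new("StructuringElement", shape = shape, radius = as.integer(radius))
}

#' ClusterSet: hard partition from K-means
#'
#' @slot k number of clusters.
#' @slot labels integer vector of cluster assignments (values in `1..k`).
#' @slot dims image dimensions `(h, w)` when the points are pixels, else
#'   `integer(0)`.
#' @slot centers `k x d` matrix of cluster centers.
#' @slot objective within-cluster sum of squared distances J.
#' @export
setClass("ClusterSet",
  representation(k = "integer", labels = "integer", dims = "integer",
                 centers = "matrix", objective = "numeric"),
  validity = function(object) {
    if (object@k < 1L) return("k must be >= 1")
    if (min(object@labels) < 1L || max(object@labels) > object@k)
      return("labels must lie in [1, k]")
    if (length(unique(object@labels)) != object@k)
      return("every cluster 1..k must be non-empty")
    if (nrow(object@centers) != object@k) return("centers must have k rows")
    if (object@objective < 0) return("objective must be >= 0")
    if (length(object@dims) == 2L &&
        prod(object@dims) != length(object@labels))
      return("dims inconsistent with number of points")
    TRUE
  })

#' MembershipMatrix: soft partition from fuzzy C-means
#'
#' @slot u `n x c` membership matrix; rows sum to 1.
#' @slot m fuzzifier (> 1).
#' @slot centers `c x d` matrix of weighted centers.
#' @slot dims image dimensions `(h, w)` or `integer(0)`.
#' @export
setClass("MembershipMatrix",
  representation(u = "matrix", m = "numeric", centers = "matrix",
                 dims = "integer"),
  validity = function(object) {
    if (object@m <= 1) return("fuzzifier m must be > 1")
    if (any(object@u < -1e-9) || any(object@u > 1 + 1e-9))
      return("memberships must lie in [0, 1]")
    if (max(abs(rowSums(object@u) - 1)) > 1e-9)
      return("membership rows must sum to 1")
    TRUE
  })

#' WaveletPyramid: multilevel 2-D discrete wavelet decomposition
#'
#' One approximation band at the coarsest level plus three oriented detail
#' bands (horizontal, vertical, diagonal) per level. `sizes[[j]]` records the
#' dimensions of the input to decomposition step `j`, which the inverse
#' transform needs to crop reconstructions of odd-sized inputs.
#'
#' @slot wavelet filter name, `"db4"` or `"haar"`.
#' @slot levels number of decomposition levels.
#' @slot approx coarsest approximation band (matrix).
#' @slot details list of length `levels`; element `j` (finest first) is a
#'   list with matrices `h`, `v`, `d`.
#' @slot sizes list of `c(h, w)` input sizes per level.
#' @export
setClass("WaveletPyramid",
  representation(wavelet = "character", levels = "integer",
                 approx = "matrix", details = "list", sizes = "list"),
  validity = function(object) {
    if (object@levels < 1L) return("levels must be >= 1")
    if (length(object@details) != object@levels)
      return("details must have one entry per level")
    for (dl in object@details)
      if (!all(c("h", "v", "d") %in% names(dl)))
        return("each detail level needs bands h, v, d")
    TRUE
  })

#' ConfusionCounts: pixelwise 2x2 tally
#'
#' @slot tp,tn,fp,fn nonnegative pixel counts.
#' @export
setClass("ConfusionCounts",
  representation(tp = "numeric", tn = "numeric", fp = "numeric", fn = "numeric"),
  validity = function(object) {
    v <- c(object@tp, object@tn, object@fp, object@fn)
    if (any(v < 0) || any(v != round(v))) return("counts must be nonnegative integers")
    TRUE
  })

#' PhantomSpec: parameters of a synthetic ILD slice
#'
#' Describes one synthetic 2-D lung-CT look-alike: the ILD pattern category,
#' lesion geometry, corruption level and random seed. Identical specs produce
#' bitwise-identical phantoms.
#'
#' @slot height,width image size in pixels (default 240 x 320).
#' @slot category one of `healthy`, `consolidation`, `emphysema`, `fibrosis`,
#'   `ground_glass`, `micronodules`.
#' @slot nLesions lesion count (0 for healthy).
#' @slot lesionSize mean lesion radius/scale in pixels.
#' @slot noiseSigma additive Gaussian noise standard deviation.
#' @slot blurLen horizontal motion-blur kernel length (0 = off).
#' @slot seed integer random seed.
#' @export
setClass("PhantomSpec",
  representation(height = "integer", width = "integer", category = "character",
                 nLesions = "integer", lesionSize = "numeric",
                 noiseSigma = "numeric", blurLen = "integer", seed = "integer"),
  validity = function(object) {
    cats <- c("healthy", "consolidation", "emphysema", "fibrosis",
              "ground_glass", "micronodules")
    if (!object@category %in% cats)
      return(paste("category must be one of:", paste(cats, collapse = ", ")))
    if (object@category == "healthy" && object@nLesions != 0L)
      return("healthy phantoms must have nLesions == 0")
    if (object@height < 8L || object@width < 8L) return("phantom must be >= 8 x 8")
    if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
    if (object@blurLen < 0L) return("blurLen must be >= 0")
    TRUE
  })

#' PipelineConfig: all tunable parameters of the segmentation pipeline
#'
#' Serializes losslessly to/from JSON via [configToJSON()] /
#' [configFromJSON()].
#'
#' @slot resizeH,resizeW working geometry (default 240 x 320).
#' @slot gaussianSigma pre-smoothing sigma in pixels.
#' @slot mmgrR1,mmgrR2 structuring-element radius range of the multi-scale
#'   gradient reconstruction.
#' @slot seShape SE shape for gradient/MMGR (`disk` or `square`).
#' @slot k number of K-means clusters.
#' @slot seed,maxIter,tol clustering controls.
#' @slot clusterMode `"manual"` or `"auto"` cluster selection.
#' @slot clusterIndices selected cluster indices (manual mode; 1 or 2 of them).
#' @slot waveletName,waveletLevels wavelet fusion controls.
#' @slot fusionRule `"max_abs"` (pixel-level maxima) or `"mean"`.
#' @slot binarizeThreshold mask threshold as a fraction of the fused maximum.
#' @slot morphRadius disk radius of the post-fusion opening.
#' @export
setClass("PipelineConfig",
  representation(resizeH = "integer", resizeW = "integer",
                 gaussianSigma = "numeric", mmgrR1 = "integer",
                 mmgrR2 = "integer", seShape = "character", k = "integer",
                 seed = "integer", maxIter = "integer", tol = "numeric",
                 clusterMode = "character", clusterIndices = "integer",
                 waveletName = "character", waveletLevels = "integer",
                 fusionRule = "character", binarizeThreshold = "numeric",
                 morphRadius = "integer"),
  validity = function(object) {
    if (object@resizeH < 8L || object@resizeW < 8L) return("resize dims must be >= 8")
    if (object@gaussianSigma < 0) return("gaussianSigma must be >= 0")
    if (object@mmgrR1 < 1L || object@mmgrR1 > object@mmgrR2)
      return("need 1 <= mmgrR1 <= mmgrR2")
    if (!object@seShape %in% c("disk", "square")) return("bad seShape")
    if (object@k < 1L) return("k must be >= 1")
    if (!object@clusterMode %in% c("manual", "auto")) return("bad clusterMode")
    if (object@clusterMode == "manual" &&
        !length(object@clusterIndices) %in% c(1L, 2L))
      return("manual selection needs 1 or 2 cluster indices")
    if (!object@fusionRule %in% c("max_abs", "mean")) return("bad fusionRule")
    if (object@binarizeThreshold <= 0 || object@binarizeThreshold >= 1)
      return("binarizeThreshold must lie in (0, 1)")
    if (object@morphRadius < 0L) return("morphRadius must be >= 0")
    TRUE
  })

#' @rdname PipelineConfig-class
#' @param resizeH,resizeW,gaussianSigma,mmgrR1,mmgrR2,seShape,k,seed,maxIter,tol
#'   see slot documentation.
#' @param clusterMode,clusterIndices,waveletName,waveletLevels,fusionRule
#'   see slot documentation.
#' @param binarizeThreshold,morphRadius see slot documentation.
#' @return a validated [PipelineConfig-class].
#' @examples
#' cfg <- pipelineConfig(k = 3L, clusterMode = "auto")
#' @export
pipelineConfig <- function(resizeH = 240L, resizeW = 320L, gaussianSigma = 1.0,
                           mmgrR1 = 1L, mmgrR2 = 2L, seShape = "disk",
                           k = 3L, seed = 0L, maxIter = 100L, tol = 1e-4,
                           clusterMode = "auto", clusterIndices = integer(0),
                           waveletName = "db4", waveletLevels = 2L,
                           fusionRule = "max_abs", binarizeThreshold = 0.5,
                           morphRadius = 1L) {
  new("PipelineConfig", resizeH = as.integer(resizeH),
      resizeW = as.integer(resizeW), gaussianSigma = gaussianSigma,
      mmgrR1 = as.integer(mmgrR1), mmgrR2 = as.integer(mmgrR2),
      seShape = seShape, k = as.integer(k), seed = as.integer(seed),
      maxIter = as.integer(maxIter), tol = tol, clusterMode = clusterMode,
      clusterIndices = as.integer(clusterIndices), waveletName = waveletName,
      waveletLevels = as.integer(waveletLevels), fusionRule = fusionRule,
      binarizeThreshold = binarizeThreshold,
      morphRadius = as.integer(morphRadius))
}
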