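# Accessor generics and show methods. Slots are never touched directly by
# user code; these accessors are the supported surface.

#' Pixel data of an image-like object
#' @param x a RasterImage, BinaryMask or LabelMap.
#' @return the underlying array/matrix (copy).
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))
#' @rdname imgData
#' @export
setMethod("imgData", "RasterImage", function(x) x@data)

#' @describeIn BinaryMask-class logical matrix of the mask.
#' @param x a BinaryMask.
#' @export
setGeneric("maskData", function(x) standardGeneric("maskData"))
#' @rdname BinaryMask-class
#' @export
setMethod("maskData", "BinaryMask", function(x) x@data)

#' @describeIn LabelMap-class integer matrix of region labels.
#' @param x a LabelMap.
#' @export
setGeneric("labelData", function(x) standardGeneric("labelData"))
#' @rdname LabelMap-class
#' @export
setMethod("labelData", "LabelMap", function(x) x@labels)

#' @describeIn LabelMap-class number of regions.
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))
#' @rdname LabelMap-class
#' @export
setMethod("nRegions", "LabelMap", function(x) x@nRegions)

#' Colorspace tag of a RasterImage
#' @param x a RasterImage.
#' @return `"gray"`, `"sRGB"` or `"Lab"`.
#' @export
setGeneric("colorspace", function(x) standardGeneric("colorspace"))
#' @rdname colorspace
#' @export
setMethod("colorspace", "RasterImage", function(x) x@colorspace)

#' Number of channels of a RasterImage
#' @param x a RasterImage.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname nChannels
#' @export
setMethod("nChannels", "RasterImage", function(x) dim(x@data)[3])

#' @export
setMethod("dim", "RasterImage", function(x) dim(x@data)[1:2])
#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@data))
#' @export
setMethod("dim", "LabelMap", function(x) dim(x@labels))

#' Cluster centers
#' @param x a ClusterSet or MembershipMatrix.
#' @return numeric matrix, one row per cluster.
#' @export
setGeneric("clusterCenters", function(x) standardGeneric("clusterCenters"))
#' @rdname clusterCenters
#' @export
setMethod("clusterCenters", "ClusterSet", function(x) x@centers)
#' @rdname clusterCenters
#' @export
setMethod("clusterCenters", "MembershipMatrix", function(x) x@centers)

#' @describeIn ClusterSet-class integer vector of hard assignments.
#' @param x a ClusterSet.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname ClusterSet-class
#' @export
setMethod("clusterLabels", "ClusterSet", function(x) x@labels)

#' @describeIn ClusterSet-class number of clusters.
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))
#' @rdname ClusterSet-class
#' @export
setMethod("nClusters", "ClusterSet", function(x) x@k)
#' @rdname MembershipMatrix-class
#' @param x a MembershipMatrix.
#' @export
setMethod("nClusters", "MembershipMatrix", function(x) ncol(x@u))

#' @describeIn ClusterSet-class within-cluster sum of squared distances J.
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))
#' @rdname ClusterSet-class
#' @export
setMethod("objectiveValue", "ClusterSet", function(x) x@objective)

#' @describeIn MembershipMatrix-class `n x c` membership matrix.
#' @export
setGeneric("memberships", function(x) standardGeneric("memberships"))
#' @rdname MembershipMatrix-class
#' @export
setMethod("memberships", "MembershipMatrix", function(x) x@u)

#' Confusion tallies as a named vector
#' @param x a ConfusionCounts.
#' @return named numeric vector with elements `tp`, `tn`, `fp`, `fn`.
#' @export
setGeneric("confusionVector", function(x) standardGeneric("confusionVector"))
#' @rdname confusionVector
#' @export
setMethod("confusionVector", "ConfusionCounts",
          function(x) c(tp = x@tp, tn = x@tn, fp = x@fp, fn = x@fn))

setMethod("show", "RasterImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("RasterImage %d x %d, %d channel(s), %s, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], object@colorspace,
              min(object@data), max(object@data)))
})

setMethod("show", "LabelMap", function(object) {
  cat(sprintf("LabelMap %d x %d with %d regions\n",
              nrow(object@labels), ncol(object@labels), object@nRegions))
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask %d x %d, %d foreground pixel(s) (%.1f%%)\n",
              nrow(object@data), ncol(object@data), sum(object@data),
              100 * mean(object@data)))
})

setMethod("show", "ClusterSet", function(object) {
  cat(sprintf("ClusterSet: k = %d, n = %d points, J = %.6g\n",
              object@k, length(object@labels), object@objective))
  sz <- tabulate(object@labels, object@k)
  cat("  cluster sizes:", paste(sz, collapse = ", "), "\n")
})

setMethod("show", "MembershipMatrix", function(object) {
  cat(sprintf("MembershipMatrix: n = %d, c = %d, m = %.2f\n",
              nrow(object@u), ncol(object@u), object@m))
})

setMethod("show", "WaveletPyramid", function(object) {
  cat(sprintf("WaveletPyramid: %s, %d level(s), approx %d x %d\n",
              object@wavelet, object@levels,
              nrow(object@approx), ncol(object@approx)))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d TN=%d FP=%d FN=%d (total %d)\n",
              object@tp, object@tn, object@fp, object@fn,
              object@tp + object@tn + object@fp + object@fn))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %s, %d x %d, %d lesion(s) of scale %.3g, noise %.3g, blur %d, seed %d\n",
    object@category, object@height, object@width, object@nLesions,
    object@lesionSize, object@noiseSigma, object@blurLen, object@seed))
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig:\n")
  cat(sprintf("  resize %d x %d | sigma %.3g | MMGR %s r=%d..%d\n",
              object@resizeH, object@resizeW, object@gaussianSigma,
              object@seShape, object@mmgrR1, object@mmgrR2))
  idx <- if (length(object@clusterIndices))
    paste(object@clusterIndices, collapse = ",") else "-"
  cat(sprintf("  k=%d seed=%d | clusters %s [%s] | %s x%d, rule %s, thr %.2f, open r=%d\n",
              object@k, object@seed, object@clusterMode, idx,
              object@waveletName, object@waveletLevels, object@fusionRule,
              object@binarizeThreshold, object@morphRadius))
})
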