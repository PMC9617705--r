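# Lab conversion, Lloyd K-means, the fuzzy C-means baseline, per-cluster
# image extraction and cluster selection.

#' Convert sRGB (or gray) to CIE Lab
#'
#' Conversion under the D65 white point via the sRGB -> XYZ -> Lab chain
#' (delegated to [grDevices::convertColor()]). Gray input is replicated to
#' three channels first, so its a/b channels come out (numerically) zero.
#'
#' @param img a [RasterImage-class] in `sRGB` or `gray`.
#' @return a 3-channel [RasterImage-class] tagged `Lab`; L in `[0, 100]`.
#' @export
rgbToLab <- function(img) {
  stopifnot(is(img, "RasterImage"))
  if (colorspace(img) == "Lab") {
    warning("image is already in Lab space; returning unchanged")
    return(img)
  }
  d <- imgData(img)
  h <- dim(d)[1]; w <- dim(d)[2]
  rgb <- if (dim(d)[3] == 1L) matrix(as.vector(d[, , 1]), h * w, 3L)
         else cbind(as.vector(d[, , 1]), as.vector(d[, , 2]), as.vector(d[, , 3]))
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  new("RasterImage", data = array(lab, c(h, w, 3L)), colorspace = "Lab")
}

# relabel to contiguous 1..k' dropping empty clusters; build a ClusterSet
makeClusterSet <- function(labels, centers, points, dims = integer(0)) {
  used <- sort(unique(labels))
  map <- integer(max(labels)); map[used] <- seq_along(used)
  labels <- map[labels]
  centers <- centers[used, , drop = FALSE]
  obj <- sum((points - centers[labels, , drop = FALSE])^2)
  new("ClusterSet", k = length(used), labels = as.integer(labels),
      dims = as.integer(dims), centers = centers, objective = obj)
}

#' K-means clustering (Lloyd iterations)
#'
#' Assigns each point to its nearest center under squared Euclidean
#' distance (ties broken toward the lower cluster index), recomputes centers
#' as member means, and stops when the maximum center displacement falls
#' below `tol` or after `maxIter` sweeps. Initial centers are `k` distinct
#' points drawn uniformly at random under `seed`; a cluster that empties is
#' re-seeded in-run at the point farthest from its assigned center, so all
#' `k` clusters are non-empty on return. The objective J (within-cluster sum
#' of squared distances) is non-increasing across iterations.
#'
#' Because Lloyd iterations only find a local optimum of J, the algorithm is
#' restarted `nstart` times (seeds `seed, seed + 1, ...`) and the solution
#' with the smallest J is kept; the whole procedure is deterministic for a
#' fixed `seed`.
#'
#' @param points numeric `n x d` matrix of feature vectors.
#' @param k number of clusters (`1 <= k <= n`).
#' @param seed integer seed for initialization; default 0.
#' @param maxIter,tol stopping controls; defaults 100 and 1e-4.
#' @param dims optional `(h, w)` recording that the points are the pixels of
#'   an image of that size.
#' @param nstart number of random restarts; default 10.
#' @return a [ClusterSet-class].
#' @export
kmeansCluster <- function(points, k, seed = 0L, maxIter = 100L, tol = 1e-4,
                          dims = integer(0), nstart = 10L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k > n) stop("k must not exceed the number of points")
  if (k < 1L) stop("k must be >= 1")
  # Lloyd on the distinct rows weighted by multiplicity: exactly equivalent
  # to clustering the raw points (flattened superpixel images have few
  # distinct values, making restarts cheap)
  g <- rowGroups(points)
  if (nrow(g$uniq) < k)
    stop("fewer than k distinct points; cannot place k distinct centers")
  best <- NULL
  for (s in seq_len(max(1L, nstart)) - 1L) {
    fit <- kmeansOnce(g$uniq, g$counts, k, seed = seed + s,
                      maxIter = maxIter, tol = tol)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  makeClusterSet(best$labels[g$id], best$centers, points, dims)
}

# canonical (sorted) distinct rows, multiplicities, and per-row group index
rowGroups <- function(points) {
  df <- unname(as.data.frame(points))
  o <- do.call(order, df)
  sp <- points[o, , drop = FALSE]
  if (nrow(sp) > 1) {
    new <- rowSums(abs(sp[-1, , drop = FALSE] -
                       sp[-nrow(sp), , drop = FALSE])) > 0
    gid_sorted <- cumsum(c(1L, as.integer(new)))
  } else gid_sorted <- 1L
  id <- integer(nrow(points))
  id[o] <- gid_sorted
  first <- o[!duplicated(gid_sorted)]
  list(uniq = points[first, , drop = FALSE],
       counts = as.numeric(tabulate(id)), id = id)
}

# one weighted Lloyd run over distinct rows
kmeansOnce <- function(U, w, k, seed, maxIter, tol) {
  m <- nrow(U)
  centers <- withLocalSeed(seed, U[sample.int(m, k), , drop = FALSE])
  usq <- rowSums(U^2)
  assign_step <- function(centers) {
    d2 <- outer(usq, rowSums(centers^2), "+") - 2 * U %*% t(centers)
    list(lab = max.col(-d2, ties.method = "first"), d2 = d2)
  }
  a <- assign_step(centers)
  for (it in seq_len(maxIter)) {
    # deterministic in-run recovery of empty clusters: re-seed at the point
    # farthest from its assigned center
    repeat {
      empty <- setdiff(seq_len(k), unique(a$lab))
      if (!length(empty)) break
      resid <- a$d2[cbind(seq_len(m), a$lab)]
      centers[empty[1], ] <- U[which.max(resid), ]
      a <- assign_step(centers)
    }
    wsum <- as.vector(rowsum(w, a$lab))
    newc <- rowsum(U * w, a$lab) / wsum
    shift <- sqrt(max(rowSums((newc - centers)^2)))
    centers <- newc
    a <- assign_step(centers)
    if (shift < tol) break
  }
  obj <- sum(w * pmax(a$d2[cbind(seq_len(m), a$lab)], 0))
  list(labels = a$lab, centers = centers, objective = obj)
}

#' Fuzzy C-means clustering
#'
#' Standard alternating optimization: memberships from inverse squared
#' distances raised to `2 / (m - 1)`, centers as membership-weighted means.
#' A point coinciding exactly with a center receives membership 1 there and
#' 0 elsewhere (singularity rule). Rows of the membership matrix sum to 1 at
#' every iteration. Used as the soft-clustering baseline.
#'
#' @param points numeric `n x d` matrix.
#' @param c number of clusters (>= 1).
#' @param m fuzzifier (> 1); default 2.
#' @param seed,maxIter,tol as in [kmeansCluster()].
#' @param dims optional image dims, as in [kmeansCluster()].
#' @return a [MembershipMatrix-class] (centers included).
#' @export
fcmCluster <- function(points, c, m = 2, seed = 0L, maxIter = 100L,
                       tol = 1e-4, dims = integer(0)) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (c < 1L) stop("c must be >= 1")
  if (c > n) stop("c must not exceed the number of points")
  if (m <= 1) stop("fuzzifier m must be > 1")
  uniq <- points[!duplicated(points), , drop = FALSE]
  if (nrow(uniq) < c) stop("fewer than c distinct points")
  centers <- withLocalSeed(seed, uniq[sample.int(nrow(uniq), c), , drop = FALSE])
  ptsq <- rowSums(points^2)
  memb <- function(centers) {
    d2 <- outer(ptsq, rowSums(centers^2), "+") - 2 * points %*% t(centers)
    d2 <- pmax(d2, 0)
    zero <- d2 < 1e-24
    pw <- d2^(-1 / (m - 1))
    u <- pw / rowSums(pw)
    hit <- rowSums(zero) > 0
    if (any(hit)) {
      u[hit, ] <- 0
      first0 <- max.col(-d2[hit, , drop = FALSE], ties.method = "first")
      u[cbind(which(hit), first0)] <- 1
    }
    u
  }
  u <- memb(centers)
  for (it in seq_len(maxIter)) {
    um <- u^m
    newc <- t(um) %*% points / colSums(um)
    shift <- sqrt(max(rowSums((newc - centers)^2)))
    centers <- newc
    u <- memb(centers)
    if (shift < tol) break
  }
  new("MembershipMatrix", u = u, m = m, centers = centers,
      dims = as.integer(dims))
}

#' Defuzzify a fuzzy partition
#'
#' Hard assignment by per-row argmax of the memberships, returned as a
#' [ClusterSet-class] (empty clusters dropped and labels made contiguous).
#'
#' @param mm a [MembershipMatrix-class].
#' @param points the `n x d` matrix the memberships were fitted on.
#' @return a [ClusterSet-class].
#' @export
defuzzify <- function(mm, points) {
  labels <- max.col(memberships(mm), ties.method = "first")
  makeClusterSet(labels, clusterCenters(mm), as.matrix(points), mm@dims)
}

#' Per-cluster images
#'
#' One single-channel image per cluster: the source luminance where the
#' pixel belongs to that cluster and 0 elsewhere. Supports are pairwise
#' disjoint and their union covers the nonzero support of the source.
#'
#' @param cs a [ClusterSet-class] whose points are the pixels of `source`.
#' @param source the [RasterImage-class] the clustering was computed from.
#' @return list of `k` single-channel [RasterImage-class] objects.
#' @export
clusterImages <- function(cs, source) {
  stopifnot(is(cs, "ClusterSet"), is(source, "RasterImage"))
  dm <- dim(source)
  if (length(cs@dims) != 2L || !all(cs@dims == dm))
    stop("cluster set does not cover the source image pixels")
  lum <- toLuminance(source)
  lab <- matrix(clusterLabels(cs), dm[1], dm[2])
  lapply(seq_len(nClusters(cs)), function(j) {
    m <- lum
    m[lab != j] <- 0
    grayImage(m)
  })
}

#' Select clusters for fusion
#'
#' Manual mode returns the named clusters (1 or 2 of them), mirroring the
#' semi-automatic user choice of the segmentation workflow. Auto mode ranks
#' cluster images by their count of nonzero pixels inside the ROI (default
#' ROI: union of the nonzero supports, i.e. the superpixel foreground) and
#' returns the top two.
#'
#' @param images list of cluster images from [clusterImages()].
#' @param mode `"manual"` or `"auto"`.
#' @param indices cluster indices for manual mode (length 1 or 2).
#' @param roi optional [BinaryMask-class] restricting the ranking.
#' @return the selected sublist of `images`, with the chosen indices in
#'   attribute `"indices"`.
#' @export
selectClusters <- function(images, mode = c("manual", "auto"),
                           indices = NULL, roi = NULL) {
  mode <- match.arg(mode)
  if (mode == "manual") {
    if (is.null(indices) || !length(indices) %in% c(1L, 2L))
      stop("manual selection requires 1 or 2 cluster indices")
    if (any(indices < 1L | indices > length(images)))
      stop("cluster index out of range (k = ", length(images), ")")
    out <- images[indices]
    attr(out, "indices") <- as.integer(indices)
    return(out)
  }
  supp <- lapply(images, function(im) imgData(im)[, , 1] != 0)
  roiM <- if (is.null(roi)) Reduce(`|`, supp) else maskData(roi)
  counts <- vapply(supp, function(s) sum(s & roiM), numeric(1))
  idx <- order(-counts)[seq_len(min(2L, length(images)))]
  out <- images[idx]
  attr(out, "indices") <- as.integer(idx)
  out
}

#' Pick lesion cluster(s) by intensity polarity
#'
#' Programmatic stand-in for the interactive cluster choice: ILD lesions are
#' either brighter than the lung parenchyma (consolidation, ground glass,
#' fibrosis, micronodules) or darker (emphysema), so the lesion cluster is
#' found by ranking cluster centers on their first feature (Lab L). When an
#' `roi` (typically the lung field) is supplied, clusters with fewer than
#' half their pixels inside it (e.g. the air background) are skipped.
#'
#' @param cs a pixel-level [ClusterSet-class].
#' @param polarity `"bright"` or `"dark"`.
#' @param roi optional [BinaryMask-class].
#' @param n number of clusters to return (1 or 2).
#' @return integer vector of cluster indices, best first.
#' @export
chooseLesionClusters <- function(cs, polarity = c("bright", "dark"),
                                 roi = NULL, n = 1L) {
  polarity <- match.arg(polarity)
  L <- clusterCenters(cs)[, 1]
  ord <- order(L, decreasing = (polarity == "bright"))
  if (!is.null(roi)) {
    stopifnot(length(cs@dims) == 2L)
    rv <- as.vector(maskData(roi))
    frac <- vapply(seq_len(nClusters(cs)), function(j)
      mean(rv[clusterLabels(cs) == j]), numeric(1))
    keep <- ord[frac[ord] >= 0.5]
    if (length(keep)) ord <- c(keep, setdiff(ord, keep))
  }
  ord[seq_len(min(n, length(ord)))]
}
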