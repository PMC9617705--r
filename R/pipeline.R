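# End-to-end orchestration of the hybrid segmentation flow and the
# plain-clustering baselines, plus JSON (de)serialization of the run
# configuration.

#' Run the hybrid superpixel + fused K-means segmentation
#'
#' Executes the full flow: resize to the working geometry, Gaussian
#' smoothing, morphological gradient, multi-scale gradient reconstruction,
#' watershed superpixels, region-mean flattening, Lab conversion, K-means
#' over the flattened pixels, cluster-image extraction and selection,
#' wavelet fusion, binarization, morphological opening, boundary extraction
#' and color overlay. Fully deterministic for a fixed config; every
#' intermediate stage is returned for inspection.
#'
#' @param image input [RasterImage-class] (any size; resized internally).
#' @param config a [PipelineConfig-class].
#' @param truth optional reference [BinaryMask-class] at the working
#'   geometry; when supplied a metrics row is appended to the result.
#' @param roi optional [BinaryMask-class]; restricts metric counting.
#' @param clusterSelector optional `function(cs)` returning 1 or 2 lesion
#'   cluster indices from the fitted [ClusterSet-class]; overrides
#'   `config@clusterMode` (the programmatic analogue of the interactive
#'   cluster choice).
#' @return list with `mask` ([BinaryMask-class]), `overlay`
#'   ([RasterImage-class]), `boundary`, `intermediates` (named list of every
#'   stage), `clusters` (the [ClusterSet-class]), `report` (data.frame or
#'   NULL) and the echoed `config`.
#' @export
runSPFKMC <- function(image, config = pipelineConfig(), truth = NULL,
                      roi = NULL, clusterSelector = NULL) {
  stopifnot(is(image, "RasterImage"), is(config, "PipelineConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  im <- stage("resize", resizeRaster(image, config@resizeH, config@resizeW))
  sm <- stage("gaussian_smooth", gaussianSmooth(im, config@gaussianSigma))
  lum <- stage("luminance", grayImage(toLuminance(sm)))
  se <- structuringElement(config@seShape, 1L)
  gr <- stage("morphological_gradient", morphGradient(lum, se))
  rg <- stage("mmgr", mmgr(gr, config@mmgrR1, config@mmgrR2, config@seShape))
  sp <- stage("watershed_superpixels", watershedSuperpixels(rg))
  flat <- stage("superpixel_mean_image", superpixelMeanImage(im, sp))
  lab <- stage("rgb_to_lab", rgbToLab(flat))
  feats <- apply(imgData(lab), 3L, as.vector)
  # flattened images carry few distinct values, so extra restarts are cheap
  # and make the J-optimal partition reliably found
  cs <- stage("kmeans", kmeansCluster(feats, config@k, seed = config@seed,
                                      maxIter = config@maxIter,
                                      tol = config@tol, dims = dim(flat),
                                      nstart = 30L))
  imgs <- stage("cluster_images", clusterImages(cs, flat))
  sel <- stage("select_clusters", {
    if (!is.null(clusterSelector)) {
      idx <- clusterSelector(cs)
      selectClusters(imgs, "manual", indices = idx)
    } else if (config@clusterMode == "manual") {
      selectClusters(imgs, "manual", indices = config@clusterIndices)
    } else {
      selectClusters(imgs, "auto")
    }
  })
  fus <- stage("fuse_cluster_images",
               fuseClusterImages(sel, wavelet = config@waveletName,
                                 levels = config@waveletLevels,
                                 rule = config@fusionRule,
                                 binarizeThreshold = config@binarizeThreshold))
  mask <- fus$mask
  if (config@morphRadius > 0L)
    mask <- stage("opening", openMask(mask,
      structuringElement("disk", config@morphRadius)))
  bnd <- stage("extract_boundary", extractBoundary(mask))
  ovl <- stage("apply_color_mask", applyColorMask(im, mask))
  report <- NULL
  if (!is.null(truth)) {
    if (!all(dim(truth) == dim(mask)))
      stop("truth mask must match the working geometry ",
           config@resizeH, " x ", config@resizeW)
    report <- metricsRow("spfkmc", mask, truth, roi)
  }
  list(mask = mask, overlay = ovl, boundary = bnd,
       intermediates = list(resized = im, smoothed = sm, luminance = lum,
                            gradient = gr, mmgr = rg, superpixels = sp,
                            flattened = flat, lab = lab,
                            cluster_images = imgs, selected = sel,
                            fused = fus$fused, raw_mask = fus$mask),
       clusters = cs, selectedIndices = attr(sel, "indices"),
       report = report, config = config)
}

#' Run a plain-clustering baseline (K-means or FCM)
#'
#' Same products as [runSPFKMC()] but skipping superpixel presegmentation
#' and wavelet fusion: pixels of the (resized, smoothed) image are
#' clustered directly in Lab space and the single best cluster image is
#' thresholded into the mask — the "without fusion" arm of the method
#' comparison.
#'
#' @inheritParams runSPFKMC
#' @param method `"kmeans"` or `"fcm"`.
#' @return list as in [runSPFKMC()] (no fusion intermediates).
#' @export
runBaseline <- function(image, method = c("kmeans", "fcm"),
                        config = pipelineConfig(), truth = NULL, roi = NULL,
                        clusterSelector = NULL) {
  method <- match.arg(method)
  stopifnot(is(image, "RasterImage"), is(config, "PipelineConfig"))
  im <- resizeRaster(image, config@resizeH, config@resizeW)
  sm <- gaussianSmooth(im, config@gaussianSigma)
  lab <- rgbToLab(sm)
  feats <- apply(imgData(lab), 3L, as.vector)
  cs <- if (method == "kmeans") {
    kmeansCluster(feats, config@k, seed = config@seed,
                  maxIter = config@maxIter, tol = config@tol, dims = dim(sm))
  } else {
    defuzzify(fcmCluster(feats, config@k, m = 2, seed = config@seed,
                         maxIter = config@maxIter, tol = config@tol,
                         dims = dim(sm)), feats)
  }
  imgs <- clusterImages(cs, sm)
  idx <- if (!is.null(clusterSelector)) clusterSelector(cs)[1]
         else if (config@clusterMode == "manual") config@clusterIndices[1]
         else attr(selectClusters(imgs, "auto"), "indices")[1]
  sel <- selectClusters(imgs, "manual", indices = idx)
  fus <- fuseClusterImages(sel, binarizeThreshold = config@binarizeThreshold)
  mask <- fus$mask
  if (config@morphRadius > 0L)
    mask <- openMask(mask, structuringElement("disk", config@morphRadius))
  bnd <- extractBoundary(mask)
  ovl <- applyColorMask(im, mask)
  report <- if (!is.null(truth)) metricsRow(method, mask, truth, roi) else NULL
  list(mask = mask, overlay = ovl, boundary = bnd,
       intermediates = list(resized = im, smoothed = sm, lab = lab,
                            cluster_images = imgs, selected = sel,
                            fused = fus$fused, raw_mask = fus$mask),
       clusters = cs, selectedIndices = idx, report = report, config = config)
}

#' Serialize / deserialize a PipelineConfig as JSON
#'
#' The round trip is lossless, so a run can be reproduced exactly from the
#' `config.json` echoed into its output directory.
#'
#' @param config a [PipelineConfig-class].
#' @return `configToJSON`: a JSON string; `configFromJSON`: a
#'   [PipelineConfig-class].
#' @export
configToJSON <- function(config) {
  stopifnot(is(config, "PipelineConfig"))
  sl <- slotNames("PipelineConfig")
  vals <- lapply(sl, function(s) slot(config, s))
  names(vals) <- sl
  as.character(jsonlite::toJSON(vals, auto_unbox = TRUE, digits = NA))
}

#' @rdname configToJSON
#' @param json JSON string or path to a JSON file.
#' @export
configFromJSON <- function(json) {
  vals <- jsonlite::fromJSON(json)
  defaults <- pipelineConfig()
  for (s in names(vals)) {
    v <- vals[[s]]
    if (is.integer(slot(defaults, s))) v <- as.integer(v)
    slot(defaults, s) <- v
  }
  validObject(defaults)
  defaults
}
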