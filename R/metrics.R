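# Confusion counting and the three segmentation metrics (accuracy, Jaccard,
# Dice), plus the multi-method comparison report.

#' Pixelwise confusion counts
#'
#' 2x2 tally of a predicted against a reference mask; foreground is `TRUE`.
#' The four counts always sum to the pixel count.
#'
#' @param pred,truth [BinaryMask-class] objects of equal size.
#' @return a [ConfusionCounts-class].
#' @export
confusionCounts <- function(pred, truth) {
  stopifnot(is(pred, "BinaryMask"), is(truth, "BinaryMask"))
  p <- maskData(pred); t <- maskData(truth)
  if (!all(dim(p) == dim(t))) stop("mask sizes differ")
  new("ConfusionCounts",
      tp = sum(p & t), tn = sum(!p & !t),
      fp = sum(p & !t), fn = sum(!p & t))
}

#' Segmentation accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param cc a [ConfusionCounts-class].
#' @return value in `[0, 1]`.
#' @export
segAccuracy <- function(cc) {
  stopifnot(is(cc, "ConfusionCounts"))
  tot <- cc@tp + cc@tn + cc@fp + cc@fn
  if (tot <= 0) stop("confusion counts are empty")
  (cc@tp + cc@tn) / tot
}

#' Jaccard similarity index
#'
#' `TP / (TP + FP + FN)` — intersection over union. Two empty masks agree
#' perfectly by convention (returns 1), which matters for lesion-free
#' phantoms.
#'
#' @inheritParams segAccuracy
#' @return value in `[0, 1]`.
#' @export
jaccardIndex <- function(cc) {
  stopifnot(is(cc, "ConfusionCounts"))
  den <- cc@tp + cc@fp + cc@fn
  if (den == 0) return(1.0)
  cc@tp / den
}

#' Dice similarity coefficient
#'
#' `2 TP / (2 TP + FP + FN)`; related to Jaccard by `DSC = 2 J / (1 + J)`
#' when both come from the same counts. Empty-vs-empty returns 1.
#'
#' @inheritParams segAccuracy
#' @return value in `[0, 1]`.
#' @export
diceCoefficient <- function(cc) {
  stopifnot(is(cc, "ConfusionCounts"))
  den <- 2 * cc@tp + cc@fp + cc@fn
  if (den == 0) return(1.0)
  2 * cc@tp / den
}

#' Dice from Jaccard
#'
#' The algebraic identity `DSC = 2 J / (1 + J)` linking the two overlap
#' measures computed from one confusion table.
#'
#' @param j Jaccard index value(s) in `[0, 1]`.
#' @return corresponding Dice value(s).
#' @export
diceFromJaccard <- function(j) 2 * j / (1 + j)

metricsRow <- function(method, pred, truth, roi = NULL) {
  if (!is.null(roi)) {
    r <- maskData(roi)
    pred <- BinaryMask(maskData(pred) & r)
    truth <- BinaryMask(maskData(truth) & r)
  }
  cc <- confusionCounts(pred, truth)
  data.frame(method = method,
             accuracy = segAccuracy(cc),
             jsi = jaccardIndex(cc),
             dsc = diceCoefficient(cc),
             stringsAsFactors = FALSE)
}

#' Compare segmentation methods on one image
#'
#' Runs each requested method end-to-end — `fcm` and `kmeans` are the
#' plain-clustering baselines without superpixel presegmentation or fusion,
#' `spfkmc` the full hybrid pipeline — and scores each result against the
#' reference mask. The `spfkmc` vs `kmeans` rows quantify the
#' with/without-fusion difference. A method failure is recorded as an NA row
#' rather than aborting the comparison. When `roi` is given (typically the
#' lung field), both predicted and reference masks are restricted to it
#' before counting.
#'
#' @param image a [RasterImage-class].
#' @param truth reference [BinaryMask-class].
#' @param methods subset of `c("fcm", "kmeans", "spfkmc")`.
#' @param config a [PipelineConfig-class].
#' @param roi optional [BinaryMask-class] region of interest.
#' @param clusterSelector optional `function(cs)` returning the lesion
#'   cluster indices (see [chooseLesionClusters()]); overrides the config's
#'   selection mode.
#' @return data.frame with columns `method`, `accuracy`, `jsi`, `dsc`.
#' @export
evaluateMethods <- function(image, truth, methods = c("fcm", "kmeans", "spfkmc"),
                            config = pipelineConfig(), roi = NULL,
                            clusterSelector = NULL) {
  stopifnot(all(methods %in% c("fcm", "kmeans", "spfkmc")))
  rows <- lapply(methods, function(m) {
    res <- tryCatch({
      if (m == "spfkmc")
        runSPFKMC(image, config, clusterSelector = clusterSelector)
      else
        runBaseline(image, method = m, config = config,
                    clusterSelector = clusterSelector)
    }, error = function(e) {
      warning("method '", m, "' failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res))
      return(data.frame(method = m, accuracy = NA_real_, jsi = NA_real_,
                        dsc = NA_real_, stringsAsFactors = FALSE))
    tr <- truth
    if (!all(dim(res$mask) == dim(tr)))
      stop("truth mask size must match the working geometry of the pipeline")
    metricsRow(m, res$mask, tr, roi)
  })
  if (!length(rows))
    return(data.frame(method = character(0), accuracy = numeric(0),
                      jsi = numeric(0), dsc = numeric(0)))
  do.call(rbind, rows)
}
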