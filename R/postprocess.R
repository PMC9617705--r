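# Morphological cleanup of the fused mask, boundary extraction, color
# overlay, and whole-image cross-correlation pattern matching.

#' Binary dilation
#'
#' Minkowski dilation with a flat disk/square structuring element; since the
#' SE contains the origin the output is a superset of the input. The
#' neighborhood is restricted to in-image pixels at the border.
#'
#' @param mask a [BinaryMask-class].
#' @param se a [StructuringElement-class]; default square of radius 1.
#' @return the dilated [BinaryMask-class].
#' @export
dilateMask <- function(mask, se = structuringElement("square", 1L)) {
  stopifnot(is(mask, "BinaryMask"))
  BinaryMask(grayDilate(maskData(mask) * 1, se) > 0.5)
}

#' Binary erosion
#'
#' Dual of [dilateMask()]: `erode(m) == !dilate(!m)` holds exactly for the
#' symmetric SEs used here. Output is a subset of the input.
#'
#' @inheritParams dilateMask
#' @return the eroded [BinaryMask-class].
#' @export
erodeMask <- function(mask, se = structuringElement("square", 1L)) {
  stopifnot(is(mask, "BinaryMask"))
  BinaryMask(grayErode(maskData(mask) * 1, se) > 0.5)
}

#' Binary opening (erosion then dilation)
#'
#' Anti-extensive, idempotent cleanup that removes foreground speckles
#' smaller than the SE; the pipeline's post-fusion step with a disk of
#' radius 1.
#'
#' @inheritParams dilateMask
#' @export
openMask <- function(mask, se = structuringElement("disk", 1L)) {
  dilateMask(erodeMask(mask, se), se)
}

#' Inner boundary of a mask
#'
#' `mask AND NOT erode(mask, square r = 1)`: a one-pixel-thick contour for
#' convex shapes; thin (1-px) inputs are fixed points.
#'
#' @param mask a [BinaryMask-class].
#' @return boundary [BinaryMask-class].
#' @export
extractBoundary <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  BinaryMask(maskData(mask) & !maskData(erodeMask(mask,
    structuringElement("square", 1L))))
}

#' Overlay a mask on the original image in color
#'
#' Alpha-blends masked pixels toward `color`; unmasked pixels are untouched.
#' Grayscale originals are replicated to RGB first.
#'
#' @param original a [RasterImage-class] in gray or sRGB.
#' @param mask a [BinaryMask-class] of the same size.
#' @param color RGB triple in `[0, 1]`; default red.
#' @param alpha blend weight of the color; default 0.5.
#' @return an sRGB [RasterImage-class].
#' @export
applyColorMask <- function(original, mask, color = c(1, 0, 0), alpha = 0.5) {
  stopifnot(is(original, "RasterImage"), is(mask, "BinaryMask"))
  if (!all(dim(original) == dim(mask)))
    stop("image and mask sizes differ")
  d <- imgData(original)
  if (dim(d)[3] == 1L) d <- array(d[, , c(1, 1, 1)], c(dim(d)[1:2], 3L))
  m <- maskData(mask)
  for (ch in 1:3) {
    pl <- d[, , ch]
    pl[m] <- (1 - alpha) * pl[m] + alpha * color[ch]
    d[, , ch] <- pl
  }
  RasterImage(clip01(d), "sRGB")
}

#' Classify a segmented pattern by normalized cross-correlation
#'
#' Whole-image template matching: each labeled template is resized to the
#' segmentation's shape and scored by the zero-mean normalized
#' cross-correlation (Pearson correlation over pixels, in `[-1, 1]`); the
#' best-scoring label wins. A zero-variance image or template scores 0 for
#' that pair. The score is invariant to affine intensity rescaling.
#'
#' @param seg single-channel [RasterImage-class] (e.g. the fused result).
#' @param templates named list of single-channel [RasterImage-class]
#'   templates; names are the class labels.
#' @return list with `label` and `score`, plus all `scores`.
#' @export
classifyPattern <- function(seg, templates) {
  stopifnot(is(seg, "RasterImage"))
  if (!length(templates)) stop("at least one template is required")
  if (is.null(names(templates)) || any(!nzchar(names(templates))))
    stop("templates must be named by class label")
  sv <- as.vector(toLuminance(seg))
  d <- dim(seg)
  scores <- vapply(templates, function(tp) {
    tv <- as.vector(toLuminance(resizeRaster(tp, d[1], d[2])))
    if (stats::sd(sv) == 0 || stats::sd(tv) == 0) return(0)
    stats::cor(sv, tv)
  }, numeric(1))
  best <- which.max(scores)
  list(label = names(templates)[best], score = unname(scores[best]),
       scores = scores)
}

#' Load a template library from a directory of labeled images
#'
#' Labels are taken from file names (without extension).
#'
#' @param dir directory containing PNG/JPEG patches.
#' @return named list of [RasterImage-class] templates.
#' @export
loadTemplates <- function(dir) {
  files <- list.files(dir, pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE,
                      full.names = TRUE)
  if (!length(files)) stop("no template images found in: ", dir)
  out <- lapply(files, readRaster)
  names(out) <- tools::file_path_sans_ext(basename(files))
  out
}
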