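#' Read a CT slice or mask image
#'
#' Reads PNG, JPEG or DICOM rasters and normalizes them to the package's
#' working representation: floating-point values in `[0, 1]`, one or three
#' channels. DICOM input is consumed pixel-data-only: the stored array is
#' min-max window-scaled to `[0, 1]` and tagged grayscale; all metadata
#' beyond image geometry is ignored. Only uncompressed explicit-VR
#' little-endian DICOM is supported.
#'
#' @param path path to a `.png`, `.jpg`/`.jpeg` or `.dcm` file.
#' @return a [RasterImage-class]; grayscale files yield `colorspace = "gray"`,
#'   color files `"sRGB"`.
#' @examples
#' f <- tempfile(fileext = ".png")
#' writeRaster(RasterImage(matrix(runif(256), 16, 16)), f)
#' img <- readRaster(f)
#' @export
readRaster <- function(path) {
  if (!file.exists(path))
    stop("cannot read image: file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png", "jpg", "jpeg")) {
    eb <- tryCatch(EBImage::readImage(path),
                   error = function(e) stop("unreadable ", toupper(ext),
                                            " file: ", path, " (", conditionMessage(e), ")"))
    d <- EBImage::imageData(eb)
    if (length(dim(d)) == 3L && dim(d)[3] == 4L) d <- d[, , 1:3]  # drop alpha
    if (length(dim(d)) == 3L && dim(d)[3] == 2L) d <- d[, , 1, drop = FALSE]
    eb <- EBImage::Image(d, colormode = if (length(dim(d)) == 3L && dim(d)[3] == 3L)
      "Color" else "Grayscale")
    if (length(dim(d)) == 2L || dim(d)[3] == 1L) {
      if (length(dim(d)) == 3L) d <- d[, , 1]
      return(RasterImage(array(t(clip01(d)), c(dim(d)[2], dim(d)[1], 1L)), "gray"))
    }
    return(fromEB(eb, "sRGB"))
  }
  if (ext == "dcm") return(readDicomRaster(path))
  stop("unsupported image format '", ext, "' for: ", path,
       " (supported: png, jpg/jpeg, dcm)")
}

# Minimal DICOM reader: explicit-VR little-endian, uncompressed pixel data.
readDicomRaster <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  u16 <- function() readBin(con, "integer", 1, size = 2, signed = FALSE,
                            endian = "little")
  u32 <- function() readBin(con, "integer", 1, size = 4, endian = "little")
  hdr <- readBin(con, "raw", 132)
  if (length(hdr) < 132 || rawToChar(hdr[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  rows <- cols <- bits <- NA_integer_; signed <- FALSE
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  repeat {
    grp <- u16()
    if (length(grp) == 0) stop("DICOM pixel data element not found in: ", path)
    ele <- u16()
    vr <- rawToChar(readBin(con, "raw", 2))
    if (!grepl("^[A-Z][A-Z]$", vr))
      stop("unsupported DICOM encoding (implicit VR?) in: ", path)
    len <- if (vr %in% long_vrs) { readBin(con, "raw", 2); u32() } else u16()
    tag <- sprintf("%04x%04x", grp, ele)
    if (tag == "7fe00010") {
      if (any(is.na(c(rows, cols, bits))))
        stop("DICOM geometry tags missing before pixel data in: ", path)
      nbyte <- if (bits > 8) 2L else 1L
      v <- readBin(con, "integer", rows * cols, size = nbyte,
                   signed = if (nbyte == 1L) FALSE else signed,
                   endian = "little")
      if (length(v) < rows * cols) stop("truncated DICOM pixel data in: ", path)
      m <- matrix(as.numeric(v), nrow = rows, byrow = TRUE)
      rng <- range(m)
      m <- if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
      return(grayImage(m))
    }
    val <- readBin(con, "raw", len)
    asU16 <- function(r) sum(as.integer(r) * c(1, 256))
    if (tag == "00280010") rows <- asU16(val[1:2])
    if (tag == "00280011") cols <- asU16(val[1:2])
    if (tag == "00280100") bits <- asU16(val[1:2])
    if (tag == "00280103") signed <- asU16(val[1:2]) == 1L
  }
}

#' Write a RasterImage or BinaryMask to PNG/JPEG
#'
#' Values are quantized to 8-bit at write time (the only quantization point
#' in the pipeline); masks are written as 0/255 PNG and round-trip
#' bit-exactly.
#'
#' @param x a [RasterImage-class] or [BinaryMask-class].
#' @param path output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
writeRaster <- function(x, path) {
  if (is(x, "BinaryMask")) x <- grayImage(maskData(x) * 1)
  stopifnot(is(x, "RasterImage"))
  if (colorspace(x) == "Lab")
    stop("write Lab images after converting back to sRGB/gray")
  EBImage::writeImage(asEB(x), path)
  invisible(path)
}

#' Resize to the working geometry
#'
#' Bilinear resampling with pixel-center alignment: target pixel `i`
#' (0-based) samples source coordinate `(i + 0.5) * n_src / n_dst - 0.5`,
#' clamped to the image. Same-size calls return the input unchanged. The
#' working geometry of the pipeline is 240 x 320.
#'
#' @param img a [RasterImage-class].
#' @param h,w target height and width in pixels (>= 8); default 240 x 320.
#' @return a resized [RasterImage-class] with values clipped to `[0, 1]`.
#' @export
resizeRaster <- function(img, h = 240L, w = 320L) {
  stopifnot(is(img, "RasterImage"))
  if (h < 8L || w < 8L) stop("target dimensions must be >= 8")
  d <- imgData(img)
  hs <- dim(d)[1]; ws <- dim(d)[2]
  if (hs == h && ws == w) return(img)
  ax <- function(n_src, n_dst) {
    x <- (seq_len(n_dst) - 0.5) * n_src / n_dst - 0.5
    x <- pmin(pmax(x, 0), n_src - 1)
    i0 <- pmin(floor(x), n_src - 2)  # 0-based lower sample, i0+1 valid
    if (n_src == 1L) i0 <- rep(0, n_dst)
    list(i0 = i0 + 1L, frac = x - i0)
  }
  ry <- ax(hs, h); rx <- ax(ws, w)
  out <- array(0, c(h, w, dim(d)[3]))
  for (ch in seq_len(dim(d)[3])) {
    m <- d[, , ch]
    rowint <- m[ry$i0, , drop = FALSE] * (1 - ry$frac) +
      m[pmin(ry$i0 + 1L, hs), , drop = FALSE] * ry$frac
    wx0 <- matrix(1 - rx$frac, h, w, byrow = TRUE)
    out[, , ch] <- rowint[, rx$i0, drop = FALSE] * wx0 +
      rowint[, pmin(rx$i0 + 1L, ws), drop = FALSE] * (1 - wx0)
  }
  if (colorspace(img) %in% c("gray", "sRGB")) out <- clip01(out)
  RasterImage(out, colorspace(img))
}

#' Write pipeline products to a directory
#'
#' Label maps and masks are written as PNG, metric reports as CSV and JSON,
#' and the run configuration is always echoed as `config.json` so a run can
#' be reproduced from its output directory alone.
#'
#' @param results a named list with optional entries `masks` (list of
#'   [BinaryMask-class]), `labels` (list of [LabelMap-class]), `report`
#'   (data.frame of metric rows).
#' @param dir output directory (created if needed).
#' @param config a [PipelineConfig-class] to echo.
#' @return character vector of files written.
#' @export
writeOutputs <- function(results, dir, config = pipelineConfig()) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  if (file.access(dir, 2) != 0) stop("output directory not writable: ", dir)
  written <- character(0)
  for (i in seq_along(results$masks)) {
    nm <- names(results$masks)[i]
    if (is.null(nm) || !nzchar(nm)) nm <- paste0("mask_", i)
    f <- file.path(dir, paste0(nm, ".png"))
    writeRaster(results$masks[[i]], f)
    written <- c(written, f)
  }
  for (i in seq_along(results$labels)) {
    nm <- names(results$labels)[i]
    if (is.null(nm) || !nzchar(nm)) nm <- paste0("labels_", i)
    lm <- results$labels[[i]]
    f <- file.path(dir, paste0(nm, ".png"))
    writeRaster(grayImage(labelData(lm) / nRegions(lm)), f)
    written <- c(written, f)
  }
  if (!is.null(results$report)) {
    fc <- file.path(dir, "metrics.csv")
    utils::write.csv(results$report, fc, row.names = FALSE)
    fj <- file.path(dir, "metrics.json")
    jsonlite::write_json(results$report, fj, digits = NA, pretty = TRUE)
    written <- c(written, fc, fj)
  }
  fcfg <- file.path(dir, "config.json")
  writeLines(configToJSON(config), fcfg)
  written <- c(written, fcfg)
  written
}
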