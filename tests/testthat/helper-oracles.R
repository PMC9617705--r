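# Independent oracles and fixture builders used across the suite. Each
# oracle is a deliberately naive implementation (iteration, enumeration or
# the textbook formula) kept separate from the package's computation path.

grayRaster <- function(m) RasterImage(matrix(m, nrow(m), ncol(m)))

# iterative geodesic-dilation fixpoint: dilate the marker with a 3x3 flat SE
# (8-connectivity), cap by the mask, repeat until unchanged
reconstructOracle <- function(marker, mask) {
  cur <- marker
  repeat {
    dil <- cur
    nr <- nrow(cur); nc <- ncol(cur)
    for (dy in -1:1) for (dx in -1:1) {
      ys <- pmin(pmax(seq_len(nr) + dy, 1), nr)
      xs <- pmin(pmax(seq_len(nc) + dx, 1), nc)
      sh <- cur[ys, xs, drop = FALSE]
      # out-of-image neighbors must not contribute: blank the wrapped edge
      if (dy == -1) sh[1, ] <- -Inf
      if (dy == 1) sh[nr, ] <- -Inf
      if (dx == -1) sh[, 1] <- -Inf
      if (dx == 1) sh[, nc] <- -Inf
      dil <- pmax(dil, sh)
    }
    nxt <- pmin(dil, mask)
    if (identical(nxt, cur)) return(cur)
    cur <- nxt
  }
}

# exhaustive minimum-J bipartition of n points (n small)
bruteForceKmeans2 <- function(points) {
  n <- nrow(points)
  best <- NULL
  for (code in 1:(2^(n - 1) - 1)) {   # fix point 1 in cluster 1; skip empty
    lab <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    if (length(unique(lab)) < 2L) next
    J <- 0
    for (j in 1:2) {
      mem <- points[lab == j, , drop = FALSE]
      ctr <- colMeans(mem)
      J <- J + sum(sweep(mem, 2, ctr)^2)
    }
    if (is.null(best) || J < best$J) best <- list(J = J, lab = lab)
  }
  best
}

# textbook sRGB (D65) -> XYZ -> Lab for one rgb triple in [0,1]
labOracle <- function(rgb) {
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  M <- rbind(c(0.4124564, 0.3575761, 0.1804375),
             c(0.2126729, 0.7151522, 0.0721750),
             c(0.0193339, 0.1191920, 0.9503041))
  xyz <- as.vector(M %*% lin)
  wp <- c(0.950456, 1, 1.088754)      # D65 reference white
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3),
                          t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(xyz / wp)
  c(L = 116 * fx[2] - 16, a = 500 * (fx[1] - fx[2]), b = 200 * (fx[2] - fx[3]))
}

# minimal explicit-VR little-endian DICOM writer (16-bit pixel data)
writeSyntheticDicom <- function(path, pixels) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  elemUS <- function(group, elem, value) {
    writeBin(c(group, elem), con, size = 2, endian = "little")
    writeChar("US", con, eos = NULL)
    writeBin(2L, con, size = 2, endian = "little")
    writeBin(as.integer(value), con, size = 2, endian = "little")
  }
  elemUS(0x0028L, 0x0010L, nrow(pixels))
  elemUS(0x0028L, 0x0011L, ncol(pixels))
  elemUS(0x0028L, 0x0100L, 16L)
  elemUS(0x0028L, 0x0103L, 0L)
  writeBin(c(0x7fe0L, 0x0010L), con, size = 2, endian = "little")
  writeChar("OW", con, eos = NULL)
  writeBin(0L, con, size = 2, endian = "little")          # reserved
  writeBin(length(pixels) * 2L, con, size = 4, endian = "little")
  writeBin(as.integer(t(pixels)), con, size = 2, endian = "little")  # row-major
  invisible(path)
}

randomMask <- function(h, w, p = 0.5) {
  BinaryMask(matrix(stats::runif(h * w) < p, h, w))
}

# polarity-based lesion-cluster selector used by the phantom evaluations
phantomSelector <- function(phantom, n = 1L) {
  pol <- if (phantom$spec@category == "emphysema") "dark" else "bright"
  function(cs) chooseLesionClusters(cs, pol, roi = phantom$lungMask, n = n)
}

lungRestricted <- function(mask, lung) BinaryMask(maskData(mask) & maskData(lung))
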