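# Internal helpers shared across modules.

clip01 <- function(x) pmin(pmax(x, 0), 1)

# EBImage stores images as [x, y(, c)]; the package works in [row, col(, c)].
asEB <- function(img) {
  d <- imgData(img)
  if (dim(d)[3] == 1L) EBImage::Image(t(d[, , 1]), colormode = "Grayscale")
  else EBImage::Image(aperm(d, c(2, 1, 3)), colormode = "Color")
}

fromEB <- function(eb, colorspace = NULL) {
  d <- EBImage::imageData(eb)
  if (length(dim(d)) == 2L) d <- array(t(d), c(dim(d)[2], dim(d)[1], 1L))
  else d <- aperm(d, c(2, 1, 3))
  RasterImage(clip01(d), colorspace = colorspace)
}

# Single-channel matrix view; sRGB is reduced through the Lab L channel
# (rescaled to [0,1]), gray images pass through.
toLuminance <- function(img) {
  if (nChannels(img) == 1L) return(imgData(img)[, , 1])
  if (colorspace(img) == "Lab") return(clip01(imgData(img)[, , 1] / 100))
  lab <- rgbToLab(img)
  clip01(imgData(lab)[, , 1] / 100)
}

grayImage <- function(m) RasterImage(array(clip01(m), c(dim(m), 1L)), "gray")

# Run code under a fixed seed without disturbing the caller's RNG stream.
withLocalSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

seMatrix <- function(se) {
  r <- se@radius
  if (se@shape == "square") {
    matrix(1L, 2L * r + 1L, 2L * r + 1L)
  } else {
    # pixelated disk: center distance <= r
    g <- expand.grid(y = -r:r, x = -r:r)
    matrix(as.integer(g$y^2 + g$x^2 <= r^2), 2L * r + 1L, 2L * r + 1L)
  }
}

# Grayscale dilation/erosion of a plain matrix with a flat SE.
grayDilate <- function(m, se) {
  eb <- EBImage::dilate(EBImage::Image(t(m)), seMatrix(se))
  t(EBImage::imageData(eb))
}

grayErode <- function(m, se) {
  eb <- EBImage::erode(EBImage::Image(t(m)), seMatrix(se))
  t(EBImage::imageData(eb))
}
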