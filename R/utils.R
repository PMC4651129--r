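# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. Every seeded operation in the package goes
# through this, so no function disturbs global random state.
with_rng <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Connected components of a logical matrix; 0 = background.
label_components <- function(x, connectivity = 8L) {
  stopifnot(is.matrix(x), connectivity %in% c(4L, 8L))
  .ccl_cpp(x, as.integer(connectivity))
}

# Binary disc structuring element: all integer offsets (i, j) with
# i^2 + j^2 <= (d/2)^2. This explicit definition (rather than a library
# brush) is the package's contract for every disc-based morphological step.
disc_brush <- function(diameter_px) {
  d <- max(1, diameter_px)
  r <- floor(d / 2)
  off <- seq(-r, r)
  k <- outer(off^2, off^2, "+") <= (d / 2)^2
  matrix(as.numeric(k), length(off), length(off))
}

# Gaussian smoothing of a plain matrix (replicate-padded borders).
gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  K <- outer(k, k)
  m <- EBImage::filter2(x, K, boundary = "replicate")
  matrix(as.numeric(m), nrow(x), ncol(x))
}

# Euclidean distance transform: distance from each TRUE pixel to the nearest
# FALSE pixel (0 on FALSE pixels).
dist_to_background <- function(x) {
  m <- EBImage::distmap(matrix(as.numeric(x), nrow(x), ncol(x)))
  matrix(as.numeric(m), nrow(x), ncol(x))
}

# Morphological operators on logical matrices with the package's disc
# element. Rasters are zero-padded by the disc radius first: pixels beyond
# the raster are background, not replicated (EBImage's border default).
morph_disc <- function(x, diameter_px, op) {
  br <- disc_brush(diameter_px)
  r <- (nrow(br) - 1L) %/% 2L
  h <- nrow(x); w <- ncol(x)
  pad <- matrix(0, h + 2L * r, w + 2L * r)
  pad[(r + 1):(r + h), (r + 1):(r + w)] <- as.numeric(x)
  out <- op(pad, br)
  matrix(as.numeric(out[(r + 1):(r + h), (r + 1):(r + w)]) > 0.5, h, w)
}

open_disc <- function(x, diameter_px) morph_disc(x, diameter_px, EBImage::opening)

dilate_disc <- function(x, diameter_px) morph_disc(x, diameter_px, EBImage::dilate)

erode_disc <- function(x, diameter_px) morph_disc(x, diameter_px, EBImage::erode)

`%||%` <- function(a, b) if (is.null(a)) b else a
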