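#' Stain model for haematoxylin/DAB colour separation
#'
#' Bundles the optical-density (OD) vectors of the two stains used in nuclear
#' ER immunohistochemistry -- haematoxylin (blue nuclear counterstain) and DAB
#' (brown chromogen marking ER) -- together with the background (unstained
#' glass) RGB level. Stain concentrations combine additively in OD
#' (Beer-Lambert), so a known pair of unit OD vectors lets an RGB image be
#' separated into per-stain OD maps by linear projection.
#'
#' The defaults are the widely used Ruifrok-Johnston OD triplets for
#' haematoxylin and DAB, normalised to unit length.
#'
#' @param od_haematoxylin Numeric length-3 OD vector (per RGB channel) for
#'   haematoxylin; normalised internally to unit Euclidean length.
#' @param od_dab Numeric length-3 OD vector for DAB; normalised internally.
#' @param background_rgb Length-3 integer vector in `[0, 255]`: the RGB value
#'   of an unstained (fully transmitting) pixel.
#' @return An object of class `stain_model` with components `od_haematoxylin`,
#'   `od_dab`, `od_residual` (unit vector orthogonal to both, completing the
#'   deconvolution basis) and `background_rgb`.
#' @examples
#' sm <- stain_model()
#' sqrt(sum(sm$od_haematoxylin^2)) # 1
#' @export
stain_model <- function(od_haematoxylin = c(0.650, 0.704, 0.286),
                        od_dab = c(0.269, 0.570, 0.776),
                        background_rgb = c(255, 255, 255)) {
  stopifnot(length(od_haematoxylin) == 3L, length(od_dab) == 3L,
            length(background_rgb) == 3L,
            all(od_haematoxylin >= 0), all(od_dab >= 0),
            all(background_rgb >= 0), all(background_rgb <= 255))
  vh <- od_haematoxylin / sqrt(sum(od_haematoxylin^2))
  vd <- od_dab / sqrt(sum(od_dab^2))
  ang <- acos(pmin(1, abs(sum(vh * vd)))) * 180 / pi
  if (ang <= 10) {
    stop("stain OD vectors are nearly collinear (angle ", round(ang, 1),
         " degrees); they must differ by more than 10 degrees")
  }
  vr <- c(vh[2] * vd[3] - vh[3] * vd[2],
          vh[3] * vd[1] - vh[1] * vd[3],
          vh[1] * vd[2] - vh[2] * vd[1])
  vr <- vr / sqrt(sum(vr^2))
  structure(list(od_haematoxylin = vh, od_dab = vd, od_residual = vr,
                 background_rgb = as.numeric(background_rgb)),
            class = "stain_model")
}

#' @export
print.stain_model <- function(x, ...) {
  cat("stain_model (H-DAB)\n")
  cat("  haematoxylin OD:", sprintf("%.3f", x$od_haematoxylin), "\n")
  cat("  DAB OD:         ", sprintf("%.3f", x$od_dab), "\n")
  cat("  background RGB: ", x$background_rgb, "\n")
  invisible(x)
}

#' Render stain OD maps to an RGB image (Beer-Lambert forward model)
#'
#' Converts per-pixel haematoxylin and DAB optical densities into an 8-bit RGB
#' image: for channel `c`,
#' `value = round(background_rgb[c] * 10^-(haem_od * v_h[c] + dab_od * v_d[c]))`,
#' clipped to `[0, 255]`. This is the exact forward model inverted by
#' [colour_deconvolve()], so render/deconvolve round-trips are available as a
#' numerical check of both.
#'
#' @param haem_od Numeric matrix of haematoxylin OD (non-negative).
#' @param dab_od Numeric matrix of DAB OD, same shape.
#' @param stains A [stain_model()].
#' @return An H x W x 3 integer array with values in `[0, 255]`.
#' @export
render_stains <- function(haem_od, dab_od, stains = stain_model()) {
  stopifnot(is.matrix(haem_od), is.matrix(dab_od),
            all(dim(haem_od) == dim(dab_od)),
            inherits(stains, "stain_model"))
  if (any(haem_od < 0) || any(dab_od < 0)) {
    stop("optical densities must be non-negative")
  }
  out <- array(0L, c(nrow(haem_od), ncol(haem_od), 3L))
  for (c in 1:3) {
    od <- haem_od * stains$od_haematoxylin[c] + dab_od * stains$od_dab[c]
    v <- round(stains$background_rgb[c] * 10^(-od))
    out[, , c] <- pmin(255, pmax(0, v))
  }
  storage.mode(out) <- "integer"
  out
}

#' Colour deconvolution of an H-DAB image into stain OD maps
#'
#' Converts each pixel to optical density, `OD_c = -log10(I_c / background_c)`
#' (intensities clamped to a minimum of 1 count before the log), and solves the
#' 3x3 linear system projecting the OD vector onto the haematoxylin, DAB and
#' residual basis of the stain model. Negative stain projections, which arise
#' from noise, are clipped to zero; the total clipped mass is recorded.
#'
#' @param image A [spot_image()] or a plain H x W x 3 array in `[0, 255]`.
#' @param stains A [stain_model()].
#' @return An object of class `od_maps`: list with matrices `haematoxylin_od`,
#'   `dab_od`, `residual_od`, and `clipped_od_mass`, the summed OD removed by
#'   clipping negative projections.
#' @export
colour_deconvolve <- function(image, stains = stain_model()) {
  px <- if (inherits(image, "spot_image")) image$pixels else image
  stopifnot(length(dim(px)) == 3L, dim(px)[3] == 3L,
            inherits(stains, "stain_model"))
  h <- dim(px)[1]; w <- dim(px)[2]
  od <- matrix(0, h * w, 3L)
  for (c in 1:3) {
    I <- pmax(as.numeric(px[, , c]), 1)
    od[, c] <- -log10(I / max(stains$background_rgb[c], 1))
  }
  basis <- rbind(stains$od_haematoxylin, stains$od_dab, stains$od_residual)
  # od_pixel = t(basis) %*% conc  =>  conc = solve(t(basis)) %*% od_pixel
  conc <- od %*% t(solve(t(basis)))
  clipped <- sum(pmax(-conc[, 1:2], 0))
  conc[, 1:2][conc[, 1:2] < 0] <- 0
  structure(list(
    haematoxylin_od = matrix(conc[, 1], h, w),
    dab_od = matrix(conc[, 2], h, w),
    residual_od = matrix(conc[, 3], h, w),
    clipped_od_mass = clipped
  ), class = "od_maps")
}
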