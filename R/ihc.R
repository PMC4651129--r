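#' Nucleus detection parameters
#'
#' Defaults are calibration constants for the open nuclear scorer: the
#' candidate raster is the Gaussian-smoothed sum of haematoxylin and DAB OD
#' (every nucleus is dense in at least one of the two), thresholded at
#' `threshold_od`; touching blobs are split by a distance-transform
#' watershed; components are kept only if their centroid lies on a tumour
#' pixel and their area lies within `[min_area_um2, max_area_um2]`.
#'
#' @param smooth_sigma_um Gaussian smoothing scale in microns.
#' @param threshold_od OD threshold on the smoothed haem+DAB sum. The
#'   default sits well above diffuse tissue background (epithelial sheets
#'   plus stromal texture reach about 0.34 OD) and well below nuclear cores
#'   (0.7 OD and up), so only nuclei seed candidates.
#' @param min_area_um2,max_area_um2 Component area bounds in square microns.
#' @param watershed_tolerance Minimum distance-map depth separating two
#'   nuclei before they are split.
#' @return List of class `detection_params`.
#' @export
detection_params <- function(smooth_sigma_um = 1.0, threshold_od = 0.40,
                             min_area_um2 = 12, max_area_um2 = 300,
                             watershed_tolerance = 1) {
  stopifnot(smooth_sigma_um >= 0, threshold_od > 0,
            min_area_um2 > 0, max_area_um2 > min_area_um2)
  structure(list(smooth_sigma_um = smooth_sigma_um, threshold_od = threshold_od,
                 min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 watershed_tolerance = watershed_tolerance),
            class = "detection_params")
}

#' Detect nuclei within tumour regions
#'
#' Finds candidate nuclei on the stain OD maps and keeps those whose centroid
#' lies on a tumour (T) pixel of the supplied mask -- only tumour regions are
#' passed to scoring. Per-nucleus mean haematoxylin and DAB OD are computed
#' over the component's pixels. An empty tumour region yields an empty table,
#' not an error.
#'
#' @param od An `od_maps` object from [colour_deconvolve()].
#' @param tumour_mask A [label_mask()]; only components with centroid on a T
#'   pixel are kept.
#' @param params A [detection_params()].
#' @param pixel_size_um Microns per pixel, used to convert the micron-scale
#'   parameters to pixels.
#' @return data.frame with columns `row`, `col` (centroid), `area_px`,
#'   `mean_dab_od`, `mean_haem_od` -- one row per nucleus. Intensity bins are
#'   assigned separately by [assign_intensity_bins()].
#' @export
detect_nuclei <- function(od, tumour_mask, params = detection_params(),
                          pixel_size_um = 1) {
  stopifnot(inherits(od, "od_maps"), inherits(tumour_mask, "label_mask"),
            all(dim(od$haematoxylin_od) == dim(tumour_mask)))
  empty <- data.frame(row = numeric(0), col = numeric(0),
                      area_px = integer(0), mean_dab_od = numeric(0),
                      mean_haem_od = numeric(0))
  tm <- mask_matrix(tumour_mask)
  if (!any(tm == LABEL_T)) return(empty)

  cand <- gauss_smooth(od$haematoxylin_od + od$dab_od,
                       params$smooth_sigma_um / pixel_size_um)
  fg <- cand > params$threshold_od
  if (!any(fg)) return(empty)

  dm <- dist_to_background(fg)
  ws <- EBImage::watershed(dm, tolerance = params$watershed_tolerance)
  lab <- matrix(as.integer(ws), nrow(fg), ncol(fg))
  n <- max(lab)
  if (n == 0) return(empty)

  sel <- lab > 0
  g <- lab[sel]
  area <- tabulate(g, nbins = n)
  rows <- matrix(seq_len(nrow(lab)), nrow(lab), ncol(lab))
  cols <- matrix(seq_len(ncol(lab)), nrow(lab), ncol(lab), byrow = TRUE)
  acc <- rowsum(cbind(rows[sel], cols[sel],
                      as.vector(od$dab_od)[sel], as.vector(od$haematoxylin_od)[sel]), g)
  gi <- as.integer(rownames(acc))
  cr <- numeric(n); cc <- numeric(n); sdab <- numeric(n); shaem <- numeric(n)
  cr[gi] <- acc[, 1]; cc[gi] <- acc[, 2]; sdab[gi] <- acc[, 3]; shaem[gi] <- acc[, 4]
  cr <- cr / pmax(area, 1); cc <- cc / pmax(area, 1)
  mdab <- sdab / pmax(area, 1); mhaem <- shaem / pmax(area, 1)

  min_px <- params$min_area_um2 / pixel_size_um^2
  max_px <- params$max_area_um2 / pixel_size_um^2
  ri <- pmin(nrow(tm), pmax(1L, as.integer(round(cr))))
  ci <- pmin(ncol(tm), pmax(1L, as.integer(round(cc))))
  keep <- area >= min_px & area <= max_px &
    tm[cbind(ri, ci)] == LABEL_T
  data.frame(row = cr[keep], col = cc[keep], area_px = area[keep],
             mean_dab_od = mdab[keep], mean_haem_od = mhaem[keep])
}

#' Assign staining intensity bins to detected nuclei
#'
#' Bins each nucleus's mean DAB OD into the 0-3 intensity scale using
#' half-open intervals: bin 0 below `t1`; 1 on `[t1, t2)`; 2 on `[t2, t3)`;
#' 3 at or above `t3`. A nucleus is ER-positive iff its bin is at least 1.
#' The default thresholds are calibration constants of the open scorer, not
#' biological givens; they pair with the synthetic generator, which programs
#' nuclear DAB so detected means land mid-bin.
#'
#' @param nuclei data.frame from [detect_nuclei()].
#' @param thresholds Strictly increasing positive numeric length-3 vector
#'   `(t1, t2, t3)` in OD units.
#' @return The input data.frame with `intensity_bin` (integer 0-3) and
#'   `is_positive` (logical) columns.
#' @export
assign_intensity_bins <- function(nuclei, thresholds = c(0.15, 0.40, 0.70)) {
  stopifnot(is.data.frame(nuclei), length(thresholds) == 3L)
  if (!(thresholds[1] > 0 && thresholds[1] < thresholds[2] &&
        thresholds[2] < thresholds[3])) {
    stop("thresholds must satisfy 0 < t1 < t2 < t3")
  }
  bin <- findInterval(nuclei$mean_dab_od, thresholds)
  nuclei$intensity_bin <- as.integer(bin)
  nuclei$is_positive <- bin >= 1L
  nuclei
}

allred_proportion_bin <- function(pct) {
  stopifnot(pct >= 0, pct <= 100)
  if (pct == 0) 0L
  else if (pct < 1) 1L
  else if (pct < 10) 2L
  else if (pct < 100 / 3) 3L
  else if (pct < 200 / 3) 4L
  else 5L
}

quickscore_proportion_bin <- function(pct) {
  stopifnot(pct >= 0, pct <= 100)
  if (pct < 5) 1L
  else if (pct < 20) 2L
  else if (pct < 40) 3L
  else if (pct < 60) 4L
  else if (pct < 80) 5L
  else 6L
}

#' Compute Allred score and Quickscore for one spot
#'
#' Aggregates per-nucleus measurements into the two standard ER IHC scoring
#' systems. Percent positive is cell-count based: `100 * positives /
#' n_nuclei`. The spot intensity score (0-3) is, by default, the intensity
#' bin of the mean DAB OD over positive nuclei (`aggregation = "mean_od"`);
#' `"modal_bin"` uses the most frequent positive-nucleus bin instead (ties to
#' the lower bin). Allred total = intensity + Allred proportion bin (0-5,
#' range 0-8); Quickscore total = intensity + Quickscore proportion bin
#' (1-6). ER status calls use exclusive cut-offs: Allred total > 2
#' (equivalent to the 1 percent rule) and Quickscore total > 3.
#'
#' @param nuclei data.frame with `mean_dab_od`, `intensity_bin`,
#'   `is_positive` (from [assign_intensity_bins()]). May have zero rows: the
#'   spot scores 0 everywhere (Quickscore proportion 1) with a warning.
#' @param thresholds Intensity thresholds, as in [assign_intensity_bins()].
#' @param aggregation `"mean_od"` or `"modal_bin"`.
#' @param allred_cutoff,quickscore_cutoff ER-positive iff total strictly
#'   exceeds the cut-off.
#' @return Object of class `spot_ihc_score`: list with `n_nuclei`,
#'   `percent_positive`, `intensity_score`, `allred_proportion`,
#'   `allred_total`, `quickscore_proportion`, `quickscore_total`,
#'   `er_status_allred`, `er_status_quickscore`.
#' @export
score_spot <- function(nuclei, thresholds = c(0.15, 0.40, 0.70),
                       aggregation = c("mean_od", "modal_bin"),
                       allred_cutoff = 2, quickscore_cutoff = 3) {
  aggregation <- match.arg(aggregation)
  n <- nrow(nuclei)
  if (n == 0) {
    warning("no nuclei detected; spot scored as all-zero")
    pct <- 0
    intensity <- 0L
  } else {
    pos <- nuclei$is_positive
    pct <- 100 * sum(pos) / n
    if (!any(pos)) {
      intensity <- 0L
    } else if (aggregation == "mean_od") {
      intensity <- as.integer(findInterval(mean(nuclei$mean_dab_od[pos]),
                                           thresholds))
    } else {
      tb <- table(nuclei$intensity_bin[pos])
      intensity <- as.integer(names(tb)[which.max(tb)])
    }
  }
  ap <- allred_proportion_bin(pct)
  qp <- quickscore_proportion_bin(pct)
  at <- intensity + ap
  qt <- intensity + qp
  structure(list(
    n_nuclei = n, percent_positive = pct, intensity_score = intensity,
    allred_proportion = ap, allred_total = at,
    quickscore_proportion = qp, quickscore_total = qt,
    er_status_allred = at > allred_cutoff,
    er_status_quickscore = qt > quickscore_cutoff
  ), class = "spot_ihc_score")
}

#' @export
print.spot_ihc_score <- function(x, ...) {
  cat(sprintf(
    "spot_ihc_score: %d nuclei, %.1f%% positive, intensity %d, Allred %d (%s), Quickscore %d (%s)\n",
    x$n_nuclei, x$percent_positive, x$intensity_score,
    x$allred_total, if (x$er_status_allred) "ER+" else "ER-",
    x$quickscore_total, if (x$er_status_quickscore) "ER+" else "ER-"))
  invisible(x)
}

#' Score a spot image under a tumour mask (full IHC stage)
#'
#' Convenience wrapper chaining [colour_deconvolve()], [detect_nuclei()],
#' [assign_intensity_bins()] and [score_spot()].
#'
#' @param image A [spot_image()].
#' @param mask A [label_mask()] providing the tumour regions.
#' @param stains [stain_model()].
#' @param params [detection_params()].
#' @param thresholds Intensity thresholds.
#' @param ... Passed to [score_spot()].
#' @return A `spot_ihc_score`; the nucleus table is attached as attribute
#'   `"nuclei"`.
#' @export
score_tumour_mask <- function(image, mask, stains = stain_model(),
                              params = detection_params(),
                              thresholds = c(0.15, 0.40, 0.70), ...) {
  od <- colour_deconvolve(image, stains)
  nuc <- detect_nuclei(od, mask, params, image$pixel_size_um)
  nuc <- assign_intensity_bins(nuc, thresholds)
  sc <- suppressWarnings(score_spot(nuc, thresholds, ...))
  attr(sc, "nuclei") <- nuc
  sc
}
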