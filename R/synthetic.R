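#' Configuration for the synthetic TMA spot generator
#'
#' Describes one synthetic spot: geometry, tissue composition, nuclear
#' morphology and the programmed ER score that the downstream scorer should
#' recover. All randomness is driven by `seed`; identical configurations give
#' bit-identical spots.
#'
#' Compartments follow the composition of an invasive breast cancer core:
#' tumour epithelium (the T region of the mask), normal epithelium,
#' lymphocyte fields and sparse stromal cells (all within N). Nucleus
#' densities are per mm^2 of the compartment's area; radii are in microns, so
#' spot appearance is scale-invariant under `pixel_size_um`.
#'
#' @param diameter_px Spot diameter in pixels. The image is square with the
#'   inscribed disc as the valid spot region.
#' @param pixel_size_um Microns per pixel.
#' @param tumour_fraction Target fraction of in-spot pixels labelled tumour.
#' @param n_tumour_regions Number of tumour region seeds (regions may merge).
#' @param nucleus_density_per_mm2 Named numeric: nuclei per mm^2 for
#'   `tumour`, `normal_epithelium`, `lymphocyte`, `stroma_cell`.
#' @param programmed_percent_positive Percent of tumour nuclei rendered
#'   ER-positive (DAB-stained), in `[0, 100]`.
#' @param programmed_intensity_bin Intensity bin (0-3) programmed for the
#'   positive nuclei; must be 0 iff `programmed_percent_positive` is 0.
#' @param nucleus_radius_um Named numeric nuclear radii in microns for the
#'   four compartments.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise on the
#'   8-bit scale.
#' @param seed Integer seed for the spot's private random stream.
#' @param tumour_haem_offset Uniform haematoxylin OD added inside tumour
#'   regions, emulating the denser basophilic epithelial sheets that visually
#'   separate tumour from stroma.
#' @param compartment_fractions Named numeric: fraction of in-spot pixels
#'   used for `normal_epithelium` and `lymphocyte` placement fields.
#' @param texture_amplitude,texture_sigma_um Amplitude (OD) and correlation
#'   length of the low-amplitude stromal haematoxylin texture.
#' @param nucleus_haem_od Peak haematoxylin OD of an ER-negative nucleus.
#' @param positive_nucleus_haem_od Peak haematoxylin OD of an ER-positive
#'   nucleus (DAB dominates its colour).
#' @param intensity_bin_peak_od Length-4 numeric: peak DAB OD programmed for
#'   bins 0-3. Values are chosen so the detected per-nucleus mean OD (peak
#'   attenuated by the radial profile) falls near the middle of each
#'   intensity bin of [assign_intensity_bins()].
#' @param min_separation_factor Minimum distance between nucleus centres, as
#'   a multiple of the compartment's nucleus radius.
#' @return Object of class `synthetic_spot_config`.
#' @export
synthetic_spot_config <- function(diameter_px = 600,
                                  pixel_size_um = 1.0,
                                  tumour_fraction = 0.3,
                                  n_tumour_regions = 3,
                                  nucleus_density_per_mm2 = c(
                                    tumour = 1800, normal_epithelium = 1500,
                                    lymphocyte = 4000, stroma_cell = 400),
                                  programmed_percent_positive = 50,
                                  programmed_intensity_bin = 2,
                                  nucleus_radius_um = c(
                                    tumour = 5, normal_epithelium = 4,
                                    lymphocyte = 3, stroma_cell = 3),
                                  noise_sd = 2,
                                  seed = 1L,
                                  tumour_haem_offset = 0.12,
                                  compartment_fractions = c(
                                    normal_epithelium = 0.12, lymphocyte = 0.06),
                                  texture_amplitude = 0.05,
                                  texture_sigma_um = 8,
                                  nucleus_haem_od = 0.65,
                                  positive_nucleus_haem_od = 0.25,
                                  intensity_bin_peak_od = c(0, 0.35, 0.80, 1.45),
                                  min_separation_factor = 2.3) {
  comps <- c("tumour", "normal_epithelium", "lymphocyte", "stroma_cell")
  stopifnot(diameter_px > 0, pixel_size_um > 0,
            tumour_fraction >= 0, tumour_fraction <= 1,
            n_tumour_regions >= 1,
            all(comps %in% names(nucleus_density_per_mm2)),
            all(nucleus_density_per_mm2 > 0),
            programmed_percent_positive >= 0, programmed_percent_positive <= 100,
            programmed_intensity_bin %in% 0:3,
            all(comps %in% names(nucleus_radius_um)),
            all(nucleus_radius_um > 0),
            noise_sd >= 0, length(intensity_bin_peak_od) == 4L,
            min_separation_factor > 0)
  if (programmed_percent_positive == 0 && programmed_intensity_bin != 0) {
    stop("programmed_intensity_bin must be 0 when programmed_percent_positive is 0")
  }
  if (programmed_percent_positive > 0 && programmed_intensity_bin == 0) {
    stop("programmed_intensity_bin must be in 1..3 when positive nuclei are programmed")
  }
  structure(list(
    diameter_px = as.integer(diameter_px), pixel_size_um = pixel_size_um,
    tumour_fraction = tumour_fraction,
    n_tumour_regions = as.integer(n_tumour_regions),
    nucleus_density_per_mm2 = nucleus_density_per_mm2[comps],
    programmed_percent_positive = programmed_percent_positive,
    programmed_intensity_bin = as.integer(programmed_intensity_bin),
    nucleus_radius_um = nucleus_radius_um[comps],
    noise_sd = noise_sd, seed = as.integer(seed),
    tumour_haem_offset = tumour_haem_offset,
    compartment_fractions = compartment_fractions,
    texture_amplitude = texture_amplitude,
    texture_sigma_um = texture_sigma_um,
    nucleus_haem_od = nucleus_haem_od,
    positive_nucleus_haem_od = positive_nucleus_haem_od,
    intensity_bin_peak_od = intensity_bin_peak_od,
    min_separation_factor = min_separation_factor
  ), class = "synthetic_spot_config")
}

# Sum of anisotropic Gaussian bumps at `centers` (n x 2 matrix of row/col),
# with length scale `scale_px`, plus smooth random modulation.
bump_field <- function(h, w, centers, scale_px) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  f <- matrix(0, h, w)
  for (i in seq_len(nrow(centers))) {
    a <- scale_px * runif(1, 0.8, 1.3)
    b <- a * runif(1, 0.5, 0.9)
    th <- runif(1, 0, pi)
    dr <- rows - centers[i, 1]; dc <- cols - centers[i, 2]
    u <- cos(th) * dr + sin(th) * dc
    v <- -sin(th) * dr + cos(th) * dc
    f <- f + exp(-0.5 * ((u / a)^2 + (v / b)^2))
  }
  mod <- gauss_smooth(matrix(rnorm(h * w), h, w), scale_px / 2)
  rg <- max(f) - min(f)
  if (rg > 0 && sd(mod) > 0) f <- f + 0.15 * rg * mod / sd(mod)
  f
}

# Threshold `field` over `region` so that `fraction` of region pixels are TRUE.
threshold_fraction <- function(field, region, fraction) {
  out <- matrix(FALSE, nrow(field), ncol(field))
  if (fraction <= 0) return(out)
  vals <- field[region]
  if (fraction >= 1) { out[region] <- TRUE; return(out) }
  thr <- quantile(vals, 1 - fraction, names = FALSE, type = 1L)
  out[region & field > thr] <- TRUE
  # type-1 quantile with strict > can undershoot on ties; accept as-is
  out
}

# Hard-core sampling of `n` points over TRUE pixels of `allowed`, with
# minimum pairwise distance `min_dist` px. Errors if infeasible.
place_nuclei <- function(allowed, n, min_dist, compartment) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  idx <- which(allowed)
  if (length(idx) == 0) {
    stop("no pixels available to place ", compartment, " nuclei")
  }
  h <- nrow(allowed)
  pts <- matrix(NA_real_, n, 2)
  cell <- max(min_dist, 1)
  grid <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(r, c) paste(floor(r / cell), floor(c / cell))
  placed <- 0L
  attempts <- 0L
  max_attempts <- 40L * n
  cand <- sample(idx, length(idx))
  ci <- 1L
  while (placed < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    if (ci > length(cand)) ci <- 1L
    p <- cand[ci]; ci <- ci + 1L
    r <- ((p - 1L) %% h) + 1L
    c <- ((p - 1L) %/% h) + 1L
    ok <- TRUE
    gr <- floor(r / cell); gc <- floor(c / cell)
    for (dr in -1:1) for (dc in -1:1) {
      k <- paste(gr + dr, gc + dc)
      if (!ok) next
      nb <- grid[[k]]
      if (!is.null(nb)) {
        for (q in seq_len(nrow(nb))) {
          if ((nb[q, 1] - r)^2 + (nb[q, 2] - c)^2 < min_dist^2) { ok <- FALSE; break }
        }
      }
    }
    if (ok) {
      placed <- placed + 1L
      pts[placed, ] <- c(r, c)
      k <- key(r, c)
      grid[[k]] <- rbind(grid[[k]], c(r, c))
    }
  }
  if (placed < n) {
    stop("could not place ", n, " ", compartment, " nuclei at density; ",
         "placed ", placed, " -- density infeasible for the compartment area")
  }
  pts
}

# Add one elliptical nucleus profile (flat core, cosine edge) into `od` at
# centre (r0, c0) with nominal radius `rad_px`; returns the updated matrix.
add_nucleus_profile <- function(od, r0, c0, rad_px, peak, axis_ratio, angle) {
  if (peak <= 0) return(od)
  h <- nrow(od); w <- ncol(od)
  a <- rad_px * sqrt(axis_ratio)
  b <- rad_px / sqrt(axis_ratio)
  ext <- ceiling(1.1 * max(a, b)) + 1
  r1 <- max(1, floor(r0 - ext)); r2 <- min(h, ceiling(r0 + ext))
  c1 <- max(1, floor(c0 - ext)); c2 <- min(w, ceiling(c0 + ext))
  rr <- r1:r2; cc <- c1:c2
  dr <- matrix(rr - r0, length(rr), length(cc))
  dc <- matrix(cc - c0, length(rr), length(cc), byrow = TRUE)
  u <- cos(angle) * dr + sin(angle) * dc
  v <- -sin(angle) * dr + cos(angle) * dc
  rho <- sqrt((u / a)^2 + (v / b)^2)
  f <- pmin(1, pmax(0, (1.1 - rho) / (1.1 - 0.85)))
  od[rr, cc] <- od[rr, cc] + peak * f
  od
}

#' Generate a synthetic TMA spot with ground truth
#'
#' Builds one circular TMA spot image by a Beer-Lambert forward model: tumour
#' regions are grown from seeded anisotropic blobs to a target area fraction;
#' nuclei are placed per compartment by hard-core sampling and rendered as
#' ellipses with a flat-core radial OD profile (overlaps sum in OD, keeping
#' the forward model linear and so exactly invertible by colour
#' deconvolution); a programmed fraction of tumour nuclei carry DAB at the
#' peak OD of the programmed intensity bin. The returned ground truth carries
#' the label mask, the nucleus inventory and the realised percent-positive.
#'
#' @param config A [synthetic_spot_config()].
#' @param stains A [stain_model()].
#' @return List with components `image` (a [spot_image()]) and `truth`, a
#'   `ground_truth` list: `mask` ([label_mask()]), `nuclei` (data.frame with
#'   `row`, `col`, `compartment`, `is_positive`, `dab_od`),
#'   `percent_positive_tumour`, and `config` (the echoed configuration).
#' @examples
#' sp <- generate_spot(synthetic_spot_config(diameter_px = 200, seed = 3))
#' sp$truth$percent_positive_tumour
#' @export
generate_spot <- function(config = synthetic_spot_config(),
                          stains = stain_model()) {
  stopifnot(inherits(config, "synthetic_spot_config"))
  with_rng(config$seed, {
    d <- config$diameter_px
    h <- d; w <- d
    ctr <- (d + 1) / 2
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    rad2 <- (rows - ctr)^2 + (cols - ctr)^2
    inside <- rad2 <= (d / 2)^2

    # --- tumour regions ---
    Tm <- matrix(FALSE, h, w)
    if (config$tumour_fraction > 0) {
      n <- config$n_tumour_regions
      ang <- runif(n, 0, 2 * pi)
      rr <- (d / 2) * 0.72 * sqrt(runif(n))
      centers <- cbind(ctr + rr * sin(ang), ctr + rr * cos(ang))
      scale_px <- 0.5 * (d / 2) / sqrt(n)
      f <- bump_field(h, w, centers, scale_px)
      Tm <- threshold_fraction(f, inside, config$tumour_fraction)
    }

    # --- sub-compartments of the non-tumour area (mask label stays N) ---
    Nm <- inside & !Tm
    frac_of_inside <- function(fr) fr * sum(inside) / max(1, sum(Nm))
    normal <- matrix(FALSE, h, w)
    lymph <- matrix(FALSE, h, w)
    if (sum(Nm) > 0) {
      fr_n <- min(1, frac_of_inside(config$compartment_fractions[["normal_epithelium"]]))
      if (fr_n > 0) {
        p <- Nm_center_points(Nm, 2L)
        normal <- threshold_fraction(bump_field(h, w, p, d / 8), Nm, fr_n)
      }
      rest <- Nm & !normal
      fr_l <- min(1, config$compartment_fractions[["lymphocyte"]] * sum(inside) /
                    max(1, sum(rest)))
      if (fr_l > 0 && sum(rest) > 0) {
        p <- Nm_center_points(rest, 3L)
        lymph <- threshold_fraction(bump_field(h, w, p, d / 12), rest, fr_l)
      }
    }
    stroma <- Nm & !normal & !lymph

    # --- nucleus placement ---
    px_mm2 <- (config$pixel_size_um / 1000)^2
    comp_masks <- list(tumour = Tm, normal_epithelium = normal,
                       lymphocyte = lymph, stroma_cell = stroma)
    nuclei <- list()
    for (comp in names(comp_masks)) {
      cm <- comp_masks[[comp]]
      area <- sum(cm) * px_mm2
      n <- round(config$nucleus_density_per_mm2[[comp]] * area)
      if (n == 0) next
      rad_px <- config$nucleus_radius_um[[comp]] / config$pixel_size_um
      allowed <- erode_disc(cm, 2 * rad_px + 1)
      if (!any(allowed)) allowed <- cm
      pts <- place_nuclei(allowed, n, config$min_separation_factor * rad_px, comp)
      nuclei[[comp]] <- data.frame(row = pts[, 1], col = pts[, 2],
                                   compartment = comp,
                                   stringsAsFactors = FALSE)
    }
    nuc <- do.call(rbind, nuclei)
    if (is.null(nuc)) {
      nuc <- data.frame(row = numeric(0), col = numeric(0),
                        compartment = character(0), stringsAsFactors = FALSE)
    }
    rownames(nuc) <- NULL

    # --- ER positivity of tumour nuclei ---
    tum_idx <- which(nuc$compartment == "tumour")
    n_tum <- length(tum_idx)
    n_pos <- round(config$programmed_percent_positive / 100 * n_tum)
    nuc$is_positive <- FALSE
    if (n_pos > 0) {
      nuc$is_positive[sample(tum_idx, n_pos)] <- TRUE
    }
    nuc$dab_od <- ifelse(nuc$is_positive,
                         config$intensity_bin_peak_od[config$programmed_intensity_bin + 1L],
                         0)

    # --- OD maps ---
    sigma_px <- config$texture_sigma_um / config$pixel_size_um
    tex <- gauss_smooth(matrix(rnorm(h * w), h, w), sigma_px)
    tex <- tex / max(sd(tex), .Machine$double.eps)
    haem <- 0.04 + config$texture_amplitude * tex
    haem[haem < 0] <- 0
    haem[Tm] <- haem[Tm] + config$tumour_haem_offset
    dab <- matrix(0, h, w)
    if (nrow(nuc) > 0) {
      rad_all <- config$nucleus_radius_um[nuc$compartment] / config$pixel_size_um
      ratio <- runif(nrow(nuc), 0.85, 1.2)
      angle <- runif(nrow(nuc), 0, pi)
      haem_peak <- ifelse(nuc$is_positive, config$positive_nucleus_haem_od,
                          config$nucleus_haem_od)
      haem_peak[nuc$compartment == "lymphocyte"] <- config$nucleus_haem_od * 1.25
      for (i in seq_len(nrow(nuc))) {
        haem <- add_nucleus_profile(haem, nuc$row[i], nuc$col[i], rad_all[i],
                                    haem_peak[i], ratio[i], angle[i])
        if (nuc$dab_od[i] > 0) {
          dab <- add_nucleus_profile(dab, nuc$row[i], nuc$col[i], rad_all[i],
                                     nuc$dab_od[i], ratio[i], angle[i])
        }
      }
    }

    # --- render, add noise, blank the exterior ---
    img <- render_stains(haem, dab, stains)
    if (config$noise_sd > 0) {
      for (c in 1:3) {
        img[, , c] <- pmin(255L, pmax(0L, as.integer(round(
          img[, , c] + rnorm(h * w, sd = config$noise_sd)))))
      }
    }
    for (c in 1:3) {
      plane <- img[, , c]
      plane[!inside] <- as.integer(stains$background_rgb[c])
      img[, , c] <- plane
    }

    mask <- matrix(LABEL_OUTSIDE, h, w)
    mask[inside] <- LABEL_N
    mask[Tm] <- LABEL_T

    truth <- structure(list(
      mask = label_mask(mask),
      nuclei = nuc,
      percent_positive_tumour = if (n_tum > 0) 100 * n_pos / n_tum else 0,
      config = config
    ), class = "ground_truth")
    list(image = spot_image(img, config$pixel_size_um, inside), truth = truth)
  })
}

# Pick k rough centre points within a region for placing sub-compartments.
Nm_center_points <- function(region, k) {
  idx <- which(region)
  pick <- sample(idx, min(k, length(idx)))
  h <- nrow(region)
  cbind(((pick - 1L) %% h) + 1L, ((pick - 1L) %/% h) + 1L)
}
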