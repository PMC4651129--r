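#' Compute SLIC-style superpixels of a spot image
#'
#' Groups pixels into compact, visually homogeneous regions by localized
#' k-means in colour + position space (the SLIC algorithm), so boundaries of
#' cellular compartments tend to coincide with superpixel boundaries.
#' Clustering is restricted to the valid spot region; exterior pixels get id
#' -1. A connectivity pass reassigns stray fragments so every id is one
#' connected region. The procedure is deterministic: seeds are a fixed grid
#' and iteration count is fixed.
#'
#' @param image A [spot_image()].
#' @param region_size_px Nominal superpixel spacing (grid step) in pixels;
#'   mean superpixel area is close to `region_size_px^2`.
#' @param compactness Trade-off between colour fidelity and spatial
#'   regularity, on the 0-255 colour scale; larger values give squarer
#'   superpixels. 10 is a conventional default for 8-bit images.
#' @param iterations Number of assignment/update sweeps.
#' @return Object of class `superpixel_map`: list with `ids` (integer matrix,
#'   1..K inside the spot, -1 outside), `n` (number of superpixels) and
#'   `region_size_px`.
#' @export
compute_superpixels <- function(image, region_size_px = 16, compactness = 10,
                                iterations = 10) {
  stopifnot(inherits(image, "spot_image"), region_size_px >= 4)
  px <- image$pixels
  if (region_size_px > min(dim(px)[1:2])) {
    stop("region_size_px (", region_size_px, ") exceeds the spot extent")
  }
  ids <- .slic_cpp(matrix(as.numeric(px[, , 1]), dim(px)[1]),
                   matrix(as.numeric(px[, , 2]), dim(px)[1]),
                   matrix(as.numeric(px[, , 3]), dim(px)[1]),
                   image$inside_spot,
                   as.integer(region_size_px), as.numeric(compactness),
                   as.integer(iterations))
  structure(list(ids = ids, n = max(ids), region_size_px = region_size_px),
            class = "superpixel_map")
}

#' @export
print.superpixel_map <- function(x, ...) {
  cat(sprintf("superpixel_map: %d superpixels, nominal size %d px\n",
              x$n, as.integer(x$region_size_px)))
  invisible(x)
}

# Boundary pixels of a superpixel map: inside-spot pixels with a 4-neighbour
# of a different id.
superpixel_boundaries <- function(spmap) {
  ids <- spmap$ids
  h <- nrow(ids); w <- ncol(ids)
  b <- matrix(FALSE, h, w)
  b[-h, ] <- b[-h, ] | (ids[-h, ] != ids[-1, ])
  b[-1, ] <- b[-1, ] | (ids[-1, ] != ids[-h, ])
  b[, -w] <- b[, -w] | (ids[, -w] != ids[, -1])
  b[, -1] <- b[, -1] | (ids[, -1] != ids[, -w])
  b & ids > 0
}

#' Per-superpixel features with neighbour context
#'
#' Summarises each superpixel by colour (mean/sd of RGB and of deconvolved
#' haematoxylin/DAB OD), texture (mean/sd of Gaussian-derivative filter-bank
#' responses: gradient magnitude and Laplacian at two scales on the grey
#' image), shape (area, eccentricity, boundary compactness), and the mean of
#' the adjacent superpixels' colour/texture features over the region
#' adjacency graph. When a reference mask is supplied, each superpixel also
#' receives a training label: the majority T/N label of its pixels, with
#' exact ties resolved to N (never over-call tumour).
#'
#' @param image A [spot_image()].
#' @param spmap A `superpixel_map` from [compute_superpixels()].
#' @param reference_mask Optional [label_mask()] supplying training labels.
#' @param stains [stain_model()] used for OD features.
#' @return A data.frame, one row per superpixel id, with feature columns and
#'   (when a reference mask is given) a factor column `label` in `{N, T}`.
#' @export
extract_features <- function(image, spmap, reference_mask = NULL,
                             stains = stain_model()) {
  stopifnot(inherits(image, "spot_image"), inherits(spmap, "superpixel_map"))
  ids <- spmap$ids
  stopifnot(all(dim(ids) == dim(image$pixels)[1:2]))
  K <- spmap$n
  idv <- as.vector(ids)
  sel <- idv > 0
  gid <- idv[sel]
  n_px <- tabulate(gid, nbins = K)

  stat_pair <- function(v, prefix) {
    a <- rowsum(cbind(v, v * v), gid)
    g <- as.integer(rownames(a))
    s1 <- numeric(K); s2 <- numeric(K)
    s1[g] <- a[, 1]; s2[g] <- a[, 2]
    mn <- ifelse(n_px > 0, s1 / pmax(n_px, 1), 0)
    vv <- ifelse(n_px > 1, (s2 - n_px * mn^2) / pmax(n_px - 1, 1), 0)
    out <- data.frame(mn = mn, sd = sqrt(pmax(vv, 0)))
    names(out) <- paste0(prefix, c("_mean", "_sd"))
    out
  }

  od <- colour_deconvolve(image, stains)
  grey <- (as.numeric(image$pixels[, , 1]) + as.numeric(image$pixels[, , 2]) +
           as.numeric(image$pixels[, , 3])) / (3 * 255)
  grey <- matrix(grey, nrow(ids), ncol(ids))

  planes <- list(
    r = as.numeric(image$pixels[, , 1])[sel],
    g = as.numeric(image$pixels[, , 2])[sel],
    b = as.numeric(image$pixels[, , 3])[sel],
    haem_od = as.vector(od$haematoxylin_od)[sel],
    dab_od = as.vector(od$dab_od)[sel]
  )
  for (s in c(1, 3)) { # two filter-bank scales (px)
    sm <- gauss_smooth(grey, s)
    gr <- grad_mag(sm)
    lap <- laplacian(sm)
    planes[[paste0("gradmag_s", s)]] <- as.vector(gr)[sel]
    planes[[paste0("laplace_s", s)]] <- as.vector(lap)[sel]
  }
  feat <- do.call(cbind, unname(Map(stat_pair, planes, names(planes))))

  # shape
  area <- as.numeric(n_px)
  mom <- EBImage::computeFeatures.moment(replace(ids, ids < 0, 0L))
  shp <- EBImage::computeFeatures.shape(replace(ids, ids < 0, 0L))
  ecc <- rep(0, K); per <- rep(0, K)
  ecc[seq_len(nrow(mom))] <- mom[, "m.eccentricity"]
  per[seq_len(nrow(shp))] <- shp[, "s.perimeter"]
  feat$area <- area
  feat$eccentricity <- ecc
  feat$compactness <- ifelse(area > 0, per^2 / (4 * pi * pmax(area, 1)), 0)

  # neighbour aggregates over the region adjacency graph
  adj <- adjacency_pairs(ids)
  nb_cols <- grep("_(mean|sd)$", names(feat), value = TRUE)
  deg <- tabulate(c(adj[, 1], adj[, 2]), nbins = K)
  for (cl in nb_cols) {
    v <- feat[[cl]]
    s <- numeric(K)
    s_acc <- tapply(c(v[adj[, 2]], v[adj[, 1]]), c(adj[, 1], adj[, 2]), sum)
    s[as.integer(names(s_acc))] <- as.numeric(s_acc)
    feat[[paste0("nb_", cl)]] <- ifelse(deg > 0, s / pmax(deg, 1), v)
  }

  feat$superpixel_id <- seq_len(K)
  if (!is.null(reference_mask)) {
    check_comparable_image(reference_mask, image)
    lab <- mask_matrix(reference_mask)[ids > 0]
    a <- rowsum(as.numeric(lab == LABEL_T), gid)
    nT <- numeric(K)
    nT[as.integer(rownames(a))] <- a[, 1]
    feat$label <- factor(ifelse(nT / pmax(n_px, 1) > 0.5, "T", "N"),
                         levels = c("N", "T"))
  }
  feat
}

check_comparable_image <- function(mask, image) {
  if (!all(dim(mask) == dim(image$pixels)[1:2])) {
    stop("mask and image shapes differ")
  }
  invisible(TRUE)
}

grad_mag <- function(x) {
  h <- nrow(x); w <- ncol(x)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gy[2:(h - 1), ] <- (x[3:h, ] - x[1:(h - 2), ]) / 2
  gx[, 2:(w - 1)] <- (x[, 3:w] - x[, 1:(w - 2)]) / 2
  sqrt(gx^2 + gy^2)
}

laplacian <- function(x) {
  h <- nrow(x); w <- ncol(x)
  l <- matrix(0, h, w)
  l[2:(h - 1), 2:(w - 1)] <-
    x[1:(h - 2), 2:(w - 1)] + x[3:h, 2:(w - 1)] +
    x[2:(h - 1), 1:(w - 2)] + x[2:(h - 1), 3:w] - 4 * x[2:(h - 1), 2:(w - 1)]
  l
}

# Unique adjacent (id, id) pairs under 4-connectivity, ids > 0.
adjacency_pairs <- function(ids) {
  h <- nrow(ids); w <- ncol(ids)
  p1 <- cbind(as.vector(ids[-h, ]), as.vector(ids[-1, ]))
  p2 <- cbind(as.vector(ids[, -w]), as.vector(ids[, -1]))
  p <- rbind(p1, p2)
  p <- p[p[, 1] > 0 & p[, 2] > 0 & p[, 1] != p[, 2], , drop = FALSE]
  p <- cbind(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2]))
  unique(p)
}
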