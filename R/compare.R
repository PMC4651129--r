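# Disagreement-map class codes
DIS_OUTSIDE <- 0L
DIS_AGREE_N <- 1L
DIS_AGREE_T <- 2L
DIS_TYPE1 <- 3L
DIS_TYPE2 <- 4L
DIS_TYPE3 <- 5L

#' Pixel-level contingency table of two label masks
#'
#' Counts, over in-spot pixels only, the four possible label pairs when
#' comparing a pixel's labels in two masks: (T,T), (T,N), (N,T), (N,N), where
#' the first element comes from `maskA`. A normalised view (dividing by the
#' in-spot total) is included; its entries sum to 1.
#'
#' @param maskA,maskB [label_mask()] objects of identical shape and identical
#'   OUTSIDE sets (the spot perimeters must agree).
#' @return Object of class `contingency_2x2`: list with `counts` and
#'   `normalized`, both 2x2 matrices with rows = `maskA` label (T, N) and
#'   columns = `maskB` label.
#' @export
pixel_contingency <- function(maskA, maskB) {
  check_comparable(maskA, maskB)
  a <- mask_matrix(maskA); b <- mask_matrix(maskB)
  ins <- a != LABEL_OUTSIDE
  av <- a[ins]; bv <- b[ins]
  counts <- matrix(c(sum(av == LABEL_T & bv == LABEL_T),
                     sum(av == LABEL_T & bv == LABEL_N),
                     sum(av == LABEL_N & bv == LABEL_T),
                     sum(av == LABEL_N & bv == LABEL_N)),
                   2, 2, byrow = TRUE,
                   dimnames = list(maskA = c("T", "N"), maskB = c("T", "N")))
  contingency_2x2(counts)
}

#' Build a 2x2 contingency object from counts or normalised proportions
#'
#' @param counts 2x2 numeric matrix, rows = first source (T, N), columns =
#'   second source.
#' @return Object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(counts) {
  stopifnot(is.matrix(counts), all(dim(counts) == c(2, 2)), all(counts >= 0))
  tot <- sum(counts)
  if (tot <= 0) stop("contingency table is empty")
  if (is.null(dimnames(counts))) {
    dimnames(counts) <- list(maskA = c("T", "N"), maskB = c("T", "N"))
  }
  structure(list(counts = counts, normalized = counts / tot),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat("contingency_2x2 (normalized):\n")
  print(round(x$normalized, 3))
  invisible(x)
}

#' Classify pixel-level mask disagreements into three types
#'
#' Applies, in order, the three-type taxonomy of segmentation-mask
#' disagreements:
#'
#' 1. **Type 1** -- thin boundary-offset disagreements: strips where the two
#'    boundaries are separated by only a few pixels, too small to include or
#'    exclude an entire epithelial cell. Operationally: the disagreement
#'    pixels removed by a morphological opening of the disagreement raster
#'    with a disc of diameter `cell_diameter_px` (a strip that cannot
#'    contain the disc cannot contain a cell).
#' 2. **Type 2** -- extent disagreements: a remaining disagreement pixel is
#'    labelled T in exactly one mask; it is Type 2 iff the connected
#'    T component (8-connectivity) containing it in that mask overlaps (shares
#'    at least one pixel with) a T region of the other mask.
#' 3. **Type 3** -- everything else: presence/absence disagreements about
#'    whole regions.
#'
#' @param maskA,maskB Comparable [label_mask()] objects.
#' @param cell_diameter_px Positive integer: minimum epithelial cell diameter
#'   in pixels (the default elsewhere in the package derives from 8 microns
#'   at the image's pixel size).
#' @return Object of class `disagreement_map`: list with `map` (integer
#'   matrix of classes OUTSIDE/AGREE_N/AGREE_T/TYPE1/TYPE2/TYPE3),
#'   `cell_diameter_px`, and `counts` (named vector of the three type counts).
#' @export
classify_disagreements <- function(maskA, maskB, cell_diameter_px) {
  check_comparable(maskA, maskB)
  stopifnot(cell_diameter_px >= 1)
  a <- mask_matrix(maskA); b <- mask_matrix(maskB)
  ins <- a != LABEL_OUTSIDE
  D <- ins & (a != b)

  out <- matrix(DIS_OUTSIDE, nrow(a), ncol(a))
  out[ins & a == LABEL_N & b == LABEL_N] <- DIS_AGREE_N
  out[ins & a == LABEL_T & b == LABEL_T] <- DIS_AGREE_T

  if (any(D)) {
    opened <- open_disc(D, cell_diameter_px)
    type1 <- D & !opened
    rest <- D & opened
    if (any(rest)) {
      type2 <- matrix(FALSE, nrow(a), ncol(a))
      for (m in list(list(own = a, other = b), list(own = b, other = a))) {
        ownT <- m$own == LABEL_T
        comp <- label_components(ownT, 8L)
        overlap_ids <- unique(comp[comp > 0 & m$other == LABEL_T])
        hit <- comp > 0 & matrix(comp %in% overlap_ids, nrow(a), ncol(a))
        # disagreement pixels that are T in this mask only
        type2 <- type2 | (rest & ownT & m$other != LABEL_T & hit)
      }
      out[rest & type2] <- DIS_TYPE2
      out[rest & !type2] <- DIS_TYPE3
    }
    out[type1] <- DIS_TYPE1
  }
  structure(list(map = out, cell_diameter_px = as.integer(cell_diameter_px),
                 counts = c(type1 = sum(out == DIS_TYPE1),
                            type2 = sum(out == DIS_TYPE2),
                            type3 = sum(out == DIS_TYPE3))),
            class = "disagreement_map")
}

#' @export
print.disagreement_map <- function(x, ...) {
  cat("disagreement_map (cell diameter", x$cell_diameter_px, "px):\n")
  print(x$counts)
  invisible(x)
}

#' Summarise disagreement maps over a cohort of spots
#'
#' For each spot, the proportion of its disagreement pixels in each type
#' (summing to 1 when any disagreement exists); cohort statistics are the
#' unweighted mean and sd of these per-spot proportions. Spots with zero
#' disagreement pixels are excluded from the cohort statistics (with a
#' message).
#'
#' @param maps List of `disagreement_map` objects.
#' @return List with `per_spot` (data.frame: spot, n_disagree, type1..type3
#'   proportions), `mean` and `sd` (named length-3 vectors over included
#'   spots), and `n_excluded`.
#' @export
summarise_disagreements <- function(maps) {
  stopifnot(length(maps) >= 1,
            all(vapply(maps, inherits, TRUE, "disagreement_map")))
  per <- do.call(rbind, lapply(seq_along(maps), function(i) {
    ct <- maps[[i]]$counts
    n <- sum(ct)
    data.frame(spot = i, n_disagree = n,
               type1 = if (n > 0) ct[["type1"]] / n else NA_real_,
               type2 = if (n > 0) ct[["type2"]] / n else NA_real_,
               type3 = if (n > 0) ct[["type3"]] / n else NA_real_)
  }))
  ok <- per$n_disagree > 0
  if (any(!ok)) {
    message(sum(!ok), " spot(s) with zero disagreement pixels excluded from cohort statistics")
  }
  m <- colMeans(per[ok, c("type1", "type2", "type3"), drop = FALSE])
  s <- vapply(per[ok, c("type1", "type2", "type3"), drop = FALSE], sd, 0)
  list(per_spot = per, mean = m, sd = s, n_excluded = sum(!ok))
}

#' Render a colour-coded difference image
#'
#' Type 1 disagreements are drawn red, Type 2 green, Type 3 blue; agreement
#' pixels show the background image (if supplied) or neutral grey; OUTSIDE is
#' black.
#'
#' @param dmap A `disagreement_map`.
#' @param background Optional [spot_image()] of the same shape.
#' @return H x W x 3 integer array in `[0, 255]`.
#' @export
render_difference_image <- function(dmap, background = NULL) {
  stopifnot(inherits(dmap, "disagreement_map"))
  m <- dmap$map
  h <- nrow(m); w <- ncol(m)
  if (!is.null(background)) {
    stopifnot(inherits(background, "spot_image"),
              all(dim(background$pixels)[1:2] == dim(m)))
    out <- background$pixels
  } else {
    out <- array(200L, c(h, w, 3L))
  }
  cols <- list(c(255L, 0L, 0L), c(0L, 255L, 0L), c(0L, 0L, 255L))
  codes <- c(DIS_TYPE1, DIS_TYPE2, DIS_TYPE3)
  for (i in 1:3) {
    sel <- m == codes[i]
    for (c in 1:3) {
      plane <- out[, , c]
      plane[sel] <- cols[[i]][c]
      out[, , c] <- plane
    }
  }
  for (c in 1:3) {
    plane <- out[, , c]
    plane[m == DIS_OUTSIDE] <- 0L
    out[, , c] <- plane
  }
  storage.mode(out) <- "integer"
  out
}
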