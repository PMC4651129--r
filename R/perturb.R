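#' Perturb a label mask to emulate annotator variation
#'
#' Produces a plausibly different segmentation of the same spot, emulating
#' the ways two pathologists' hand-drawn tumour masks differ:
#'
#' * `boundary_jitter` displaces T/N boundaries locally by at most
#'   `magnitude_px`, via a smooth random field added to the signed distance
#'   from the tumour boundary. With magnitudes below a cell diameter this
#'   manufactures thin, type-1-style disagreement strips.
#' * `region_resize` dilates or erodes whole tumour components (random
#'   choice per component) by `magnitude_px`, emulating differences of
#'   opinion about the spatial extent of a tumour region (type 2).
#' * `component_flip` adds a new tumour component of diameter
#'   `magnitude_px`, or deletes an existing one, emulating disagreement about
#'   whether a group of cells is malignant at all (type 3).
#'
#' OUTSIDE pixels are never altered.
#'
#' @param mask A [label_mask()].
#' @param mode One of `"boundary_jitter"`, `"region_resize"`,
#'   `"component_flip"`.
#' @param magnitude_px Positive integer magnitude in pixels (displacement,
#'   resize radius, or added/deleted component diameter).
#' @param seed Integer seed; identical arguments give identical output.
#' @param direction For `component_flip`: `"add"`, `"delete"` or `"random"`.
#' @return A [label_mask()] of the same shape.
#' @export
perturb_mask <- function(mask, mode = c("boundary_jitter", "region_resize",
                                        "component_flip"),
                         magnitude_px, seed,
                         direction = c("random", "add", "delete")) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  stopifnot(inherits(mask, "label_mask"), magnitude_px >= 1)
  magnitude_px <- as.integer(round(magnitude_px))
  m <- mask_matrix(mask)
  inside <- m != LABEL_OUTSIDE
  Tm <- m == LABEL_T
  if (!any(Tm) && mode %in% c("region_resize")) {
    stop("mask has no T pixels; cannot ", mode)
  }
  if (!any(Tm) && mode == "component_flip" && direction == "delete") {
    stop("mask has no T pixels; cannot delete a component")
  }

  with_rng(seed, {
    newT <- switch(mode,
      boundary_jitter = {
        if (!any(Tm) || !any(inside & !Tm)) {
          Tm # no boundary to move
        } else {
          signed <- dist_to_background(Tm) - dist_to_background(!Tm)
          f <- gauss_smooth(matrix(rnorm(length(m)), nrow(m), ncol(m)),
                            max(4, magnitude_px))
          f <- f / max(sd(f), .Machine$double.eps) * (magnitude_px / 2)
          f <- pmin(magnitude_px, pmax(-magnitude_px, f))
          (signed + f) > 0
        }
      },
      region_resize = {
        comp <- label_components(Tm, 8L)
        out <- matrix(FALSE, nrow(m), ncol(m))
        for (k in seq_len(max(comp))) {
          ck <- comp == k
          grow <- runif(1) < 0.5
          ck2 <- if (grow) dilate_disc(ck, 2L * magnitude_px + 1L)
                 else erode_disc(ck, 2L * magnitude_px + 1L)
          if (!any(ck2)) ck2 <- ck # never let resizing delete a component
          out <- out | ck2
        }
        out
      },
      component_flip = {
        if (direction == "random") {
          direction <- if (any(Tm) && runif(1) < 0.5) "delete" else "add"
        }
        if (direction == "add") {
          rad <- max(1, magnitude_px / 2)
          clearance <- dist_to_background(inside & !Tm)
          ok <- clearance > rad + 1
          if (!any(ok)) {
            stop("no room to add a T component of diameter ", magnitude_px)
          }
          p <- sample(which(ok), 1L)
          r0 <- ((p - 1L) %% nrow(m)) + 1L
          c0 <- ((p - 1L) %/% nrow(m)) + 1L
          rows <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
          cols <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE)
          Tm | ((rows - r0)^2 + (cols - c0)^2 <= rad^2)
        } else {
          comp <- label_components(Tm, 8L)
          sizes <- tabulate(comp[comp > 0])
          diam <- 2 * sqrt(sizes / pi)
          cand <- which(diam >= magnitude_px)
          k <- if (length(cand) > 0) sample(rep(cand, 2L), 1L) else which.max(sizes)
          out <- Tm
          out[comp == k] <- FALSE
          out
        }
      }
    )
    newT <- newT & inside
    res <- m
    res[inside] <- LABEL_N
    res[newT] <- LABEL_T
    label_mask(res)
  })
}
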