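#' Read and write label masks as 8-bit PNG
#'
#' Masks use the fixed encoding 0 = OUTSIDE, 1 = N, 2 = T stored as raw
#' 8-bit grey values, so round-trips are bit-exact. Files containing any
#' other value are rejected with the offending values listed.
#'
#' @param mask A [label_mask()].
#' @param path Output/input file path.
#' @return `write_mask` invisibly returns `path`; `read_mask` returns a
#'   [label_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  png::writePNG(mask_matrix(mask) / 255, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  v <- as.integer(round(m * 255))
  bad <- setdiff(unique(v), c(0L, 1L, 2L))
  if (length(bad) > 0) {
    stop("mask file contains invalid label values: ", paste(bad, collapse = ", "))
  }
  label_mask(matrix(v, nrow(m), ncol(m)))
}

#' Read and write spot images (8-bit RGB PNG or TIFF)
#'
#' The format is chosen from the file extension (`.png`, `.tif`/`.tiff`).
#' The pixel size and validity region are not stored in the raster; supply
#' them when reading (the validity region defaults to the inscribed disc,
#' matching how spot perimeters are delineated).
#'
#' @param image A [spot_image()] (for writing).
#' @param path File path.
#' @param pixel_size_um Pixel size to attach on read.
#' @param inside_spot Optional logical matrix; default is the inscribed disc.
#' @return `write_image` invisibly returns `path`; `read_image` a
#'   [spot_image()].
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "spot_image"))
  arr <- image$pixels / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(arr, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  } else {
    stop("unsupported image format: .", ext)
  }
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path, pixel_size_um = 1, inside_spot = NULL) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format: .", ext)
  }
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3), c(dim(arr), 3L))
  arr <- arr[, , 1:3, drop = FALSE]
  px <- array(as.integer(round(arr * 255)), dim(arr))
  if (is.null(inside_spot)) {
    h <- dim(px)[1]; w <- dim(px)[2]
    ctr_r <- (h + 1) / 2; ctr_c <- (w + 1) / 2
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    inside_spot <- (rows - ctr_r)^2 + (cols - ctr_c)^2 <= (min(h, w) / 2)^2
  }
  spot_image(px, pixel_size_um, inside_spot)
}

score_csv_columns <- c("spot_id", "mask_source", "n_nuclei", "percent_positive",
                       "intensity", "allred_prop", "allred_total",
                       "qs_prop", "qs_total", "er_allred", "er_qs")

#' Read and write per-spot score tables as CSV
#'
#' One row per (spot, mask source) with the fixed column set `spot_id`,
#' `mask_source`, `n_nuclei`, `percent_positive`, `intensity`,
#' `allred_prop`, `allred_total`, `qs_prop`, `qs_total`, `er_allred`,
#' `er_qs`. A file with a missing column is rejected, naming the column.
#'
#' @param scores data.frame with the columns above.
#' @param path CSV file path.
#' @return `write_scores` invisibly returns `path`; `read_scores` the
#'   data.frame.
#' @export
write_scores <- function(scores, path) {
  miss <- setdiff(score_csv_columns, names(scores))
  if (length(miss) > 0) {
    stop("score table missing column(s): ", paste(miss, collapse = ", "))
  }
  write.csv(scores[, score_csv_columns], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(score_csv_columns, names(df))
  if (length(miss) > 0) {
    stop("score file missing column(s): ", paste(miss, collapse = ", "))
  }
  df
}

# One score row in the CSV schema.
score_row <- function(spot_id, source, sc) {
  data.frame(spot_id = spot_id, mask_source = source, n_nuclei = sc$n_nuclei,
             percent_positive = sc$percent_positive,
             intensity = sc$intensity_score, allred_prop = sc$allred_proportion,
             allred_total = sc$allred_total, qs_prop = sc$quickscore_proportion,
             qs_total = sc$quickscore_total, er_allred = sc$er_status_allred,
             er_qs = sc$er_status_quickscore, stringsAsFactors = FALSE)
}

#' Write and read synthetic ground truth
#'
#' The nucleus inventory is written as CSV (`row`, `col`, `compartment`,
#' `is_positive`, `dab_od`) and the generator configuration as a JSON
#' sidecar next to it (same path with extension `.json`).
#'
#' @param truth A `ground_truth` object from [generate_spot()].
#' @param path CSV file path; the JSON sidecar replaces its extension.
#' @return `write_ground_truth` invisibly returns the two paths;
#'   `read_ground_truth_nuclei` the nucleus data.frame.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  write.csv(truth$nuclei[, c("row", "col", "compartment", "is_positive",
                             "dab_od")], path, row.names = FALSE)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  cfg <- unclass(truth$config)
  cfg$percent_positive_tumour <- truth$percent_positive_tumour
  jsonlite::write_json(cfg, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(path, sidecar))
}

#' @rdname write_ground_truth
#' @export
read_ground_truth_nuclei <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("row", "col", "compartment", "is_positive", "dab_od")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("ground-truth file missing column(s): ", paste(miss, collapse = ", "))
  }
  df
}
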