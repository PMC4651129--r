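#' Train a superpixel tumour classifier
#'
#' Fits a random forest to labelled superpixel feature tables (one table per
#' training spot, from [extract_features()] with a reference mask). The
#' feature schema (ordered column names) is hashed into the model so that
#' prediction-time tables are checked for compatibility, and the annotator
#' whose masks supplied the labels is recorded.
#'
#' @param features A single data.frame or a list of data.frames with a
#'   `label` column as produced by [extract_features()].
#' @param annotator_tag Short text naming the annotation source (e.g. "A").
#' @param seed Integer seed for the forest.
#' @param ntree Number of trees.
#' @return Object of class `segmenter_model`.
#' @export
train_segmenter <- function(features, annotator_tag = "A", seed = 1L,
                            ntree = 200) {
  if (is.data.frame(features)) features <- list(features)
  stopifnot(length(features) >= 1, all(vapply(features, is.data.frame, TRUE)))
  tab <- do.call(rbind, features)
  if (is.null(tab$label)) {
    stop("training tables must carry a 'label' column (supply a reference mask)")
  }
  present <- levels(droplevels(tab$label))
  if (length(unique(as.character(tab$label))) < 2) {
    missing <- setdiff(c("N", "T"), unique(as.character(tab$label)))
    stop("training data contains a single class; missing class: ",
         paste(missing, collapse = ", "))
  }
  xcols <- feature_columns(tab)
  x <- tab[, xcols, drop = FALSE]
  y <- factor(as.character(tab$label), levels = c("N", "T"))
  fit <- with_rng(seed, randomForest::randomForest(x = x, y = y, ntree = ntree))
  structure(list(fit = fit, feature_schema = xcols,
                 schema_hash = schema_hash(xcols),
                 annotator_tag = annotator_tag, seed = as.integer(seed)),
            class = "segmenter_model")
}

feature_columns <- function(tab) {
  setdiff(names(tab), c("label", "superpixel_id", "spot_id"))
}

schema_hash <- function(cols) {
  # order-sensitive 32-bit polynomial hash of the schema string
  s <- utf8ToInt(paste(cols, collapse = "\x1f"))
  h <- 0
  for (v in s) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' @export
print.segmenter_model <- function(x, ...) {
  cat(sprintf("segmenter_model: %d features, annotator '%s', schema %s\n",
              length(x$feature_schema), x$annotator_tag, x$schema_hash))
  invisible(x)
}

# Predict per-superpixel tumour scores for a feature table.
predict_superpixels <- function(model, features) {
  stopifnot(inherits(model, "segmenter_model"))
  xcols <- feature_columns(features)
  if (!identical(schema_hash(xcols), model$schema_hash)) {
    stop("feature schema does not match the model (hash mismatch)")
  }
  p <- predict(model$fit, features[, xcols, drop = FALSE], type = "prob")
  p[, "T"]
}

#' Predict a tumour mask for a spot
#'
#' Segments the image into superpixels, extracts features, scores each
#' superpixel with the trained classifier, and paints every pixel with its
#' superpixel's class. The decision rule is score >= 0.5 for T; exact ties
#' fall to N so tumour is never over-called. OUTSIDE pixels are preserved.
#'
#' @param image A [spot_image()].
#' @param model A `segmenter_model` from [train_segmenter()].
#' @param region_size_px,compactness Superpixel parameters; use the values
#'   the training features were built with.
#' @param stains [stain_model()] for OD features.
#' @param min_component_px Optional post-processing: predicted T components
#'   smaller than this many pixels are reverted to N (0 disables, the
#'   default).
#' @return A [label_mask()].
#' @export
predict_mask <- function(image, model, region_size_px = 16, compactness = 10,
                         stains = stain_model(), min_component_px = 0) {
  spmap <- compute_superpixels(image, region_size_px, compactness)
  feats <- extract_features(image, spmap, reference_mask = NULL, stains = stains)
  score <- predict_superpixels(model, feats)
  isT <- score > 0.5 # an exact 0.5 tie falls to N
  lab <- matrix(LABEL_OUTSIDE, nrow(spmap$ids), ncol(spmap$ids))
  ins <- spmap$ids > 0
  lab[ins] <- ifelse(isT[spmap$ids[ins]], LABEL_T, LABEL_N)
  if (min_component_px > 0) {
    comp <- label_components(lab == LABEL_T, 8L)
    sizes <- tabulate(comp[comp > 0])
    drop <- which(sizes < min_component_px)
    lab[comp %in% drop] <- LABEL_N
  }
  label_mask(lab)
}

# Seeded spot-level fold assignment: shuffle, then contiguous blocks.
assign_folds <- function(n, k, seed) {
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k (", k, ") exceeds number of spots (", n, ")")
  with_rng(seed, {
    ord <- sample.int(n)
    f <- integer(n)
    f[ord] <- sort(rep_len(seq_len(k), n))
    f
  })
}

#' Spot-level k-fold cross-validation of the segmenter
#'
#' Partitions spots into `k` folds (seeded shuffle, then contiguous blocks)
#' and predicts each spot's mask with a model trained only on the other
#' folds' spots, so no superpixel of a test spot ever contributes to its own
#' model. This is the spot-level design used to evaluate automated
#' segmentation against an annotator's masks.
#'
#' @param spots List of `list(image =, mask =)` pairs; `mask` is the
#'   annotator's [label_mask()] used for training labels and evaluation.
#' @param k Number of folds (default 8).
#' @param seed Integer seed controlling fold assignment and forest seeds.
#' @param annotator_tag Annotation source tag stored in each fold's model.
#' @param region_size_px,compactness,stains,ntree,min_component_px Passed to
#'   the feature/classifier stages.
#' @return List with `masks` (predicted [label_mask()] per spot), `folds`
#'   (fold id per spot), and `report`: per-fold data.frame with pixel
#'   agreement of prediction vs the annotator masks.
#' @export
cross_validate <- function(spots, k = 8, seed = 1L, annotator_tag = "A",
                           region_size_px = 16, compactness = 10,
                           stains = stain_model(), ntree = 200,
                           min_component_px = 0) {
  n <- length(spots)
  folds <- assign_folds(n, k, seed)

  # features are computed once per spot and reused across folds
  spmaps <- lapply(spots, function(s)
    compute_superpixels(s$image, region_size_px, compactness))
  feats <- Map(function(s, sp)
    extract_features(s$image, sp, reference_mask = s$mask, stains = stains),
    spots, spmaps)

  masks <- vector("list", n)
  report <- data.frame(fold = seq_len(k), n_train_spots = NA_integer_,
                       n_test_spots = NA_integer_, pixel_agreement = NA_real_)
  for (fold in seq_len(k)) {
    test <- which(folds == fold)
    train <- which(folds != fold)
    model <- train_segmenter(feats[train], annotator_tag = annotator_tag,
                             seed = seed + fold, ntree = ntree)
    agr <- numeric(length(test))
    for (t in seq_along(test)) {
      i <- test[t]
      score <- predict_superpixels(model, feats[[i]])
      ids <- spmaps[[i]]$ids
      lab <- matrix(LABEL_OUTSIDE, nrow(ids), ncol(ids))
      ins <- ids > 0
      lab[ins] <- ifelse(score[ids[ins]] > 0.5, LABEL_T, LABEL_N)
      if (min_component_px > 0) {
        comp <- label_components(lab == LABEL_T, 8L)
        sizes <- tabulate(comp[comp > 0])
        lab[comp %in% which(sizes < min_component_px)] <- LABEL_N
      }
      masks[[i]] <- label_mask(lab)
      ref <- mask_matrix(spots[[i]]$mask)
      agr[t] <- mean(lab[ins] == ref[ins])
    }
    report$n_train_spots[fold] <- length(train)
    report$n_test_spots[fold] <- length(test)
    report$pixel_agreement[fold] <- mean(agr)
  }
  list(masks = masks, folds = folds, report = report)
}
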