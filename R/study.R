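#' Study configuration
#'
#' One JSON-serialisable document describing a full synthetic comparison
#' study: cohort size, generator settings, the programmed ER score profile
#' cycled over spots, simulated-annotator perturbations, segmentation,
#' comparison and scoring parameters, and the global seed.
#'
#' The two simulated annotators re-draw the ground-truth tumour mask the way
#' two pathologists would: annotator A applies a small boundary jitter;
#' annotator B applies jitter plus, with configured probabilities, a whole-
#' region resize or a component flip -- so synthetic inter-annotator
#' disagreement exhibits all three disagreement types.
#'
#' @param n_spots Cohort size.
#' @param seed Global seed; everything derives from it.
#' @param generator Named list of [synthetic_spot_config()] overrides shared
#'   by all spots (per-spot seed and programmed scores are managed by the
#'   study).
#' @param er_profiles List with numeric `percent` and integer `bin` of equal
#'   length: programmed (percent positive, intensity bin) pairs assigned to
#'   spots in rotation.
#' @param annotators Named list: `jitter_px` (annotator A and B boundary
#'   jitter), `resize_prob`, `resize_px`, `flip_prob`, `flip_px` (annotator B
#'   extras).
#' @param segmentation Named list: `region_size_px`, `compactness`, `k`,
#'   `ntree`, `min_component_px`.
#' @param comparison Named list: `cell_diameter_um`.
#' @param scoring Named list: `thresholds` (length 3), `allred_cutoff`,
#'   `quickscore_cutoff`.
#' @return Object of class `study_config` (a nested list).
#' @export
study_config <- function(n_spots = 16,
                         seed = 1L,
                         generator = list(),
                         er_profiles = list(
                           percent = c(0, 90, 50, 25, 5, 0.5, 60, 0),
                           bin = c(0L, 3L, 2L, 2L, 1L, 1L, 3L, 0L)),
                         annotators = list(jitter_px = 3, resize_prob = 0.5,
                                           resize_px = 5, flip_prob = 0.3,
                                           flip_px = 25),
                         segmentation = list(region_size_px = 16,
                                             compactness = 10, k = 8,
                                             ntree = 200,
                                             min_component_px = 0),
                         comparison = list(cell_diameter_um = 8),
                         scoring = list(thresholds = c(0.15, 0.40, 0.70),
                                        allred_cutoff = 2,
                                        quickscore_cutoff = 3)) {
  stopifnot(n_spots >= 1, length(er_profiles$percent) == length(er_profiles$bin),
            length(er_profiles$percent) >= 1)
  structure(list(n_spots = as.integer(n_spots), seed = as.integer(seed),
                 generator = generator,
                 er_profiles = list(percent = as.numeric(er_profiles$percent),
                                    bin = as.integer(er_profiles$bin)),
                 annotators = annotators, segmentation = segmentation,
                 comparison = comparison, scoring = scoring),
            class = "study_config")
}

#' Write / read a study configuration as JSON
#'
#' The JSON round-trip is lossless: `read_study_config(write_study_config(x))`
#' reproduces `x`.
#'
#' @param config A [study_config()].
#' @param path JSON file path.
#' @return `write_study_config` invisibly returns `path`;
#'   `read_study_config` a [study_config()].
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(study_config, raw)
}

source_pairs <- function() {
  list(c("manualA", "manualB"),
       c("autoA", "manualA"), c("autoA", "manualB"),
       c("autoB", "manualA"), c("autoB", "manualB"))
}

#' Run a full synthetic comparison study
#'
#' End-to-end pipeline: generate a seeded synthetic cohort; derive two
#' simulated-annotator mask sets from the ground truth; train and
#' cross-validate the automated segmenter on each annotator's masks (spot
#' -level folds); compare all mask-source pairs pixel-by-pixel and by the
#' three-type disagreement taxonomy; score every spot under every mask
#' source; and compute ordinal agreement statistics between sources.
#'
#' @param config A [study_config()].
#' @param return_masks Keep all mask rasters in the result (memory-heavy for
#'   large cohorts).
#' @param verbose Emit per-stage progress messages.
#' @return Object of class `study_report`: list with
#'   \describe{
#'     \item{contingency}{named list of pooled [contingency_2x2] per source
#'       pair.}
#'     \item{disagreement}{named list per pair: output of
#'       [summarise_disagreements()].}
#'     \item{scores}{data.frame, one row per spot x source (including
#'       `ground_truth`), in the score CSV schema.}
#'     \item{kappa}{data.frame of quadratic-weighted kappa per source pair
#'       and score component (intensity, Allred/Quickscore proportion and
#'       totals).}
#'     \item{er_concordance}{data.frame of ER-status agreement counts per
#'       pair and scoring system.}
#'     \item{bland_altman}{list of [bland_altman()] results for percent
#'       positive, auto vs manual.}
#'     \item{cv_reports}{per-annotator cross-validation fold reports.}
#'     \item{config}{the configuration echo.}
#'   }
#' @export
run_study <- function(config = study_config(), return_masks = FALSE,
                      verbose = TRUE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (verbose) message(...)
  n <- config$n_spots
  spot_seeds <- with_rng(config$seed, sample.int(1000000L, n))
  prof <- config$er_profiles
  np <- length(prof$percent)

  say("generating ", n, " synthetic spots")
  spots <- vector("list", n)
  for (i in seq_len(n)) {
    gen_args <- config$generator
    gen_args$seed <- spot_seeds[i]
    gen_args$programmed_percent_positive <- prof$percent[((i - 1) %% np) + 1]
    gen_args$programmed_intensity_bin <- prof$bin[((i - 1) %% np) + 1]
    spots[[i]] <- generate_spot(do.call(synthetic_spot_config, gen_args))
  }

  say("simulating two annotators")
  ann <- config$annotators
  manualA <- lapply(seq_len(n), function(i)
    perturb_mask(spots[[i]]$truth$mask, "boundary_jitter", ann$jitter_px,
                 seed = spot_seeds[i] + 1L))
  manualB <- lapply(seq_len(n), function(i) {
    m <- perturb_mask(spots[[i]]$truth$mask, "boundary_jitter", ann$jitter_px,
                      seed = spot_seeds[i] + 2L)
    with_rng(spot_seeds[i] + 3L, {
      if (runif(1) < ann$resize_prob && any(mask_matrix(m) == LABEL_T)) {
        m <- perturb_mask(m, "region_resize", ann$resize_px,
                          seed = spot_seeds[i] + 4L)
      }
      if (runif(1) < ann$flip_prob) {
        m <- perturb_mask(m, "component_flip", ann$flip_px,
                          seed = spot_seeds[i] + 5L)
      }
    })
    m
  })

  seg <- config$segmentation
  px_um <- spots[[1]]$image$pixel_size_um
  say("cross-validating segmenter trained on annotator A (k = ", seg$k, ")")
  cvA <- cross_validate(Map(function(s, m) list(image = s$image, mask = m),
                            spots, manualA),
                        k = seg$k, seed = config$seed + 101L,
                        annotator_tag = "A",
                        region_size_px = seg$region_size_px,
                        compactness = seg$compactness, ntree = seg$ntree,
                        min_component_px = seg$min_component_px)
  say("cross-validating segmenter trained on annotator B")
  cvB <- cross_validate(Map(function(s, m) list(image = s$image, mask = m),
                            spots, manualB),
                        k = seg$k, seed = config$seed + 202L,
                        annotator_tag = "B",
                        region_size_px = seg$region_size_px,
                        compactness = seg$compactness, ntree = seg$ntree,
                        min_component_px = seg$min_component_px)

  sources <- list(manualA = manualA, manualB = manualB,
                  autoA = cvA$masks, autoB = cvB$masks)

  say("comparing mask sources")
  cell_px <- max(1L, as.integer(round(config$comparison$cell_diameter_um / px_um)))
  contingency <- list()
  disagreement <- list()
  for (pr in source_pairs()) {
    key <- paste(pr, collapse = "_vs_")
    counts <- matrix(0, 2, 2, dimnames = list(maskA = c("T", "N"),
                                              maskB = c("T", "N")))
    maps <- vector("list", n)
    for (i in seq_len(n)) {
      ct <- pixel_contingency(sources[[pr[1]]][[i]], sources[[pr[2]]][[i]])
      counts <- counts + ct$counts
      maps[[i]] <- classify_disagreements(sources[[pr[1]]][[i]],
                                          sources[[pr[2]]][[i]], cell_px)
    }
    contingency[[key]] <- contingency_2x2(counts)
    disagreement[[key]] <- suppressMessages(summarise_disagreements(maps))
  }

  say("scoring spots under every mask source")
  sc <- config$scoring
  score_sources <- c(list(ground_truth = lapply(spots, function(s) s$truth$mask)),
                     sources)
  score_rows <- list()
  for (src in names(score_sources)) {
    for (i in seq_len(n)) {
      s <- score_tumour_mask(spots[[i]]$image, score_sources[[src]][[i]],
                             thresholds = sc$thresholds,
                             allred_cutoff = sc$allred_cutoff,
                             quickscore_cutoff = sc$quickscore_cutoff)
      score_rows[[length(score_rows) + 1L]] <- score_row(i, src, s)
    }
  }
  scores <- do.call(rbind, score_rows)

  say("computing agreement statistics")
  comp_levels <- list(intensity = 0:3, allred_prop = 0:5, qs_prop = 1:6,
                      allred_total = 0:8, qs_total = 1:9)
  kap <- list()
  er_rows <- list()
  for (pr in source_pairs()) {
    s1 <- scores[scores$mask_source == pr[1], ]
    s2 <- scores[scores$mask_source == pr[2], ]
    s1 <- s1[order(s1$spot_id), ]; s2 <- s2[order(s2$spot_id), ]
    for (cmp in names(comp_levels)) {
      conf <- ordinal_confusion(s1[[cmp]], s2[[cmp]], comp_levels[[cmp]])
      k <- weighted_kappa(conf, "quadratic")
      kap[[length(kap) + 1L]] <- data.frame(
        source_pair = paste(pr, collapse = "_vs_"), component = cmp,
        weighted_kappa = as.numeric(k),
        flag = attr(k, "reason") %||% "", stringsAsFactors = FALSE)
    }
    for (sys in c("er_allred", "er_qs")) {
      er_rows[[length(er_rows) + 1L]] <- data.frame(
        source_pair = paste(pr, collapse = "_vs_"), system = sys,
        n_agree = sum(s1[[sys]] == s2[[sys]]), n = nrow(s1),
        stringsAsFactors = FALSE)
    }
  }
  kappa <- do.call(rbind, kap)
  er_concordance <- do.call(rbind, er_rows)

  ba <- list()
  for (pr in list(c("autoA", "manualA"), c("autoB", "manualB"))) {
    s1 <- scores[scores$mask_source == pr[1], ]
    s2 <- scores[scores$mask_source == pr[2], ]
    s1 <- s1[order(s1$spot_id), ]; s2 <- s2[order(s2$spot_id), ]
    ba[[paste(pr, collapse = "_vs_")]] <-
      bland_altman(s1$percent_positive, s2$percent_positive)
  }

  structure(list(contingency = contingency, disagreement = disagreement,
                 scores = scores, kappa = kappa,
                 er_concordance = er_concordance, bland_altman = ba,
                 cv_reports = list(A = cvA$report, B = cvB$report),
                 masks = if (return_masks) sources else NULL,
                 truth = if (return_masks)
                   lapply(spots, function(s) s$truth) else NULL,
                 config = config),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report:", x$config$n_spots, "spots\n")
  cat("  mean CV pixel agreement (A, B): ",
      sprintf("%.3f", mean(x$cv_reports$A$pixel_agreement)), ", ",
      sprintf("%.3f", mean(x$cv_reports$B$pixel_agreement)), "\n", sep = "")
  at <- x$kappa[x$kappa$component == "allred_total", ]
  cat("  quadratic-weighted kappa, Allred totals:\n")
  for (i in seq_len(nrow(at))) {
    cat(sprintf("    %-20s %.3f\n", at$source_pair[i], at$weighted_kappa[i]))
  }
  invisible(x)
}

#' Write a study report to CSV files
#'
#' Emits `contingency.csv`, `disagreement_types.csv`, `scores.csv`,
#' `kappa.csv`, `er_concordance.csv` and `bland_altman.csv` under `dir`.
#' Output is deterministic: identical reports give byte-identical files.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- function(f) file.path(dir, f)

  ct <- do.call(rbind, lapply(names(report$contingency), function(key) {
    nm <- report$contingency[[key]]$normalized
    data.frame(source_pair = key, TT = nm[1, 1], TN = nm[1, 2],
               NT = nm[2, 1], NN = nm[2, 2], stringsAsFactors = FALSE)
  }))
  write.csv(ct, p("contingency.csv"), row.names = FALSE)

  dt <- do.call(rbind, lapply(names(report$disagreement), function(key) {
    d <- report$disagreement[[key]]
    cbind(data.frame(source_pair = key), d$per_spot)
  }))
  write.csv(dt, p("disagreement_types.csv"), row.names = FALSE)

  write_scores(report$scores, p("scores.csv"))
  write.csv(report$kappa, p("kappa.csv"), row.names = FALSE)
  write.csv(report$er_concordance, p("er_concordance.csv"), row.names = FALSE)

  bad <- do.call(rbind, lapply(names(report$bland_altman), function(key) {
    b <- report$bland_altman[[key]]
    data.frame(source_pair = key, n = b$n, bias = b$bias, sd_diff = b$sd_diff,
               loa_lower = b$loa_lower, loa_upper = b$loa_upper,
               stringsAsFactors = FALSE)
  }))
  write.csv(bad, p("bland_altman.csv"), row.names = FALSE)

  paths <- c(p("contingency.csv"), p("disagreement_types.csv"), p("scores.csv"),
             p("kappa.csv"), p("er_concordance.csv"), p("bland_altman.csv"))
  invisible(paths)
}
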