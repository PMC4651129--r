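# Shared fixtures, generated once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A mid-size synthetic spot used by most module tests.
fixture_spot <- function() {
  memo("spot300", generate_spot(synthetic_spot_config(diameter_px = 300, seed = 42)))
}

# A small cohort of trivially separable spots for segmenter tests.
fixture_cohort <- function(n = 4, diameter = 220) {
  memo(paste0("cohort", n, "_", diameter), {
    lapply(seq_len(n), function(i) {
      sp <- generate_spot(synthetic_spot_config(
        diameter_px = diameter, seed = 100 + i,
        programmed_percent_positive = c(50, 0, 90, 25)[((i - 1) %% 4) + 1],
        programmed_intensity_bin = c(2L, 0L, 3L, 1L)[((i - 1) %% 4) + 1]))
      list(image = sp$image, mask = sp$truth$mask, truth = sp$truth)
    })
  })
}

# A segmenter model trained on the fixture cohort's ground-truth masks.
fixture_model <- function() {
  memo("model", {
    cohort <- fixture_cohort()
    feats <- lapply(cohort, function(s) {
      spm <- compute_superpixels(s$image, 14, 10)
      extract_features(s$image, spm, s$mask)
    })
    train_segmenter(feats, annotator_tag = "GT", seed = 9, ntree = 100)
  })
}

# All-inside label mask from an integer matrix of 1s and 2s.
mk_mask <- function(m) {
  storage.mode(m) <- "integer"
  label_mask(m)
}

# Square all-N mask of side n.
blank_mask <- function(n) mk_mask(matrix(1L, n, n))

# Reference normalized pixel contingency blocks from a two-pathologist
# breast-TMA ER study (rows: source 1 label T/N; columns: source 2).
reference_pathologist_block <- function() {
  matrix(c(0.270, 0.049, 0.043, 0.638), 2, 2, byrow = TRUE,
         dimnames = list(c("T", "N"), c("T", "N")))
}

reference_auto_block <- function() {
  matrix(c(0.221, 0.097, 0.092, 0.591), 2, 2, byrow = TRUE,
         dimnames = list(c("T", "N"), c("T", "N")))
}
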