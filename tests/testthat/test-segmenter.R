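toy_features <- function(n = 40, sep = TRUE, seed = 1) {
  set.seed(seed)
  lab <- rep(c("N", "T"), each = n / 2)
  x1 <- ifelse(lab == "T", 5, -5) + rnorm(n, sd = if (sep) 0.1 else 10)
  data.frame(x1 = x1, x2 = rnorm(n),
             label = factor(lab, levels = c("N", "T")))
}

test_that("a separable toy problem is fit perfectly", {
  f <- toy_features()
  m <- train_segmenter(f, annotator_tag = "toy", seed = 4)
  p <- tmascore:::predict_superpixels(m, f)
  expect_identical(unname(p > 0.5), f$label == "T")
})

test_that("single-class training data is rejected naming the missing class", {
  f <- toy_features()
  expect_error(train_segmenter(f[f$label == "N", ], seed = 1),
               "missing class: T")
})

test_that("training is reproducible under a seed", {
  f <- toy_features(seed = 2)
  hold <- toy_features(n = 20, seed = 3)
  m1 <- train_segmenter(f, seed = 11)
  m2 <- train_segmenter(f, seed = 11)
  expect_identical(tmascore:::predict_superpixels(m1, hold),
                   tmascore:::predict_superpixels(m2, hold))
})

test_that("a feature schema mismatch is an error", {
  f <- toy_features()
  m <- train_segmenter(f, seed = 1)
  bad <- f
  names(bad)[1] <- "other"
  expect_error(tmascore:::predict_superpixels(m, bad), "schema")
})

test_that("predicted masks stay in the label codomain and preserve OUTSIDE", {
  sp <- fixture_spot()
  pred <- predict_mask(sp$image, fixture_model(), region_size_px = 14)
  m <- unclass(pred)
  expect_true(all(m %in% c(0L, 1L, 2L)))
  expect_identical(m == 0L, !sp$image$inside_spot)
  expect_identical(dim(m), dim(sp$image$pixels)[1:2])
})

test_that("a nucleus-free rendered background predicts as all non-tumour", {
  n <- 220
  set.seed(1)
  haem <- 0.04 + 0.05 * tmascore:::gauss_smooth(matrix(rnorm(n * n), n, n), 8)
  haem[haem < 0] <- 0
  img <- render_stains(haem, matrix(0, n, n))
  ctr <- (n + 1) / 2
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  si <- spot_image(img, 1, (rows - ctr)^2 + (cols - ctr)^2 <= (n / 2)^2)
  pred <- predict_mask(si, fixture_model(), region_size_px = 14)
  expect_true(all(unclass(pred)[si$inside_spot] == 1L))
})

test_that("fold assignment partitions spots evenly and reproducibly", {
  f <- tmascore:::assign_folds(32, 8, seed = 5)
  expect_identical(sort(unique(f)), 1:8)
  expect_true(all(tabulate(f, 8) == 4))
  expect_identical(f, tmascore:::assign_folds(32, 8, seed = 5))
  expect_false(identical(f, tmascore:::assign_folds(32, 8, seed = 6)))
  expect_error(tmascore:::assign_folds(4, 8, seed = 1), "exceeds")
  expect_error(tmascore:::assign_folds(4, 1, seed = 1), ">= 2")
})

test_that("two-fold cross-validation recovers easy ground truth", {
  cohort <- fixture_cohort()
  cv <- cross_validate(cohort, k = 2, seed = 21, region_size_px = 14,
                       ntree = 100)
  expect_identical(sort(unique(cv$folds)), 1:2)
  for (i in seq_along(cohort)) {
    m <- unclass(cv$masks[[i]])
    r <- unclass(cohort[[i]]$mask)
    ins <- r != 0L
    expect_gt(mean(m[ins] == r[ins]), 0.9)
    expect_identical(m == 0L, r == 0L)
  }
})
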