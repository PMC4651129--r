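test_that("deconvolution recovers a rendered DAB OD within 0.02", {
  sm <- stain_model()
  img <- render_stains(matrix(0, 3, 3), matrix(0.8, 3, 3), sm)
  od <- colour_deconvolve(img, sm)
  expect_lt(max(abs(od$dab_od - 0.8)), 0.02)
  expect_lt(max(od$haematoxylin_od), 0.02)
})

test_that("well-separated tumour nuclei are detected one-for-one", {
  for (seed in c(1, 2, 3)) {
    sp <- generate_spot(synthetic_spot_config(
      diameter_px = 300, seed = seed, tumour_fraction = 0.45,
      nucleus_density_per_mm2 = c(tumour = 900, normal_epithelium = 800,
                                  lymphocyte = 2000, stroma_cell = 300),
      min_separation_factor = 3.2, noise_sd = 1))
    od <- colour_deconvolve(sp$image)
    nuc <- detect_nuclei(od, sp$truth$mask, pixel_size_um = 1)
    n_true <- sum(sp$truth$nuclei$compartment == "tumour")
    expect_identical(nrow(nuc), as.integer(n_true))
  }
})

test_that("an all-N mask yields an empty nucleus table, not an error", {
  sp <- fixture_spot()
  m <- unclass(sp$truth$mask)
  m[m == 2L] <- 1L
  od <- colour_deconvolve(sp$image)
  nuc <- detect_nuclei(od, label_mask(m), pixel_size_um = 1)
  expect_identical(nrow(nuc), 0L)
})

test_that("no detected nucleus centroid lies outside tumour regions", {
  sp <- fixture_spot()
  od <- colour_deconvolve(sp$image)
  nuc <- detect_nuclei(od, sp$truth$mask, pixel_size_um = 1)
  m <- unclass(sp$truth$mask)
  expect_true(all(m[cbind(round(nuc$row), round(nuc$col))] == 2L))
})

test_that("detection is deterministic", {
  sp <- fixture_spot()
  od <- colour_deconvolve(sp$image)
  a <- detect_nuclei(od, sp$truth$mask, pixel_size_um = 1)
  b <- detect_nuclei(od, sp$truth$mask, pixel_size_um = 1)
  expect_identical(a, b)
})

test_that("intensity bins follow the half-open threshold convention", {
  nuc <- data.frame(mean_dab_od = c(0, 0.14, 0.15, 0.39, 0.40, 0.69, 0.70, 2))
  out <- assign_intensity_bins(nuc, thresholds = c(0.15, 0.40, 0.70))
  expect_identical(out$intensity_bin, c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L))
  expect_identical(out$is_positive, out$intensity_bin >= 1L)
  expect_error(assign_intensity_bins(nuc, thresholds = c(0.4, 0.2, 0.7)),
               "t1 < t2 < t3")
})

test_that("proportion bins match the Allred and Quickscore tables", {
  ap <- tmascore:::allred_proportion_bin
  expect_identical(vapply(c(0, 0.5, 1, 9.9, 10, 33, 34, 66, 67, 100), ap, 0L),
                   c(0L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L))
  qp <- tmascore:::quickscore_proportion_bin
  expect_identical(vapply(c(0, 4.9, 5, 19, 20, 39, 40, 59, 60, 79, 80, 100), qp, 0L),
                   c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L, 6L, 6L))
})

test_that("spot scores combine intensity and proportion as defined", {
  nuc <- data.frame(mean_dab_od = c(rep(0.5, 3), rep(0.01, 7)))
  nuc <- assign_intensity_bins(nuc)
  sc <- score_spot(nuc)
  expect_equal(sc$percent_positive, 30)
  expect_identical(sc$allred_proportion, 3L)
  expect_identical(sc$quickscore_proportion, 3L)
  expect_identical(sc$intensity_score, 2L)
  expect_identical(sc$allred_total, 5L)
  expect_identical(sc$quickscore_total, 5L)

  # maximum case: all positive at saturating OD
  nuc2 <- assign_intensity_bins(data.frame(mean_dab_od = rep(1.5, 4)))
  sc2 <- score_spot(nuc2)
  expect_identical(sc2$allred_total, 8L)

  # empty spot scores all-zero with Quickscore proportion 1
  expect_warning(sc0 <- score_spot(nuc2[0, ]), "no nuclei")
  expect_identical(sc0$allred_total, 0L)
  expect_identical(sc0$quickscore_proportion, 1L)
  expect_false(sc0$er_status_allred)
})

test_that("ER status uses the >2 Allred and >3 Quickscore cut-offs", {
  mk <- function(n_pos, n_neg, od) {
    assign_intensity_bins(data.frame(mean_dab_od = c(rep(od, n_pos),
                                                     rep(0.01, n_neg))))
  }
  # Allred total 2 (intensity 1 + proportion 1): negative
  s2 <- score_spot(mk(1, 200, 0.2))
  expect_identical(s2$allred_total, 2L)
  expect_false(s2$er_status_allred)
  # Allred total 3 (intensity 1 + proportion 2): positive
  s3 <- score_spot(mk(4, 96, 0.2))
  expect_identical(s3$allred_total, 3L)
  expect_true(s3$er_status_allred)
  # Quickscore total 3 negative, 4 positive
  q3 <- score_spot(mk(10, 90, 0.3)) # intensity 1 + proportion 2 = 3
  expect_identical(q3$quickscore_total, 3L)
  expect_false(q3$er_status_quickscore)
  q4 <- score_spot(mk(25, 75, 0.3)) # intensity 1 + proportion 3 = 4
  expect_identical(q4$quickscore_total, 4L)
  expect_true(q4$er_status_quickscore)
})

test_that("raising every nucleus's DAB OD never lowers any score", {
  set.seed(4)
  base <- data.frame(mean_dab_od = runif(60, 0, 1))
  for (delta in c(0.1, 0.3, 0.8)) {
    lo <- score_spot(assign_intensity_bins(base))
    hi <- score_spot(assign_intensity_bins(
      data.frame(mean_dab_od = base$mean_dab_od + delta)))
    expect_gte(hi$percent_positive, lo$percent_positive)
    expect_gte(hi$intensity_score, lo$intensity_score)
    expect_gte(hi$allred_total, lo$allred_total)
    expect_gte(hi$quickscore_total, lo$quickscore_total)
  }
})
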