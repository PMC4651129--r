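test_that("identical config and stains give bit-identical spots", {
  cfg <- synthetic_spot_config(diameter_px = 200, seed = 7)
  a <- generate_spot(cfg)
  b <- generate_spot(cfg)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(unclass(a$truth$mask), unclass(b$truth$mask))
  expect_identical(a$truth$nuclei, b$truth$nuclei)
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_spot(synthetic_spot_config(diameter_px = 150, seed = 1)))
  expect_identical(runif(1), before)
})

test_that("tumour area fraction tracks the configured target", {
  sp <- generate_spot(synthetic_spot_config(diameter_px = 600, seed = 11,
                                            tumour_fraction = 0.30))
  m <- unclass(sp$truth$mask)
  frac <- sum(m == 2L) / sum(m != 0L)
  expect_gte(frac, 0.25)
  expect_lte(frac, 0.35)
})

test_that("mask OUTSIDE is exactly the complement of the inscribed disc", {
  sp <- fixture_spot()
  m <- unclass(sp$truth$mask)
  expect_identical(m == 0L, !sp$image$inside_spot)
  d <- nrow(m)
  ctr <- (d + 1) / 2
  rows <- matrix(seq_len(d), d, d)
  cols <- matrix(seq_len(d), d, d, byrow = TRUE)
  expect_identical(sp$image$inside_spot,
                   (rows - ctr)^2 + (cols - ctr)^2 <= (d / 2)^2)
})

test_that("ground truth nuclei satisfy their invariants", {
  sp <- fixture_spot()
  nuc <- sp$truth$nuclei
  m <- unclass(sp$truth$mask)
  tum <- nuc[nuc$compartment == "tumour", ]
  idx <- cbind(round(tum$row), round(tum$col))
  expect_true(all(m[idx] == 2L))
  expect_equal(sp$truth$percent_positive_tumour,
               100 * sum(tum$is_positive) / nrow(tum), tolerance = 1e-9)
  # positives only among tumour nuclei, with the programmed peak OD
  expect_true(all(!nuc$is_positive[nuc$compartment != "tumour"]))
  expect_true(all(nuc$dab_od[nuc$is_positive] > 0))
})

test_that("a zero-percent-positive spot has no DAB anywhere in truth", {
  sp <- generate_spot(synthetic_spot_config(diameter_px = 200, seed = 5,
                                            programmed_percent_positive = 0,
                                            programmed_intensity_bin = 0))
  expect_true(all(!sp$truth$nuclei$is_positive))
  expect_true(all(sp$truth$nuclei$dab_od == 0))
})

test_that("inconsistent programmed score configurations are rejected", {
  expect_error(synthetic_spot_config(programmed_percent_positive = 0,
                                     programmed_intensity_bin = 2),
               "intensity_bin")
  expect_error(synthetic_spot_config(programmed_percent_positive = 50,
                                     programmed_intensity_bin = 0),
               "intensity_bin")
})

test_that("infeasible nucleus density fails naming the compartment", {
  cfg <- synthetic_spot_config(
    diameter_px = 150, seed = 2,
    nucleus_density_per_mm2 = c(tumour = 60000, normal_epithelium = 1500,
                                lymphocyte = 4000, stroma_cell = 400))
  expect_error(generate_spot(cfg), "tumour")
})

test_that("boundary jitter moves boundaries by at most its magnitude", {
  sp <- fixture_spot()
  mag <- 4L
  p <- perturb_mask(sp$truth$mask, "boundary_jitter", mag, seed = 8)
  m0 <- unclass(sp$truth$mask); m1 <- unclass(p)
  expect_identical(m1 == 0L, m0 == 0L) # OUTSIDE untouched
  changed <- m0 != m1
  expect_gt(sum(changed), 0)
  # every changed pixel lies within `mag` of the original T/N boundary
  T0 <- m0 == 2L
  dist_in <- tmascore:::dist_to_background(T0)
  dist_out <- tmascore:::dist_to_background(!T0)
  d <- pmax(dist_in, dist_out)
  expect_lte(max(d[changed]), mag + 1)
})

test_that("jitter on an all-N mask is the identity", {
  m <- blank_mask(30)
  expect_identical(unclass(perturb_mask(m, "boundary_jitter", 1, seed = 1)),
                   unclass(m))
})

test_that("component_flip(add) creates exactly one new T component", {
  m <- blank_mask(60)
  p <- perturb_mask(m, "component_flip", 10, seed = 3, direction = "add")
  comp <- tmascore:::label_components(unclass(p) == 2L, 8L)
  expect_identical(max(comp), 1L)
})

test_that("region_resize and delete require T pixels; perturbation is seeded", {
  m <- blank_mask(30)
  expect_error(perturb_mask(m, "region_resize", 2, seed = 1), "no T")
  expect_error(perturb_mask(m, "component_flip", 2, seed = 1,
                            direction = "delete"), "no T")
  sp <- fixture_spot()
  a <- perturb_mask(sp$truth$mask, "region_resize", 3, seed = 12)
  b <- perturb_mask(sp$truth$mask, "region_resize", 3, seed = 12)
  expect_identical(unclass(a), unclass(b))
  expect_identical(unclass(a) == 0L, unclass(sp$truth$mask) == 0L)
})
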