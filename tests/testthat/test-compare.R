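test_that("identical masks give a diagonal contingency table", {
  sp <- fixture_spot()
  ct <- pixel_contingency(sp$truth$mask, sp$truth$mask)
  expect_identical(ct$counts[1, 2] + ct$counts[2, 1], 0L)
  expect_equal(sum(ct$normalized), 1, tolerance = 1e-9)
})

test_that("hand-counted label flips appear on the off-diagonal", {
  a <- matrix(1L, 4, 4); a[2, 2] <- 2L
  b <- a
  b[1, 1] <- 2L; b[2, 2] <- 1L; b[3, 4] <- 2L # 3 flips
  ct <- pixel_contingency(mk_mask(a), mk_mask(b))
  expect_identical(ct$counts["T", "N"] + ct$counts["N", "T"], 3L)
})

test_that("masks with different perimeters are rejected", {
  a <- matrix(1L, 4, 4)
  b <- a; b[1, 1] <- 0L
  expect_error(pixel_contingency(mk_mask(a), mk_mask(b)), "perimeters")
  expect_error(pixel_contingency(mk_mask(a), mk_mask(matrix(1L, 5, 5))),
               "shapes")
})

test_that("the reference normalized tables are valid instances", {
  expect_equal(sum(reference_pathologist_block()), 1, tolerance = 1e-3)
  expect_equal(sum(reference_auto_block()), 1.001, tolerance = 1e-3)
})

test_that("a thin dilation ring is entirely Type 1", {
  a <- matrix(1L, 40, 40); a[10:29, 10:29] <- 2L
  b <- matrix(1L, 40, 40); b[8:31, 8:31] <- 2L
  dm <- classify_disagreements(mk_mask(a), mk_mask(b), 8)
  expect_gt(dm$counts[["type1"]], 0)
  expect_identical(sum(dm$counts[c("type2", "type3")]), 0L)
  expect_identical(unname(dm$counts[["type1"]]), sum(a != b))
})

test_that("a separated added square is Type 3 in its core", {
  a <- matrix(1L, 48, 48); a[10:29, 10:29] <- 2L
  b <- a; b[36:47, 36:47] <- 2L # 12x12, well separated from a's T
  dm <- classify_disagreements(mk_mask(a), mk_mask(b), 8)
  expect_identical(dm$counts[["type2"]], 0L)
  expect_gt(dm$counts[["type3"]], 0)
  # the square's centre survives the opening and is Type 3
  expect_identical(dm$map[41, 41], 5L) # DIS_TYPE3
  # matches the literal rule-by-rule oracle
  orc <- oracle_classify(mk_mask(a), mk_mask(b), 8)
  expect_identical(unname(dm$counts),
                   c(sum(orc == 1L), sum(orc == 2L), sum(orc == 3L)))
})

test_that("an attached wide protrusion is Type 2 in its core", {
  a <- matrix(1L, 40, 40); a[10:29, 10:29] <- 2L
  b <- a; b[14:25, 30:38] <- 2L
  dm <- classify_disagreements(mk_mask(a), mk_mask(b), 8)
  expect_gt(dm$counts[["type2"]], 0)
  expect_identical(dm$counts[["type3"]], 0L)
  expect_identical(dm$map[20, 33], 4L) # DIS_TYPE2 in the protrusion core
})

test_that("classification equals the brute-force oracle on random masks", {
  for (seed in 1:30) {
    pair <- random_mask_pair(48, seed)
    cd <- sample(c(3, 5, 8), 1)
    dm <- classify_disagreements(pair$A, pair$B, cd)
    orc <- oracle_classify(pair$A, pair$B, cd)
    got <- dm$map
    got[!(got %in% c(3L, 4L, 5L))] <- 0L
    got[got == 3L] <- 1L; got[got == 4L] <- 2L; got[got == 5L] <- 3L
    expect_identical(got, orc)
  }
})

test_that("the taxonomy is symmetric, conservative, and monotone in cell size", {
  for (seed in 31:40) {
    pair <- random_mask_pair(48, seed)
    d1 <- classify_disagreements(pair$A, pair$B, 6)
    d2 <- classify_disagreements(pair$B, pair$A, 6)
    expect_identical(d1$counts, d2$counts)
    expect_identical(which(d1$map == 3L), which(d2$map == 3L))
    # conservation against the contingency off-diagonal
    ct <- pixel_contingency(pair$A, pair$B)
    expect_identical(sum(d1$counts),
                     ct$counts["T", "N"] + ct$counts["N", "T"])
  }
})

test_that("a larger cell disc never shrinks the Type-1 set when discs nest", {
  # Opening anti-monotonicity is a theorem only when the larger structuring
  # disc is itself openable by the smaller one; digital discs do not nest
  # for arbitrary diameter pairs, so the premise is verified first.
  small <- 6; large <- 8
  big <- tmascore:::disc_brush(large) > 0
  expect_identical(tmascore:::open_disc(big, small), big) # coverable pair
  for (seed in 41:55) {
    pair <- random_mask_pair(48, seed)
    d1 <- classify_disagreements(pair$A, pair$B, small)
    d3 <- classify_disagreements(pair$A, pair$B, large)
    expect_true(all(which(d1$map == 3L) %in% which(d3$map == 3L)))
  }
})

test_that("summaries normalise per spot and aggregate as mean and sd", {
  a <- matrix(1L, 40, 40); a[10:29, 10:29] <- 2L
  b <- matrix(1L, 40, 40); b[8:31, 8:31] <- 2L   # all type 1
  m1 <- classify_disagreements(mk_mask(a), mk_mask(b), 8)
  s1 <- summarise_disagreements(list(m1))
  expect_equal(unname(s1$mean), c(1, 0, 0))

  c2 <- matrix(1L, 40, 40)
  c2[10:29, 10:29] <- 2L
  c2[34:39, 1:6] <- 2L                            # separated added block
  m2 <- classify_disagreements(mk_mask(a), mk_mask(c2), 1)
  # with a single-pixel disc nothing is opened away: pure type 3
  expect_identical(m2$counts[["type1"]], 0L)
  s <- summarise_disagreements(list(m1, m2))
  expect_equal(unname(s$mean), c(0.5, 0, 0.5))
  expect_equal(unname(s$sd), c(sqrt(0.5), 0, sqrt(0.5)), tolerance = 1e-9)

  ident <- classify_disagreements(mk_mask(a), mk_mask(a), 8)
  expect_message(s3 <- summarise_disagreements(list(m1, ident)), "excluded")
  expect_identical(s3$n_excluded, 1L)
  expect_equal(unname(s3$mean), c(1, 0, 0))
})

test_that("difference images code the three types and conserve counts", {
  a <- matrix(1L, 40, 40); a[10:29, 10:29] <- 2L
  b <- matrix(1L, 40, 40); b[8:31, 8:31] <- 2L
  dm <- classify_disagreements(mk_mask(a), mk_mask(b), 8)
  img <- render_difference_image(dm)
  red <- img[, , 1] == 255L & img[, , 2] == 0L & img[, , 3] == 0L
  expect_identical(sum(red), unname(dm$counts[["type1"]]))

  ident <- classify_disagreements(mk_mask(a), mk_mask(a), 8)
  img0 <- render_difference_image(ident)
  pure <- (img0[, , 1] == 255L & img0[, , 2] == 0L & img0[, , 3] == 0L) |
          (img0[, , 2] == 255L & img0[, , 1] == 0L & img0[, , 3] == 0L) |
          (img0[, , 3] == 255L & img0[, , 1] == 0L & img0[, , 2] == 0L)
  expect_identical(sum(pure), 0L)
})
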