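test_that("observed agreement is the diagonal mass of the printed blocks", {
  expect_equal(observed_agreement(reference_pathologist_block()), 0.908,
               tolerance = 1e-9)
  expect_equal(observed_agreement(reference_auto_block()), 0.812 / 1.001,
               tolerance = 1e-3)
  expect_identical(observed_agreement(diag(4)), 1)
  expect_error(observed_agreement(matrix(0, 2, 2)), "empty")
})

test_that("Cohen's kappa matches the hand-evaluated formula", {
  # independent evaluation of (po - pe)/(1 - pe) on the printed block
  m <- reference_pathologist_block()
  po <- m[1, 1] + m[2, 2]
  pe <- sum(m[1, ]) * sum(m[, 1]) + sum(m[2, ]) * sum(m[, 2])
  expect_equal(cohen_kappa(m), (po - pe) / (1 - pe), tolerance = 1e-12)
  expect_equal(cohen_kappa(m), 0.787, tolerance = 1e-3)
  # perfect agreement with balanced marginals
  expect_equal(cohen_kappa(diag(2) * 5), 1)
})

test_that("kappa is near zero for independent random labels", {
  set.seed(12)
  n <- 1e5
  a <- sample(c("N", "T"), n, replace = TRUE, prob = c(0.7, 0.3))
  b <- sample(c("N", "T"), n, replace = TRUE, prob = c(0.6, 0.4))
  conf <- ordinal_confusion(match(a, c("N", "T")), match(b, c("N", "T")), 1:2)
  expect_lt(abs(cohen_kappa(conf)), 0.02)
})

test_that("degenerate tables return flagged NA, not an error", {
  m <- matrix(c(5, 0, 0, 0), 2, 2) # both raters constant
  k <- cohen_kappa(m)
  expect_true(is.na(k))
  expect_match(attr(k, "reason"), "constant")
  wk <- weighted_kappa(m)
  expect_true(is.na(wk))
})

test_that("the definitional identity po = pe + kappa (1 - pe) holds", {
  set.seed(3)
  for (i in 1:10) {
    m <- matrix(rpois(9, 4), 3, 3) + diag(3) * 5
    po <- observed_agreement(m)
    p <- m / sum(m)
    pe <- sum(rowSums(p) * colSums(p))
    expect_equal(po, pe + cohen_kappa(m) * (1 - pe), tolerance = 1e-12)
  }
})

test_that("quadratic weighted kappa reduces to Cohen's kappa for k = 2", {
  set.seed(7)
  for (i in 1:10) {
    m <- matrix(rpois(4, 6) + 1, 2, 2)
    expect_equal(weighted_kappa(m, "quadratic"), cohen_kappa(m),
                 tolerance = 1e-12)
  }
})

test_that("weighted kappa equals the brute-force double-sum oracle", {
  expect_equal(weighted_kappa(matrix(c(5, 1, 0, 1, 5, 1, 0, 1, 5), 3, 3)),
               oracle_weighted_kappa(matrix(c(5, 1, 0, 1, 5, 1, 0, 1, 5), 3, 3)),
               tolerance = 1e-12)
  set.seed(21)
  for (i in 1:20) {
    k <- sample(3:9, 1)
    m <- matrix(rpois(k * k, 2), k, k) + diag(k) * sample(0:5, 1)
    expect_equal(weighted_kappa(m, "quadratic"), oracle_weighted_kappa(m, 2),
                 tolerance = 1e-12)
    expect_equal(weighted_kappa(m, "linear"), oracle_weighted_kappa(m, 1),
                 tolerance = 1e-12)
  }
})

test_that("quadratic weighted kappa is invariant to reversing categories", {
  set.seed(5)
  for (i in 1:10) {
    k <- sample(3:7, 1)
    m <- matrix(rpois(k * k, 3), k, k) + diag(k)
    rev_m <- m[k:1, k:1]
    expect_equal(weighted_kappa(m), weighted_kappa(rev_m), tolerance = 1e-12)
  }
})

test_that("diagonal confusion matrices give kappa 1", {
  m <- diag(c(2, 3, 4))
  expect_equal(observed_agreement(m), 1)
  expect_equal(weighted_kappa(m), 1)
})

test_that("ordinal confusions use the full declared category range", {
  conf <- ordinal_confusion(c(0, 8), c(0, 8), levels = 0:8)
  expect_identical(dim(unclass(conf)), c(9L, 9L))
  expect_error(ordinal_confusion(c(0, 9), c(0, 8), levels = 0:8), "outside")
})

test_that("Bland-Altman bias and limits follow the definitions", {
  ba0 <- bland_altman(c(5, 10, 20), c(5, 10, 20))
  expect_identical(ba0$bias, 0)
  expect_identical(ba0$loa_lower, 0)
  expect_identical(ba0$loa_upper, 0)

  ba <- bland_altman(c(10, 20), c(12, 18))
  expect_equal(ba$differences, c(-2, 2))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, sqrt(8), tolerance = 1e-12)
  expect_equal(ba$loa_upper, 1.96 * sqrt(8), tolerance = 1e-12)

  expect_error(bland_altman(1, 2), "at least 2")
  # shifting the first source shifts the bias by the same constant
  ba2 <- bland_altman(c(10, 20) + 7, c(12, 18))
  expect_equal(ba2$bias, ba$bias + 7)
})

test_that("score histograms conserve spot counts per source", {
  scores <- data.frame(source = c("a", "a", "b"),
                       allred_total = c(8, 0, 5),
                       quickscore_total = c(9, 1, 4))
  h <- score_histograms(scores)
  expect_equal(unname(rowSums(h$allred)), c(2, 1))
  expect_identical(h$allred["a", "8"], 1L)
  expect_identical(h$quickscore["b", "4"], 1L)
  expect_equal(unname(rowSums(h$quickscore)), c(2, 1))
})
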