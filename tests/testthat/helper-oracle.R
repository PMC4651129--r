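# Independent brute-force oracles, kept deliberately naive and separate from
# the package's implementation paths.

# Shift a logical matrix by (di, dj), padding with FALSE.
shift_mat <- function(x, di, dj) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(FALSE, h, w)
  src_r <- max(1, 1 - di):min(h, h - di)
  src_c <- max(1, 1 - dj):min(w, w - dj)
  out[src_r + di, src_c + dj] <- x[src_r, src_c]
  out
}

disc_offsets <- function(diameter) {
  r <- floor(diameter / 2)
  g <- expand.grid(i = -r:r, j = -r:r)
  g[g$i^2 + g$j^2 <= (diameter / 2)^2, , drop = FALSE]
}

# Opening straight from the definitions: erosion = AND over disc shifts,
# dilation of the erosion = OR over disc shifts.
oracle_opening <- function(D, diameter) {
  offs <- disc_offsets(diameter)
  er <- matrix(TRUE, nrow(D), ncol(D))
  for (t in seq_len(nrow(offs))) {
    er <- er & shift_mat(D, -offs$i[t], -offs$j[t])
  }
  op <- matrix(FALSE, nrow(D), ncol(D))
  for (t in seq_len(nrow(offs))) {
    op <- op | shift_mat(er, offs$i[t], offs$j[t])
  }
  op
}

# 8-connected components by label propagation over shifted copies: iterate
# "each pixel takes the minimum positive label among itself and its eight
# neighbours" until a fixed point -- a literal reading of connectivity.
oracle_components <- function(x) {
  h <- nrow(x); w <- ncol(x)
  lab <- matrix(seq_len(h * w), h, w)
  lab[!x] <- 0L
  repeat {
    new <- lab
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      sh <- matrix(0L, h, w)
      src_r <- max(1, 1 - di):min(h, h - di)
      src_c <- max(1, 1 - dj):min(w, w - dj)
      sh[src_r + di, src_c + dj] <- lab[src_r, src_c]
      upd <- x & sh > 0 & sh < new
      new[upd] <- sh[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  # renumber to 1..K
  u <- sort(unique(lab[lab > 0]))
  out <- matrix(0L, h, w)
  out[lab > 0] <- match(lab[lab > 0], u)
  out
}

# Literal application of the three disagreement rules. Returns an integer
# matrix: 0 none, 1/2/3 for the three types.
oracle_classify <- function(A, B, cell_diameter) {
  A <- unclass(A); B <- unclass(B)
  ins <- A != 0L
  D <- ins & (A != B)
  out <- matrix(0L, nrow(A), ncol(A))
  if (!any(D)) return(out)
  opened <- oracle_opening(D, cell_diameter)
  type1 <- D & !opened
  rest <- D & opened
  compA <- oracle_components(A == 2L)
  compB <- oracle_components(B == 2L)
  okA <- unique(compA[compA > 0L & B == 2L])
  okB <- unique(compB[compB > 0L & A == 2L])
  t2 <- rest & ((A == 2L & B != 2L &
                   matrix(compA %in% okA, nrow(A), ncol(A))) |
                (B == 2L & A != 2L &
                   matrix(compB %in% okB, nrow(A), ncol(A))))
  out[type1] <- 1L
  out[t2] <- 2L
  out[rest & !t2] <- 3L
  out
}

# Random comparable mask pair from seeded blob processes (all-inside spots).
random_mask_pair <- function(n, seed) {
  set.seed(seed)
  mk <- function() {
    m <- matrix(1L, n, n)
    for (b in seq_len(sample(0:3, 1))) {
      r0 <- runif(1, 1, n); c0 <- runif(1, 1, n)
      rad <- runif(1, 2, n / 3)
      rows <- matrix(seq_len(n), n, n)
      cols <- matrix(seq_len(n), n, n, byrow = TRUE)
      m[(rows - r0)^2 + (cols - c0)^2 <= rad^2] <- 2L
    }
    m
  }
  A <- mk()
  # B: sometimes correlated with A (shifted blobs), sometimes independent
  B <- if (runif(1) < 0.5) {
    sh <- sample(-3:3, 2, replace = TRUE)
    Bt <- shift_mat(A == 2L, sh[1], sh[2])
    Bm <- matrix(1L, n, n)
    Bm[Bt] <- 2L
    Bm
  } else mk()
  list(A = mk_mask(A), B = mk_mask(B))
}

# Brute-force weighted kappa by explicit double sums over the definitions.
oracle_weighted_kappa <- function(counts, power = 2) {
  k <- nrow(counts)
  tot <- sum(counts)
  num <- 0; den <- 0
  rm <- rowSums(counts) / tot
  cm <- colSums(counts) / tot
  for (i in seq_len(k)) for (j in seq_len(k)) {
    w <- (abs(i - j) / (k - 1))^power
    num <- num + w * counts[i, j] / tot
    den <- den + w * rm[i] * cm[j]
  }
  1 - num / den
}
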