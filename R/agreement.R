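#' Ordinal confusion matrix between two score sources
#'
#' Cross-tabulates paired ordinal scores (e.g. a spot's Allred total under
#' two segmentation sources) over a fixed, ordered category range. The full
#' range is always used -- including categories unobserved in this cohort --
#' so weights and chance expectations are well-defined and comparable across
#' cohorts.
#'
#' @param x,y Numeric/integer vectors of paired scores.
#' @param levels Ordered vector of all possible categories (e.g. `0:8` for
#'   Allred totals).
#' @return Object of class `ordinal_confusion`: a k x k count matrix with
#'   `levels` as dimnames, rows = `x`.
#' @export
ordinal_confusion <- function(x, y, levels) {
  stopifnot(length(x) == length(y), length(levels) >= 2)
  if (!all(x %in% levels) || !all(y %in% levels)) {
    stop("scores outside the declared category levels")
  }
  m <- table(factor(x, levels = levels), factor(y, levels = levels))
  m <- matrix(as.numeric(m), length(levels), length(levels),
              dimnames = list(as.character(levels), as.character(levels)))
  structure(m, class = c("ordinal_confusion", "matrix", "array"))
}

as_agreement_matrix <- function(x) {
  if (inherits(x, "contingency_2x2")) return(x$counts)
  if (inherits(x, "ordinal_confusion")) return(unclass(x))
  if (is.matrix(x) && nrow(x) == ncol(x)) return(x)
  stop("expected a contingency_2x2, ordinal_confusion, or square matrix")
}

#' Observed agreement (diagonal mass)
#'
#' The fraction of paired observations on which the two sources give the same
#' label: the diagonal sum of the (normalised) table. For a normalised 2x2
#' pixel contingency table this is the proportion of identically labelled
#' pixels.
#'
#' @param table A `contingency_2x2`, `ordinal_confusion`, or square matrix of
#'   counts or proportions.
#' @return Numeric in `[0, 1]`.
#' @export
observed_agreement <- function(table) {
  m <- as_agreement_matrix(table)
  tot <- sum(m)
  if (tot <= 0) stop("empty agreement table")
  sum(diag(m)) / tot
}

#' Cohen's kappa (chance-corrected agreement)
#'
#' `(po - pe) / (1 - pe)` where `po` is observed agreement and `pe` the
#' chance agreement from the marginal products. When both sources are
#' constant (`pe = 1`) kappa is undefined: the function returns `NA` flagged
#' with a `reason` attribute rather than raising, so cohort tables stay
#' rectangular.
#'
#' @inheritParams observed_agreement
#' @return Numeric in `[-1, 1]`, or flagged `NA` when undefined.
#' @export
cohen_kappa <- function(table) {
  m <- as_agreement_matrix(table)
  tot <- sum(m)
  if (tot <= 0) stop("empty agreement table")
  p <- m / tot
  po <- sum(diag(p))
  pe <- sum(rowSums(p) * colSums(p))
  if (abs(1 - pe) < 1e-12) {
    return(structure(NA_real_, reason = "both sources constant (pe = 1); kappa undefined"))
  }
  (po - pe) / (1 - pe)
}

#' Weighted kappa for ordinal categories
#'
#' Two-rater weighted kappa, `1 - sum(w * o) / sum(w * e)`, with disagreement
#' weights `w_ij = ((i - j)/(k - 1))^2` (quadratic, the Fleiss-Cohen weights
#' standardly meant by a "kappa-squared" agreement statistic) or
#' `|i - j|/(k - 1)` (linear); `e` is the chance expectation from the
#' marginals. For k = 2 both weightings reduce to unweighted Cohen's kappa.
#'
#' @param conf An `ordinal_confusion` (or square count matrix whose row order
#'   is the category order).
#' @param weights `"quadratic"` or `"linear"`.
#' @return Numeric, or flagged `NA` when the chance-expected weighted
#'   disagreement is zero (degenerate marginals).
#' @export
weighted_kappa <- function(conf, weights = c("quadratic", "linear")) {
  weights <- match.arg(weights)
  m <- as_agreement_matrix(conf)
  k <- nrow(m)
  stopifnot(k >= 2)
  tot <- sum(m)
  if (tot <= 0) stop("empty confusion matrix")
  o <- m / tot
  i <- matrix(seq_len(k), k, k)
  j <- t(i)
  w <- (abs(i - j) / (k - 1))^(if (weights == "quadratic") 2 else 1)
  e <- outer(rowSums(o), colSums(o))
  denom <- sum(w * e)
  if (denom < 1e-12) {
    return(structure(NA_real_, reason = "degenerate marginals; weighted kappa undefined"))
  }
  1 - sum(w * o) / denom
}

#' Bland-Altman analysis of paired percent-positive measurements
#'
#' For each pair, the mean and the difference (`source1 - source2`); bias is
#' the mean difference and the 95 percent limits of agreement are
#' `bias +/- 1.96 * sd(differences)`.
#'
#' @param x,y Numeric vectors of paired measurements (at least 2 pairs), or
#'   `x` a 2-column matrix/data.frame with `y` missing.
#' @return Object of class `bland_altman`: list with `means`, `differences`,
#'   `bias`, `sd_diff`, `loa_lower`, `loa_upper`, `n`.
#' @export
bland_altman <- function(x, y = NULL) {
  if (is.null(y)) {
    stopifnot(ncol(x) == 2)
    y <- x[, 2]; x <- x[, 1]
  }
  stopifnot(length(x) == length(y))
  if (length(x) < 2) stop("Bland-Altman analysis needs at least 2 pairs")
  d <- x - y
  m <- (x + y) / 2
  bias <- mean(d)
  s <- sd(d)
  structure(list(means = m, differences = d, bias = bias, sd_diff = s,
                 loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
                 n = length(x)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("bland_altman: n = %d, bias = %.3f, 95%% LoA [%.3f, %.3f]\n",
              x$n, x$bias, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Plot a Bland-Altman analysis
#'
#' @param x A `bland_altman` object.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$differences,
                 xlab = "Mean of the two sources",
                 ylab = "Difference (source1 - source2)", pch = 19, ...)
  graphics::abline(h = c(x$bias, x$loa_lower, x$loa_upper),
                   lty = c(1, 2, 2), col = c("black", "grey40", "grey40"))
  invisible(x)
}

#' Score histograms per mask source
#'
#' Counts spots per Allred total (0-8) and Quickscore total (1-9) for each
#' mask source, for side-by-side comparison of score distributions.
#'
#' @param scores data.frame with columns `source`, `allred_total`,
#'   `quickscore_total` (one row per spot per source), e.g. the score table
#'   of [run_study()].
#' @return List with matrices `allred` and `quickscore`: rows = sources,
#'   columns = totals; every row sums to that source's spot count.
#' @export
score_histograms <- function(scores) {
  stopifnot(all(c("source", "allred_total", "quickscore_total") %in% names(scores)))
  src <- unique(as.character(scores$source))
  al <- t(vapply(src, function(s)
    tabulate(scores$allred_total[scores$source == s] + 1L, nbins = 9L),
    integer(9)))
  qs <- t(vapply(src, function(s)
    tabulate(scores$quickscore_total[scores$source == s], nbins = 9L),
    integer(9)))
  colnames(al) <- 0:8
  colnames(qs) <- 1:9
  list(allred = al, quickscore = qs)
}
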