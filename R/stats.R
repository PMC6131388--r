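## Agreement statistics: dice overlap of binary masks and the intraclass
## correlation coefficient for coordinate reproducibility.

#' Dice coefficient of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; two empty masks agree perfectly (1).
#'
#' @param a,b logical arrays/matrices of identical shape, or
#'   [BinaryVolume3D-class] / [BinaryImage2D-class] / [ArchImage-class]
#'   objects.
#' @return dice coefficient in [0, 1]
#' @export
diceCoefficient <- function(a, b) {
  unwrap <- function(x) {
    if (is(x, "Volume3D")) x@data
    else if (is(x, "Image2D")) x@data
    else if (is(x, "ArchImage")) x@mask
    else x
  }
  a <- unwrap(a); b <- unwrap(b)
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measures: from the
#' two-way ANOVA decomposition of an n-targets x k-raters table,
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`
#' with MSR the between-target, MSC the between-rater and MSE the residual
#' mean square. This form penalizes systematic rater offsets, which is what
#' coordinate-reproducibility assessment needs.
#'
#' @param table numeric n x k matrix, n >= 2 targets, k >= 2 raters, no
#'   missing cells.
#' @return the ICC value (<= 1)
#' @export
iccAbsoluteAgreement <- function(table) {
  table <- as.matrix(table)
  if (any(!is.finite(table))) stop("missing cells in the ratings table")
  n <- nrow(table); k <- ncol(table)
  if (n < 2L) stop("need at least 2 targets")
  if (k < 2L) stop("need at least 2 raters")
  rowM <- rowMeans(table); colM <- colMeans(table); gm <- mean(table)
  ssr <- k * sum((rowM - gm)^2)
  ssc <- n * sum((colM - gm)^2)
  sse <- sum((table - outer(rowM, rep(1, k)) -
                outer(rep(1, n), colM) + gm)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom <= 0) stop("undefined ICC: zero total variance")
  (msr - mse) / denom
}
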