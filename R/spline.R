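## Natural cubic smoothing spline in piecewise-polynomial form.
##
## Minimizes  p * sum((y - f(x))^2) + (1 - p) * integral(f''(t)^2 dt)
## over natural cubic splines with knots at the data sites (the classic
## Reinsch formulation).  p = 1 interpolates; p -> 0 tends to the
## least-squares line.  The solution is obtained from the tridiagonal system
## (T + a Q'Q) g = Q'y with a = (1-p)/p, where g holds the interior second
## derivatives; fitted values are f = y - a Q g.

#' Fit a cubic smoothing spline to one coordinate
#'
#' Fits a natural cubic smoothing spline minimizing
#' `p * RSS + (1 - p) * roughness` and returns it in piecewise-polynomial
#' form (ordered breaks, four ascending-power coefficients per cubic piece).
#' With `p = 1` the spline interpolates the samples exactly.
#'
#' @param x strictly increasing parameter values (>= 4 samples).
#' @param y values at `x`.
#' @param p smoothing parameter in (0, 1].
#' @return a [SmoothingSpline-class]
#' @export
fitSmoothingSpline <- function(x, y, p = 0.99) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4L) stop("need at least 4 samples")
  if (any(diff(x) == 0)) stop("duplicate parameter values in x")
  if (any(diff(x) < 0)) stop("x must be strictly increasing")
  if (p <= 0 || p > 1) stop("p must lie in (0, 1]")
  n <- length(x)
  h <- diff(x)

  if (p == 1) {
    g <- .naturalSecondDerivs(x, y)
    a <- y
  } else {
    alpha <- (1 - p) / p
    ## Q: n x (n-2), T: (n-2) x (n-2) (Green & Silverman)
    Q <- matrix(0, n, n - 2)
    for (j in 2:(n - 1)) {
      Q[j - 1, j - 1] <- 1 / h[j - 1]
      Q[j,     j - 1] <- -1 / h[j - 1] - 1 / h[j]
      Q[j + 1, j - 1] <- 1 / h[j]
    }
    Tm <- matrix(0, n - 2, n - 2)
    for (j in 2:(n - 1)) {
      Tm[j - 1, j - 1] <- (h[j - 1] + h[j]) / 3
      if (j < n - 1) {
        Tm[j - 1, j] <- h[j] / 6
        Tm[j, j - 1] <- h[j] / 6
      }
    }
    g_int <- solve(Tm + alpha * crossprod(Q), crossprod(Q, y))
    a <- as.numeric(y - alpha * Q %*% g_int)
    g <- c(0, as.numeric(g_int), 0)
  }

  ## piecewise cubic from values a and second derivatives g at the knots
  co <- matrix(0, n - 1, 4)
  ip <- seq_len(n - 1)
  co[, 1] <- a[ip]
  co[, 3] <- g[ip] / 2
  co[, 4] <- (g[ip + 1] - g[ip]) / (6 * h)
  co[, 2] <- (a[ip + 1] - a[ip]) / h - h * (2 * g[ip] + g[ip + 1]) / 6
  new("SmoothingSpline", breaks = x, coef = co)
}

## natural-spline second derivatives for exact interpolation (p = 1)
.naturalSecondDerivs <- function(x, y) {
  n <- length(x); h <- diff(x)
  if (n == 2) return(c(0, 0))
  rhs <- 6 * diff(diff(y) / h)
  Tm <- matrix(0, n - 2, n - 2)
  for (j in 2:(n - 1)) {
    Tm[j - 1, j - 1] <- 2 * (h[j - 1] + h[j])
    if (j < n - 1) {
      Tm[j - 1, j] <- h[j]
      Tm[j, j - 1] <- h[j]
    }
  }
  c(0, as.numeric(solve(Tm, rhs)), 0)
}

#' Evaluate a smoothing spline
#'
#' Evaluates the piecewise cubic (or a derivative of it) anywhere in (or
#' beyond, by polynomial extension of the end pieces) its domain.
#'
#' @param spline a [SmoothingSpline-class]
#' @param t evaluation positions
#' @param deriv derivative order 0, 1 or 2
#' @return numeric values
#' @export
evalSpline <- function(spline, t, deriv = 0L) {
  br <- spline@breaks
  co <- spline@coef
  piece <- findInterval(t, br, all.inside = TRUE)
  dx <- t - br[piece]
  c1 <- co[piece, 1]; c2 <- co[piece, 2]; c3 <- co[piece, 3]; c4 <- co[piece, 4]
  if (deriv == 0L) c1 + dx * (c2 + dx * (c3 + dx * c4))
  else if (deriv == 1L) c2 + dx * (2 * c3 + 3 * dx * c4)
  else if (deriv == 2L) 2 * c3 + 6 * dx * c4
  else stop("deriv must be 0, 1 or 2")
}

#' Construct a planar fitted curve from two splines
#' @param x,y [SmoothingSpline-class] components over a shared parameter.
#' @return a [FittedCurve-class]
#' @export
fittedCurve <- function(x, y) new("FittedCurve", x = x, y = y)

#' Evaluate a planar fitted curve
#' @param curve a [FittedCurve-class]
#' @param t parameter values
#' @param deriv derivative order 0, 1 or 2
#' @return n x 2 matrix of (X, Y) values
#' @export
evalCurve <- function(curve, t, deriv = 0L) {
  cbind(evalSpline(curve@x, t, deriv), evalSpline(curve@y, t, deriv))
}

#' Parameter domain of a fitted curve
#' @param curve a [FittedCurve-class]
#' @return numeric(2), range of the parameter
#' @export
curveDomain <- function(curve) range(curve@x@breaks)

## serialize/deserialize pp-form for reports
.splineToList <- function(s) list(breaks = s@breaks, coef = s@coef)
.splineFromList <- function(l) {
  new("SmoothingSpline", breaks = as.numeric(l$breaks),
      coef = matrix(as.numeric(unlist(l$coef)), ncol = 4))
}
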