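#' Four-parameter logistic calibration fit
#'
#' Least-squares fit of the sigmoid
#' \deqn{y = A + \frac{B - A}{1 + e^{-(x - x_0)/s}}}
#' with lower asymptote `A`, upper asymptote `B`, inflection `x0` and scale
#' `s`. Along a dehydration trajectory the resonance frequency follows such
#' a sigmoid in relative water content, and the inflection point is the
#' operational proxy for the turgor loss point.
#'
#' @param x,y Numeric vectors, at least 6 points; `x` must not be constant.
#' @return Object of class `logistic4_fit` (also `calibration_fit`):
#'   `coefficients` (A, B, x0, s), `r2_adjusted`, `n_points`, `fitted`,
#'   `boundary` (TRUE when the optimiser stopped on a parameter bound,
#'   indicating the sigmoid degenerated, e.g. on straight-line data).
#'   Methods: `print`, `coef`, `predict`.
#' @section Errors: constant `y` gives a degenerate-data error;
#'   non-convergence of all starting points gives an error with diagnostics.
#' @examples
#' x <- seq(0.6, 1, length.out = 50)
#' y <- 0.7 + 0.3 / (1 + exp(-(x - 0.85) / 0.03))
#' fit <- fit_logistic4(x, y)
#' inflection_point(fit) # 0.85
#' @export
fit_logistic4 <- function(x, y) {
  check_xy(x, y, min_n = 6L)
  if (diff(range(y)) == 0) stop("degenerate data: y is constant")
  xr <- diff(range(x))
  # direction of trend sets which asymptote is which
  increasing <- stats::cor(x, y) >= 0
  A0 <- if (increasing) min(y) else max(y)
  B0 <- if (increasing) max(y) else min(y)
  # scale bounds: resolvable range; s below ~xr/1e3 is a step function,
  # above ~10*xr a straight line
  s_lo <- xr * 1e-3
  s_hi <- xr * 10
  resid <- function(p) y - (p[1] + (p[2] - p[1]) / (1 + exp(-(x - p[3]) / p[4])))
  yr <- diff(range(y))
  lower <- c(min(y) - yr, min(y) - yr, min(x), s_lo)
  upper <- c(max(y) + yr, max(y) + yr, max(x), s_hi)
  starts <- expand.grid(x0 = stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE),
                        s = xr * c(0.02, 0.1, 0.5))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- c(A0, B0, starts$x0[i], starts$s[i])
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, lower = lower, upper = upper, fn = resid,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    value <- sum(resid(fit$par)^2)
    if (is.null(best) || value < best$value)
      best <- list(par = fit$par, value = value)
  }
  if (is.null(best))
    stop("logistic fit did not converge from any starting point")
  p <- best$par
  # parameters pinned at bounds signal a degenerate sigmoid (e.g. a straight
  # line drives the asymptotes and scale outwards)
  reltol <- 1e-6 * pmax(abs(lower), abs(upper), 1e-12)
  boundary <- any(p - lower <= reltol) || any(upper - p <= reltol)
  fitted <- p[1] + (p[2] - p[1]) / (1 + exp(-(x - p[3]) / p[4]))
  out <- list(coefficients = c(A = p[1], B = p[2], x0 = p[3], s = p[4]),
              r2_adjusted = adj_r2(y, fitted, 4L),
              n_points = length(x), fitted = fitted, x = x, y = y,
              boundary = boundary)
  class(out) <- c("logistic4_fit", "calibration_fit")
  out
}

#' Inflection point of a logistic calibration
#'
#' Returns the `x0` parameter, where the curvature of the sigmoid changes
#' sign and its slope is maximal. Physiological reading: the turgor loss
#' point of the dehydration trajectory.
#'
#' @param model A `logistic4_fit`.
#' @return The inflection abscissa `x0`.
#' @export
inflection_point <- function(model) {
  stopifnot(inherits(model, "logistic4_fit"))
  unname(model$coefficients["x0"])
}

#' Segmented (broken-stick) linear calibration fit
#'
#' Continuous two-piece linear least squares: a single join point `x_b`
#' with slopes `m1` below and `m2` above, continuous at the join. Along a
#' dehydration trajectory, water potential against resonance frequency
#' follows such a model with the join at the turgor loss point. The join is
#' located by an exhaustive search over all midpoints between consecutive
#' distinct sorted `x` values (each a distinguishable model), followed by
#' continuous refinement of the best candidate.
#'
#' @param x,y Numeric vectors, at least 6 points spanning both sides of an
#'   admissible join.
#' @return Object of class `segmented_fit` (also `calibration_fit`):
#'   `coefficients` (x_b, y_b, m1, m2), `r2_adjusted`, `n_points`,
#'   `fitted`, `collinear` (TRUE when the data are a single straight line
#'   and the join is indeterminate; the single-line fallback `m1 = m2` is
#'   returned). Methods: `print`, `coef`, `predict`.
#' @examples
#' x <- seq(300, 700, by = 20)
#' y <- ifelse(x < 500, 0.01 * (x - 500), 0.05 * (x - 500))
#' coef(fit_segmented_linear(x, y))["x_b"] # 500
#' @export
fit_segmented_linear <- function(x, y) {
  check_xy(x, y, min_n = 6L)
  sse_at <- function(xb) {
    h <- pmax(x - xb, 0)
    f <- stats::lm.fit(cbind(1, x, h), y)
    sum(f$residuals^2)
  }
  xs <- sort(unique(x))
  if (length(xs) < 4L) stop("need at least 4 distinct x values")
  # candidate joins: midpoints with >= 2 points strictly on each side
  mids <- (xs[-1] + xs[-length(xs)]) / 2
  mids <- mids[vapply(mids, function(m) sum(x < m) >= 2 && sum(x > m) >= 2,
                      logical(1))]
  if (length(mids) == 0L) stop("no admissible join point")
  sse <- vapply(mids, sse_at, numeric(1))
  xb <- mids[which.min(sse)]
  # continuous refinement between the neighbouring candidates
  lo <- if (which.min(sse) > 1) mids[which.min(sse) - 1] else min(xs)
  hi <- if (which.min(sse) < length(mids)) mids[which.min(sse) + 1] else max(xs)
  ref <- stats::optimize(sse_at, c(lo, hi))
  if (ref$objective < min(sse)) xb <- ref$minimum
  h <- pmax(x - xb, 0)
  f <- stats::lm(y ~ x + h)
  beta <- stats::coef(f)
  m1 <- unname(beta["x"])
  m2 <- m1 + unname(beta["h"])
  yb <- unname(beta["(Intercept)"]) + m1 * xb
  fitted <- unname(stats::fitted(f))
  # collinearity: a single line explains the data as well as the broken stick
  line_sse <- sum(stats::lm.fit(cbind(1, x), y)$residuals^2)
  seg_sse <- sum(stats::residuals(f)^2)
  tot <- sum((y - mean(y))^2)
  collinear <- (line_sse - seg_sse) <= 1e-10 * max(tot, 1e-300)
  if (collinear) {
    lf <- stats::lm(y ~ x)
    m1 <- m2 <- unname(stats::coef(lf)["x"])
    yb <- unname(stats::predict(lf, data.frame(x = xb)))
    fitted <- unname(stats::fitted(lf))
  }
  out <- list(coefficients = c(x_b = unname(xb), y_b = yb, m1 = m1, m2 = m2),
              r2_adjusted = adj_r2(y, fitted, if (collinear) 2L else 4L),
              n_points = length(x), fitted = fitted, x = x, y = y,
              collinear = collinear)
  class(out) <- c("segmented_fit", "calibration_fit")
  out
}

#' Ordinary linear calibration fit
#'
#' Least-squares line with Pearson correlation, for simple resonance
#' frequency versus water potential correlations.
#'
#' @param x,y Numeric vectors, at least 3 points; `x` must not be constant.
#' @return Object of class `linear_cal` (also `calibration_fit`):
#'   `coefficients` (intercept, slope), `pearson_r`, `r2_adjusted`,
#'   `n_points`, `fitted`.
#' @export
linear_fit <- function(x, y) {
  check_xy(x, y, min_n = 3L)
  if (diff(range(x)) == 0) stop("degenerate data: x is constant")
  f <- stats::lm(y ~ x)
  fitted <- unname(stats::fitted(f))
  out <- list(coefficients = c(intercept = unname(stats::coef(f)[1]),
                               slope = unname(stats::coef(f)[2])),
              pearson_r = stats::cor(x, y),
              r2_adjusted = adj_r2(y, fitted, 2L),
              n_points = length(x), fitted = fitted, x = x, y = y)
  class(out) <- c("linear_cal", "calibration_fit")
  out
}

#' Resonance frequency normalised to full hydration
#'
#' `f / f0`, where `f0` is the resonance frequency in the saturated state.
#' Reporting trajectories on this scale makes leaves of different thickness
#' comparable.
#'
#' @param f Resonance frequency, Hz (vectorised).
#' @param f0 Reference (full hydration) resonance frequency, Hz; must be
#'   positive.
#' @return `f / f0`.
#' @examples
#' normalized_frequency(225e3, 350e3) # about 0.643
#' @export
normalized_frequency <- function(f, f0) {
  stopifnot(is.numeric(f), length(f0) == 1L, is.finite(f0))
  if (f0 <= 0) stop("f0 must be positive")
  f / f0
}

#' @export
coef.calibration_fit <- function(object, ...) object$coefficients

#' @export
predict.logistic4_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else newdata
  p <- object$coefficients
  unname(p["A"] + (p["B"] - p["A"]) / (1 + exp(-(x - p["x0"]) / p["s"])))
}

#' @export
predict.segmented_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else newdata
  p <- object$coefficients
  unname(ifelse(x <= p["x_b"],
                p["y_b"] + p["m1"] * (x - p["x_b"]),
                p["y_b"] + p["m2"] * (x - p["x_b"])))
}

#' @export
predict.linear_cal <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else newdata
  unname(object$coefficients["intercept"] + object$coefficients["slope"] * x)
}

#' @export
print.calibration_fit <- function(x, ...) {
  kind <- class(x)[1]
  cat(sprintf("Calibration fit (%s), n = %d, adjusted R^2 = %.3f\n",
              kind, x$n_points, x$r2_adjusted))
  print(round(x$coefficients, 6))
  if (!is.null(x$pearson_r))
    cat(sprintf("Pearson R = %.3f\n", x$pearson_r))
  if (isTRUE(x$boundary))
    cat("note: parameter at bound; sigmoid degenerate for these data\n")
  if (isTRUE(x$collinear))
    cat("note: data collinear; join indeterminate, single-line fallback\n")
  invisible(x)
}

check_xy <- function(x, y, min_n) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y))
    stop("x and y must be numeric vectors of equal length")
  if (length(x) < min_n)
    stop("need at least ", min_n, " points, got ", length(x))
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  invisible(TRUE)
}

# adjusted R^2 with p fitted parameters
adj_r2 <- function(y, fitted, p) {
  n <- length(y)
  tot <- sum((y - mean(y))^2)
  if (tot == 0) return(NA_real_)
  r2 <- 1 - sum((y - fitted)^2) / tot
  1 - (1 - r2) * (n - 1) / (n - p)
}
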