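#' Convert optical density to dry cell weight
#'
#' Applies the strain's linear biomass correlation
#' `g DCW/L = OD600 * 0.452`.
#'
#' @param od600 Non-negative optical density reading(s) at 600 nm.
#' @param factor Correlation slope in g DCW/L per OD unit (default 0.452,
#'   the calibration for *E. coli* W).
#' @return Dry cell weight concentration in g DCW/L.
#' @examples
#' od_to_dcw(1.0)  # 0.452
#' @export
od_to_dcw <- function(od600, factor = 0.452) {
  if (any(od600 < 0, na.rm = TRUE)) {
    stop("od600 must be non-negative", call. = FALSE)
  }
  od600 * factor
}

#' Fit a linear calibration curve
#'
#' Generic least-squares calibration utility (absorbance vs concentration
#' and the like): fits `response = intercept + slope * standard` and
#' returns a predictor for new responses.
#'
#' @param standard Known concentrations.
#' @param response Measured responses.
#' @return A list with `slope`, `intercept`, `r_squared` and `predict`, a
#'   function mapping responses back to concentrations.
#' @export
linear_calibration <- function(standard, response) {
  stopifnot(length(standard) == length(response), length(standard) >= 2)
  fit <- stats::lm(response ~ standard)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (abs(slope) < 1e-12) stop("calibration slope is zero", call. = FALSE)
  list(
    slope = slope, intercept = intercept,
    r_squared = suppressWarnings(summary(fit)$r.squared),
    predict = function(y) (y - intercept) / slope
  )
}

# R-squared of the OLS fit of log(x) on t; closed form.  A zero-variance
# response carries no growth information, so it scores 0 -- this keeps
# stationary-phase plateaus from outcompeting the true exponential window
# during phase detection (a flat stretch is a "perfect" fit of slope 0).
loglinear_r2 <- function(t, logx) {
  st <- stats::var(t)
  sx <- stats::var(logx)
  if (sx < 1e-20 || st < 1e-20) return(0)
  stats::cor(t, logx)^2
}

#' Detect the exponential growth phase of a batch curve
#'
#' Scans all contiguous windows of at least `min_points` observations
#' with positive biomass and returns the one maximising the R-squared of
#' the regression of `ln X` on time.  Ties (within 1e-9) are broken in
#' favour of the longest window, then the earliest, so a purely
#' exponential curve reports its full range.
#'
#' @param curve A data frame with columns `time_h` and `dcw_g_l` (one
#'   replicate's trajectory, times strictly increasing).
#' @param min_points Minimum number of points in the window (default 4,
#'   the smallest window where R-squared carries information).
#' @return A list of class `phase_window` with `start`, `end` (row
#'   indices), `n` and `r_squared`.
#' @export
detect_exponential_phase <- function(curve, min_points = 4) {
  t <- curve$time_h
  x <- curve$dcw_g_l
  stopifnot(length(t) == length(x), !is.unsorted(t, strictly = TRUE))
  ok <- is.finite(x) & x > 0
  if (sum(ok) < min_points) {
    stop("fewer than ", min_points, " positive biomass readings",
         call. = FALSE)
  }
  best <- NULL
  n <- length(t)
  for (i in seq_len(n)) {
    if (!ok[i]) next
    for (j in seq(i + min_points - 1L, n)) {
      if (j > n || !all(ok[i:j])) break
      r2 <- loglinear_r2(t[i:j], log(x[i:j]))
      len <- j - i + 1L
      if (is.null(best) ||
          r2 > best$r_squared + 1e-9 ||
          (r2 > best$r_squared - 1e-9 &&
           (len > best$n || (len == best$n && i < best$start)))) {
        best <- list(start = i, end = j, n = len, r_squared = r2)
      }
    }
  }
  if (is.null(best)) stop("no valid exponential window found", call. = FALSE)
  structure(best, class = "phase_window")
}

#' @export
print.phase_window <- function(x, ...) {
  cat(sprintf("<phase_window> points %d..%d (n = %d), R^2 = %.4f\n",
              x$start, x$end, x$n, x$r_squared))
  invisible(x)
}

#' Maximum specific growth rate by log-linear regression
#'
#' Estimates `mu_max` as the ordinary least-squares slope of `ln X`
#' against time over the exponential-phase window, the standard
#' operational reading of `mu = (1/X) dX/dt` for batch data.  The
#' estimate is invariant to rescaling the biomass by a positive constant.
#'
#' @param curve A data frame with columns `time_h` and `dcw_g_l`.
#' @param window A `phase_window` from [detect_exponential_phase()], or
#'   `NULL` to detect it automatically.
#' @param min_points Passed to the window detection.
#' @return A list of class `mu_max_fit` with `mu_max` (1/h),
#'   `r_squared`, and the `window` used.
#' @examples
#' curve <- tibble::tibble(time_h = 0:5, dcw_g_l = 0.1 * exp(0.5 * (0:5)))
#' fit_mu_max(curve)$mu_max  # 0.5
#' @export
fit_mu_max <- function(curve, window = NULL, min_points = 4) {
  if (is.null(window)) {
    window <- detect_exponential_phase(curve, min_points = min_points)
  }
  idx <- window$start:window$end
  t <- curve$time_h[idx]
  x <- curve$dcw_g_l[idx]
  if (any(!is.finite(x) | x <= 0)) {
    stop("non-positive biomass inside the fit window", call. = FALSE)
  }
  if (length(t) < 2L || stats::var(t) < 1e-20) {
    stop("zero time variance in the fit window", call. = FALSE)
  }
  logx <- log(x)
  slope <- if (stats::var(logx) < 1e-20) 0 else
    unname(stats::coef(stats::lm(logx ~ t))[2])
  structure(
    list(mu_max = slope, r_squared = loglinear_r2(t, logx),
         window = window),
    class = "mu_max_fit"
  )
}

#' @export
print.mu_max_fit <- function(x, ...) {
  cat(sprintf("<mu_max_fit> mu_max = %.4g 1/h (R^2 = %.4f, points %d..%d)\n",
              x$mu_max, x$r_squared, x$window$start, x$window$end))
  invisible(x)
}

#' Yield coefficients from batch endpoint deltas
#'
#' Computes the three batch yield coefficients from concentration changes
#' over the culture: biomass on substrate `Yx/s = dX/dS`, product on
#' substrate `Yp/s = dP/dS` and product on biomass `Yp/x = dP/dX`, all in
#' g/g.  The ratios are homogeneous of degree zero, i.e. invariant to a
#' common rescaling of each numerator/denominator pair's units.
#'
#' @param delta_x Biomass formed, g DCW/L (may be `NA` if only substrate
#'   yields are wanted).
#' @param delta_s Substrate consumed, g/L (must be positive).
#' @param delta_p Product formed, g/L.
#' @return A one-row tibble with columns `yxs`, `yps`, `ypx`.
#' @examples
#' compute_yields(delta_x = NA, delta_s = 10.2, delta_p = 2.18)$yps  # 0.2137
#' @export
compute_yields <- function(delta_x, delta_s, delta_p) {
  if (!is.finite(delta_s) || delta_s <= 0) {
    stop("substrate yields undefined: delta_s must be positive", call. = FALSE)
  }
  have_x <- !is.na(delta_x)
  if (have_x && delta_x <= 0) {
    stop("ypx undefined: delta_x must be positive", call. = FALSE)
  }
  tibble::tibble(
    yxs = if (have_x) delta_x / delta_s else NA_real_,
    yps = delta_p / delta_s,
    ypx = if (have_x) delta_p / delta_x else NA_real_
  )
}

#' Kinetic parameters of one batch growth curve
#'
#' Convenience wrapper: detects the exponential phase, fits `mu_max`, and
#' computes endpoint-delta yields over the whole batch (first to last
#' observation), returning one tidy row per call.
#'
#' @param curve One replicate's `growth_curve` (columns `time_h`,
#'   `dcw_g_l`, `substrate_g_l`, `product_g_l`).
#' @param min_points Minimum exponential-window size.
#' @return A one-row tibble: `mu_max`, `r_squared`, `window_start`,
#'   `window_end`, `yxs`, `yps`, `ypx`.
#' @export
estimate_kinetics <- function(curve, min_points = 4) {
  fit <- fit_mu_max(curve, min_points = min_points)
  n <- nrow(curve)
  dx <- curve$dcw_g_l[n] - curve$dcw_g_l[1]
  ds <- curve$substrate_g_l[1] - curve$substrate_g_l[n]
  dp <- curve$product_g_l[n] - curve$product_g_l[1]
  yields <- compute_yields(if (dx > 0) dx else NA, ds, dp)
  tibble::tibble(
    mu_max = fit$mu_max, r_squared = fit$r_squared,
    window_start = fit$window$start, window_end = fit$window$end,
    yxs = yields$yxs, yps = yields$yps, ypx = yields$ypx
  )
}
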