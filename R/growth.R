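#' Maximum specific growth rate from an OD time series
#'
#' Estimates mu, the steepest slope of ln(OD) against time, as a
#' plate-reader growth-curve tool would: subtract the background
#' absorbance, floor the corrected OD at a small epsilon, smooth the
#' curve, then fit a least-squares line to every run of `window_points`
#' consecutive timepoints of ln(OD) and take the largest slope. Negative
#' maxima are floored at zero. The two-point log-ratio definition of mu is
#' the `window_points = 2` limit of this estimator.
#'
#' Smoothing matters because additive reading noise becomes large on the
#' log scale at low OD, where a raw windowed maximum picks up spurious
#' steep stretches. The default (`smoothing = "logistic"`) fits a lagged
#' logistic growth model by nonlinear least squares and takes the windowed
#' slopes of the fitted curve, the model-based route of standard
#' growth-curve tools; if the fit does not converge it falls back to a
#' smoothing spline on ln(OD) weighted by OD^2 (inverse log-scale noise
#' variance). `smoothing = "spline"` forces the spline; `"none"` uses the
#' raw log readings. Exactly exponential noiseless input yields mu exactly
#' under every mode.
#'
#' @param curve a `growth_curve` data.frame (columns `time_h`, `od`) as
#'   produced by [simulate_growth_curve()], or a numeric vector of OD
#'   values (then supply `times`).
#' @param times timepoints in hours (ignored when `curve` is a
#'   `growth_curve`; must be strictly increasing).
#' @param background scalar or per-timepoint background absorbance to
#'   subtract; defaults to the curve's `background` attribute, else 0.
#' @param window_points number of consecutive timepoints per sliding fit
#'   (>= 2).
#' @param eps floor applied to background-corrected OD before taking logs.
#' @param smoothing one of `"logistic"`, `"spline"`, `"none"`.
#' @return A list of class `growth_rate`: `mu` (1/h), `flag` (`"ok"` or
#'   `"no-growth"`), `smoothing` (the mode actually used),
#'   `window_points`, `n`.
#' @examples
#' t <- seq(0, 10, by = 0.25)
#' max_specific_growth_rate(0.1 * exp(0.5 * t), times = t)$mu # 0.5
#' @export
max_specific_growth_rate <- function(curve, times = NULL, background = NULL,
                                     window_points = 5L, eps = 1e-4,
                                     smoothing = c("logistic", "spline",
                                                   "none")) {
  smoothing <- match.arg(smoothing)
  if (inherits(curve, "growth_curve")) {
    times <- curve$time_h
    od <- curve$od
    if (is.null(background))
      background <- attr(curve, "background")
  } else {
    od <- as.numeric(curve)
  }
  if (is.null(background)) background <- 0
  if (is.null(times)) stop("timepoints required")
  n <- length(times)
  if (length(od) != n) stop("times and od differ in length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  w <- as.integer(window_points)
  if (w < 2L) stop("window_points must be >= 2")
  if (n < w) stop("fewer timepoints than window_points")

  odc <- pmax(od - background, eps)
  if (max(odc) <= eps * 1.000001) {
    return(structure(list(mu = 0, flag = "no-growth",
                          smoothing = smoothing, window_points = w, n = n),
                     class = "growth_rate"))
  }
  lo <- log(odc)
  used <- "none"
  if (smoothing == "logistic" && n >= 10L) {
    pred <- fit_lagged_logistic(times, odc)
    if (!is.null(pred)) {
      lo <- log(pmax(pred, eps))
      used <- "logistic"
    }
  }
  if (used == "none" && smoothing != "none" && n >= 10L) {
    fit <- stats::smooth.spline(times, lo, w = odc^2)
    lo <- stats::predict(fit, times)$y
    used <- "spline"
  }
  slopes <- vapply(seq_len(n - w + 1L), function(i) {
    tt <- times[i:(i + w - 1L)]
    yy <- lo[i:(i + w - 1L)]
    stats::cov(tt, yy) / stats::var(tt)
  }, numeric(1))
  mu <- max(slopes)
  structure(list(mu = max(0, mu), flag = "ok", smoothing = used,
                 window_points = w, n = n),
            class = "growth_rate")
}

# Model-based smoother: least-squares fit of a lagged logistic and of a
# lagged exponential (the unsaturated limit), keeping whichever AIC
# prefers. Returns fitted values, or NULL when neither fit converges.
fit_lagged_logistic <- function(t, odc) {
  k0 <- max(odc)
  n00 <- max(min(odc), 1e-3)
  safe_nls <- function(...) {
    tryCatch(suppressWarnings(stats::nls(
      ..., algorithm = "port",
      control = stats::nls.control(warnOnly = TRUE))),
      error = function(e) NULL)
  }
  logi <- safe_nls(
    odc ~ K * N0 * exp(r * pmax(0, t - lag)) /
      (K + N0 * (exp(r * pmax(0, t - lag)) - 1)),
    start = list(K = k0, N0 = n00, r = 0.2, lag = 1),
    lower = c(K = 1e-3, N0 = 1e-5, r = 0, lag = 0),
    upper = c(K = 10 * k0, N0 = k0, r = 5, lag = max(t)))
  expo <- safe_nls(
    odc ~ N0 * exp(r * pmax(0, t - lag)),
    start = list(N0 = n00, r = 0.2, lag = 1),
    lower = c(N0 = 1e-5, r = 0, lag = 0),
    upper = c(N0 = k0, r = 5, lag = max(t)))
  fits <- Filter(Negate(is.null), list(logi, expo))
  if (length(fits) == 0L) return(NULL)
  aics <- vapply(fits, stats::AIC, numeric(1))
  as.numeric(stats::predict(fits[[which.min(aics)]], list(t = t)))
}

#' @export
print.growth_rate <- function(x, ...) {
  cat(sprintf("mu = %.4f 1/h (%s, window %d of %d points)\n",
              x$mu, x$flag, x$window_points, x$n))
  invisible(x)
}

#' Normalize kinetic parameters to a reference strain
#'
#' Plain division of each strain's parameter by the reference strain's
#' value measured in the same medium.
#'
#' @param values named numeric vector of parameter values (e.g. mu).
#' @param reference_value the reference strain's value (> 0).
#' @return Named numeric vector of normalized values.
#' @export
normalize_to_reference <- function(values, reference_value) {
  if (reference_value <= 0) stop("reference value must be positive")
  values / reference_value
}
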