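# Additive seasonal decomposition of monthly RSV series. The decomposition
# follows the STL idea -- alternate between a Loess-estimated trend and a
# seasonal component -- but with a *periodic* seasonal component: one fixed
# value per calendar month (the cycle-subseries mean of the detrended
# series), which is the form the study reports (a single peak/trough
# component per month). The Loess smoother is implemented directly: a local
# linear (or constant) fit with tricube weights over the q nearest
# neighbours.

#' Local polynomial (Loess) smoother with tricube weights
#'
#' At each point the fit uses the `q = max(degree + 1, ceiling(span * n))`
#' nearest neighbours, weighted by the tricube kernel
#' `w = (1 - (d/d_max)^3)^3` of their scaled distances, and returns the
#' weighted local polynomial fit (constant or linear) evaluated there. A
#' local linear fit reproduces straight lines exactly, so the smoother never
#' distorts a pure linear trend.
#'
#' @param xs strictly increasing predictor values.
#' @param ys responses, same length.
#' @param span fraction of points in each local neighbourhood (0, 1].
#' @param degree local polynomial degree, 0 or 1.
#' @return numeric vector of fitted values at each `xs`.
#' @examples
#' x <- 1:20
#' loess_smooth(x, 3 + 2 * x, span = 0.5, degree = 1)  # exactly 3 + 2x
#' @export
loess_smooth <- function(xs, ys, span, degree = 1) {
  n <- length(xs)
  stopifnot(length(ys) == n, degree %in% c(0, 1))
  if (n < degree + 1) {
    stop("need at least degree + 1 points", call. = FALSE)
  }
  if (is.unsorted(xs, strictly = TRUE)) {
    stop("xs must be strictly increasing", call. = FALSE)
  }
  q <- max(degree + 1, ceiling(span * n))
  q <- min(q, n)
  fitted <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(xs - xs[i])
    idx <- order(d)[seq_len(q)]
    dmax <- d[idx[q]]
    w <- if (dmax == 0) rep(1, q) else (1 - pmin(d[idx] / dmax, 1)^3)^3
    if (sum(w) == 0) w <- rep(1, q)  # all neighbours at the boundary radius
    xw <- xs[idx]
    yw <- ys[idx]
    if (degree == 0) {
      fitted[i] <- sum(w * yw) / sum(w)
    } else {
      xbar <- sum(w * xw) / sum(w)
      ybar <- sum(w * yw) / sum(w)
      sxx <- sum(w * (xw - xbar)^2)
      if (sxx < 1e-12) {
        fitted[i] <- ybar
      } else {
        beta <- sum(w * (xw - xbar) * (yw - ybar)) / sxx
        fitted[i] <- ybar + beta * (xs[i] - xbar)
      }
    }
  }
  fitted
}

#' Seasonal-trend decomposition with a periodic seasonal component
#'
#' Iterative additive decomposition: (1) estimate the trend by Loess over
#' the whole series; (2) detrend; (3) set the seasonal component of each
#' calendar month to the mean of that month's detrended values, centred so
#' the 12 components sum to zero; (4) subtract the tiled seasonal series and
#' re-estimate the trend on the deseasonalized series; repeat. The remainder
#' is defined as `input - trend - seasonal`, so the additive identity holds
#' exactly. Peak/trough months, amplitude (max - min of the monthly
#' components) and a harmonic-regression seasonality test are attached.
#'
#' @param s imputed [topic_series()] or numeric vector; length must be a
#'   whole number of cycles, at least 3.
#' @param period seasons per cycle (12 for monthly series).
#' @param n_iterations outer trend/seasonal refinement passes; `NULL` (the
#'   default) iterates until the monthly components stabilize (sup-norm
#'   change below 1e-10, at most 30 passes). The scheme converges
#'   geometrically, so this typically costs under ten passes.
#' @param trend_span Loess span for the trend; default
#'   `max(0.2, 1.5 * period / n)`.
#' @param alpha level for the seasonality-presence test.
#' @param start_month calendar month (1-12) of the first observation, used
#'   to label the components; defaults to the series' first month or
#'   January.
#' @return object of class `seasonal_decomposition`: `trend`, `seasonal`,
#'   `remainder` (same length as input), `monthly_component` (named,
#'   period-long, sums to 0), `peak_month`, `trough_month`, `amplitude`,
#'   `seasonal_present`, `seasonal_p`, `degenerate`.
#' @export
stl_periodic <- function(s, period = 12, n_iterations = NULL,
                         trend_span = NULL, alpha = 0.05,
                         start_month = NULL) {
  x <- series_values(s)
  n <- length(x)
  if (n %% period != 0) {
    stop("series length (", n, ") is not a whole number of cycles",
         call. = FALSE)
  }
  if (n %/% period < 3L) {
    stop("need at least 3 full cycles to decompose", call. = FALSE)
  }
  if (is.null(start_month)) {
    start_month <- if (inherits(s, "topic_series")) month_of(s$months[1])
                   else 1L
  }
  if (is.null(trend_span)) trend_span <- max(0.2, 1.5 * period / n)
  season_of <- ((seq_len(n) - 1 + start_month - 1) %% period) + 1
  ts_x <- seq_len(n)

  max_iter <- n_iterations %||% 30L
  tol <- if (is.null(n_iterations)) 1e-10 else 0
  trend <- loess_smooth(ts_x, x, span = trend_span, degree = 1)
  monthly <- numeric(period)
  for (it in seq_len(max_iter)) {
    detrended <- x - trend
    new_monthly <- vapply(seq_len(period),
                          function(m) mean(detrended[season_of == m]),
                          numeric(1))
    new_monthly <- new_monthly - mean(new_monthly)
    converged <- it > 1L && max(abs(new_monthly - monthly)) < tol
    monthly <- new_monthly
    seasonal <- monthly[season_of]
    trend <- loess_smooth(ts_x, x - seasonal, span = trend_span, degree = 1)
    if (converged) break
  }
  seasonal <- monthly[season_of]
  remainder <- x - trend - seasonal

  names(monthly) <- if (period == 12) MONTH_NAMES else
    paste0("season_", seq_len(period))
  st <- seasonality_test(x, period = period, alpha = alpha,
                         start_month = start_month)
  summ <- monthly_summary(monthly)
  structure(c(list(trend = trend, seasonal = seasonal,
                   remainder = remainder, monthly_component = monthly,
                   seasonal_present = st$seasonal_present,
                   seasonal_p = st$seasonal_p,
                   period = period, start_month = start_month),
              summ),
            class = "seasonal_decomposition")
}

#' @keywords internal
monthly_summary <- function(monthly) {
  amp <- max(monthly) - min(monthly)
  peak_i <- which(monthly == max(monthly))
  trough_i <- which(monthly == min(monthly))
  list(peak_month = names(monthly)[peak_i[1]],
       trough_month = names(monthly)[trough_i[1]],
       peak_value = unname(max(monthly)),
       trough_value = unname(min(monthly)),
       amplitude = amp,
       tie = length(peak_i) > 1L || length(trough_i) > 1L,
       degenerate = amp < 1e-9)
}

#' Peak, trough and amplitude of a seasonal decomposition
#'
#' The yearly amplitude is the maximum monthly seasonal component minus the
#' minimum one; the peak/trough months are the argmax/argmin, reported by
#' English month name. Ties go to the earliest calendar month and are
#' flagged.
#'
#' @param d a `seasonal_decomposition`, or a named numeric vector of monthly
#'   components.
#' @return list with `peak_month`, `trough_month`, `peak_value`,
#'   `trough_value`, `amplitude`, `tie`, `degenerate`.
#' @examples
#' comps <- c(May = 21.61, December = -22.16)
#' x <- stats::setNames(numeric(12), month.name); x[names(comps)] <- comps
#' seasonal_summary(x)$amplitude  # 43.77
#' @export
seasonal_summary <- function(d) {
  monthly <- if (inherits(d, "seasonal_decomposition")) d$monthly_component
             else d
  if (is.null(names(monthly))) {
    names(monthly) <- if (length(monthly) == 12) MONTH_NAMES else
      paste0("season_", seq_along(monthly))
  }
  monthly_summary(monthly)
}

#' Harmonic-regression test for the presence of seasonality
#'
#' Compares nested ordinary least-squares fits of the series on (a) a linear
#' time term only versus (b) linear time plus the first two Fourier
#' harmonics of the seasonal period (sine/cosine at 1 and 2 cycles per
#' year), via the standard F-test. This fills the role of a
#' seasonality-presence declaration: it asks whether a fixed periodic
#' pattern explains variance beyond the secular trend.
#'
#' @param s imputed [topic_series()] or numeric vector.
#' @param period seasons per cycle.
#' @param alpha significance level for `seasonal_present`.
#' @param start_month calendar month of the first value (phase only; the
#'   test statistic is invariant to it).
#' @return list with `seasonal_present` (logical), `seasonal_p`, `F`.
#' @export
seasonality_test <- function(s, period = 12, alpha = 0.05,
                             start_month = NULL) {
  x <- series_values(s)
  n <- length(x)
  if (n < period * 2) {
    stop("need at least 2 cycles to test for seasonality", call. = FALSE)
  }
  if (is.null(start_month)) {
    start_month <- if (inherits(s, "topic_series")) month_of(s$months[1])
                   else 1L
  }
  t_idx <- seq_len(n) - 1 + (start_month - 1)
  years <- t_idx / period
  h1 <- 2 * pi * t_idx / period
  X0 <- cbind(1, years)
  X1 <- cbind(X0, sin(h1), cos(h1), sin(2 * h1), cos(2 * h1))
  fit0 <- stats::lm.fit(X0, x)
  fit1 <- stats::lm.fit(X1, x)
  rss0 <- sum(fit0$residuals^2)
  rss1 <- sum(fit1$residuals^2)
  df_extra <- ncol(X1) - ncol(X0)
  df_res <- n - ncol(X1)
  if (rss1 <= 0) {
    return(list(seasonal_present = TRUE, seasonal_p = 0, F = Inf))
  }
  Fstat <- ((rss0 - rss1) / df_extra) / (rss1 / df_res)
  p <- stats::pf(Fstat, df_extra, df_res, lower.tail = FALSE)
  list(seasonal_present = p < alpha, seasonal_p = p, F = Fstat)
}

#' @export
print.seasonal_decomposition <- function(x, ...) {
  cat(sprintf(paste0(
    "<seasonal_decomposition> %d points, period %d\n",
    "  seasonal present: %s (p = %.3g)\n",
    "  peak %s (%.2f), trough %s (%.2f), amplitude %.2f\n"),
    length(x$trend), x$period,
    if (x$seasonal_present) "yes" else "no", x$seasonal_p,
    x$peak_month, x$peak_value, x$trough_month, x$trough_value,
    x$amplitude))
  invisible(x)
}
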