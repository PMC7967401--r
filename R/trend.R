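# Secular-trend inference. The Seasonal Mann-Kendall test sums the
# Mann-Kendall S statistic within each season (calendar month for monthly
# data), which removes the seasonal cycle from the trend comparison: values
# are only ever compared with values from the same calendar month of other
# years. Implemented from the standard formulas with the tie-corrected
# variance and the +/-1 continuity correction. The slope magnitude is
# reported separately as an ordinary least-squares slope in RSV per year.

#' @keywords internal
series_values <- function(s) {
  if (inherits(s, "topic_series")) {
    if (!s$imputed) {
      stop("series must be imputed (see impute_censored())", call. = FALSE)
    }
    s$values
  } else {
    as.numeric(s)
  }
}

#' Seasonal Mann-Kendall trend test
#'
#' For each season g with values `x[g, 1..n]` ordered by cycle (year), the
#' seasonal statistic is `S_g = sum_{i<j} sign(x[g,j] - x[g,i])` and its
#' null variance `Var_g = (n(n-1)(2n+5) - sum_k t_k(t_k-1)(2t_k+5)) / 18`,
#' where `t_k` are the sizes of tied groups within the season. Seasons are
#' treated as independent: `S = sum S_g`, `var_S = sum Var_g`. The normal
#' approximation uses the continuity correction `Z = (S -/+ 1)/sqrt(var_S)`,
#' and `tau = S / sum_g n_g(n_g-1)/2` (tie-unadjusted pair count).
#'
#' @param s imputed [topic_series()] or numeric vector; the first value is
#'   taken to fall in season 1 and length must be a multiple of `period`.
#' @param period number of seasons per cycle; 12 for monthly data.
#' @param alpha significance level used for the `significant` flag.
#' @return object of class `mk_trend`: list with `S`, `var_S`, `Z`, `tau`,
#'   `p_two_sided`, `n_years`, `period`, `significant`, `degenerate`.
#' @examples
#' seasonal_mann_kendall(seq_len(36), period = 12)$tau  # 1: monotone rise
#' @export
seasonal_mann_kendall <- function(s, period = 12, alpha = 0.05) {
  x <- series_values(s)
  n <- length(x)
  if (n %% period != 0) {
    stop("series length (", n, ") is not a multiple of the period (",
         period, ")", call. = FALSE)
  }
  cycles <- n %/% period
  if (cycles < 2L) {
    stop("need at least 2 full cycles for the seasonal test", call. = FALSE)
  }
  S <- 0
  var_S <- 0
  pairs <- 0
  for (g in seq_len(period)) {
    xg <- x[seq.int(g, n, by = period)]
    ng <- length(xg)
    d <- sign(outer(xg, xg, "-"))
    S <- S + sum(d[lower.tri(d)])  # [j, i] with j > i: sign(x_j - x_i)
    ties <- table(xg)
    ties <- ties[ties > 1L]
    var_S <- var_S +
      (ng * (ng - 1) * (2 * ng + 5) -
         sum(ties * (ties - 1) * (2 * ties + 5))) / 18
    pairs <- pairs + ng * (ng - 1) / 2
  }
  degenerate <- var_S <= 0
  Z <- if (degenerate || S == 0) 0
       else if (S > 0) (S - 1) / sqrt(var_S)
       else (S + 1) / sqrt(var_S)
  p <- if (degenerate) 1 else 2 * stats::pnorm(-abs(Z))
  structure(list(S = S, var_S = var_S, Z = Z, tau = S / pairs,
                 p_two_sided = p, n_years = cycles, period = period,
                 significant = !degenerate && p < alpha,
                 degenerate = degenerate),
            class = "mk_trend")
}

#' @export
print.mk_trend <- function(x, ...) {
  cat(sprintf(
    "<mk_trend> S = %g, var_S = %.2f, Z = %.3f, tau = %.3f, p = %.3g%s\n",
    x$S, x$var_S, x$Z, x$tau, x$p_two_sided,
    if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Ordinary least-squares slope in RSV per year
#'
#' Regresses the series on time coded in fractional years since the first
#' month (`month_index / 12`), so the slope is directly in RSV per year. The
#' p-value is the standard t-test on the slope coefficient.
#'
#' @param s imputed [topic_series()] or numeric vector of at least 24
#'   monthly values.
#' @return list with `slope` (RSV/year), `intercept`, `slope_p`.
#' @export
ols_slope <- function(s) {
  y <- series_values(s)
  if (length(y) < 24L) {
    stop("need at least 24 monthly values for a secular slope",
         call. = FALSE)
  }
  years <- (seq_along(y) - 1) / 12
  fit <- stats::lm(y ~ years)
  b <- stats::coef(fit)
  n <- length(y)
  rss <- sum(stats::residuals(fit)^2)
  sxx <- sum((years - mean(years))^2)
  se <- sqrt(rss / (n - 2) / sxx)
  # exact linear input: zero residual variance, slope is not a chance result
  p <- if (se == 0) as.numeric(b[["years"]] == 0)
       else 2 * stats::pt(-abs(b[["years"]] / se), df = n - 2)
  list(slope = unname(b[["years"]]), intercept = unname(b[["(Intercept)"]]),
       slope_p = p)
}

#' Significance stars for reported p-values
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, empty
#' otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of star strings.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}
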