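#' Four-parameter logistic dose-response model
#'
#' Constructor for the 4PL parameter set used throughout the scoring
#' pipeline. Responses are percent inhibition on a log10 molar concentration
#' axis:
#' \deqn{y(x) = d + \frac{a - d}{1 + 10^{\,b(c - x)}}}
#' where `a` is the top asymptote (maximal inhibition, %), `b` the Hill
#' slope (>0), `c` the log10 EC50 (inflection point, log10 molar) and `d`
#' the bottom asymptote (default 0: no inhibition at vanishing dose).
#'
#' @param a Top asymptote, percent inhibition in `[d, 100]`.
#' @param b Hill slope, dimensionless, in `(0, 10]`.
#' @param c Log10 EC50 (log10 molar).
#' @param d Bottom asymptote, percent inhibition (default 0).
#' @return An object of class `logistic4p` (named list `a`, `b`, `c`, `d`).
#' @examples
#' p <- logistic4p(a = 80, b = 1, c = -7)
#' predict_inhibition(p, c(-9, -7, -5))
#' @export
logistic4p <- function(a, b, c, d = 0) {
  stopifnot(is.finite(a), is.finite(b), is.finite(c), is.finite(d))
  if (d < 0 || a < d || a > 100)
    stop("logistic4p: need 0 <= d <= a <= 100, got a=", a, ", d=", d)
  if (b <= 0 || b > 10)
    stop("logistic4p: slope b must lie in (0, 10], got ", b)
  structure(list(a = a, b = b, c = c, d = d), class = "logistic4p")
}

#' @export
print.logistic4p <- function(x, ...) {
  cat(sprintf("4PL: top=%.4g  slope=%.4g  log10EC50=%.4g  bottom=%.4g\n",
              x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Predict percent inhibition from a 4PL curve
#'
#' @param p A [logistic4p()] parameter set.
#' @param x Numeric vector of log10 molar concentrations.
#' @return Percent inhibition at each `x`; strictly increasing in `x`
#'   whenever `a > d`.
#' @export
predict_inhibition <- function(p, x) {
  stopifnot(inherits(p, "logistic4p"), all(is.finite(x)))
  p$d + (p$a - p$d) / (1 + 10^(p$b * (p$c - x)))
}

#' Fit a four-parameter logistic curve to a dose series
#'
#' Constrained least squares on percent-inhibition data with the bottom
#' asymptote fixed at 0 by default (inhibition starts at no effect). The fit
#' is multi-start: a deterministic grid of slope and log10 EC50 initial
#' values is refined by bounded Levenberg-Marquardt
#' ([minpack.lm::nls.lm()]), and the start with the lowest residual sum of
#' squares wins; exact ties go to the smaller slope (smoother curve).
#'
#' Box constraints: `0 <= a <= 100`, `0 < b <= 10`,
#' `c` within the tested range widened by one log10 unit each side. A series
#' whose inhibition range is below `flat_range` percentage points is flagged
#' `identifiable = FALSE`: its potency parameters are not constrained by the
#' data (the threshold deliberately equals the default DSS activity
#' threshold).
#'
#' @param series A `dose_series` (see [extract_dose_series()]) or any list
#'   with numeric `x` (log10 molar, ascending) and `pi` (percent inhibition).
#' @param fix_bottom Fix the bottom asymptote at 0 (default `TRUE`).
#' @param slope_starts Slope grid for multi-start.
#' @param flat_range Identifiability threshold on the observed PI range
#'   (percentage points).
#' @return A `fit_result`: list with `params` ([logistic4p()]), `rss`, `r2`,
#'   `converged`, `identifiable`, `n`.
#' @examples
#' s <- list(x = -9:-5, pi = predict_inhibition(logistic4p(80, 1, -7), -9:-5))
#' fit_logistic(s)$params
#' @export
fit_logistic <- function(series, fix_bottom = TRUE,
                         slope_starts = c(0.5, 1, 2, 5),
                         flat_range = 10) {
  x <- as.numeric(series$x); y <- as.numeric(series$pi)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 2)
    stop("fit_logistic: need at least 2 distinct doses")
  ord <- order(x); x <- x[ord]; y <- y[ord]

  c_lo <- min(x) - 1; c_hi <- max(x) + 1
  # c starts: midpoints between consecutive doses plus the range center
  c_starts <- unique(c((x[-1] + x[-length(x)]) / 2, mean(range(x))))
  a0 <- min(100, max(1, max(y)))

  resid_fn <- function(par) y - par[1] / (1 + 10^(par[2] * (par[3] - x)))
  lower <- c(0, 1e-3, c_lo); upper <- c(100, 10, c_hi)

  best <- NULL
  for (b0 in slope_starts) for (c0 in c_starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(a0, b0, c0), lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12 ||
        (abs(rss - best$rss) <= 1e-12 && fit$par[2] < best$par[2])) {
      best <- list(par = fit$par, rss = rss)
    }
  }

  identifiable <- diff(range(y)) >= flat_range
  if (is.null(best)) {
    # all starts failed: fall back to a flat curve at the mean response
    a_flat <- max(0, min(100, mean(y)))
    params <- logistic4p(a = a_flat, b = 1, c = mean(range(x)), d = 0)
    rss <- sum((y - a_flat)^2)
    return(structure(list(params = params, rss = rss,
                          r2 = .r_squared(y, rss), converged = FALSE,
                          identifiable = FALSE, n = length(x)),
                     class = "fit_result"))
  }
  params <- logistic4p(a = best$par[1], b = max(best$par[2], 1e-3),
                       c = best$par[3], d = 0)
  structure(list(params = params, rss = best$rss,
                 r2 = .r_squared(y, best$rss), converged = TRUE,
                 identifiable = identifiable, n = length(x)),
            class = "fit_result")
}

.r_squared <- function(y, rss) {
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) return(if (rss <= 1e-12) 1 else -Inf)
  1 - rss / tss
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("4PL fit (n=%d): rss=%.4g r2=%.4f converged=%s identifiable=%s\n",
              x$n, x$rss, x$r2, x$converged, x$identifiable))
  print(x$params)
  invisible(x)
}

#' Potency summaries from a fitted curve
#'
#' The relative EC50 is the inflection concentration `10^c`. The absolute
#' IC50 is the concentration at which the fitted curve crosses 50 percent
#' inhibition,
#' \deqn{IC_{50} = 10^{\,c - (1/b)\log_{10}(a/50 - 1)},}
#' defined only when the top asymptote exceeds 50 (otherwise the curve never
#' reaches half-maximal inhibition and `NA` is returned).
#'
#' @param fit A `fit_result` from [fit_logistic()].
#' @return List with `ec50` (molar), `ic50_abs` (molar or `NA` when not
#'   reached), and `reliable` (`FALSE` for unidentifiable fits).
#' @export
potency <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  if (!fit$converged) stop("potency: fit did not converge")
  p <- fit$params
  ec50 <- 10^p$c
  ic50 <- if (p$a > 50) 10^(p$c - (1 / p$b) * log10(p$a / 50 - 1)) else NA_real_
  list(ec50 = ec50, ic50_abs = ic50, reliable = isTRUE(fit$identifiable))
}
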