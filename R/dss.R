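#' Drug sensitivity score configuration
#'
#' The DSS integrates the fitted dose-response curve above a minimum
#' activity threshold `t` over a log10 molar concentration window, then
#' normalizes by the maximal attainable area. With 5-point, 10-fold dilution
#' series the default window is the tested 4-log-unit range.
#'
#' @param t Minimum activity threshold, percent inhibition (default 10).
#' @param x_min,x_max Integration window on the log10 molar axis.
#' @param variant `"DSS2"` (default, area further divided by `log10(a)`,
#'   keeping scores on the ~0-50 scale on which the DSS >= 10 effectiveness
#'   cutoff operates) or `"DSS1"`.
#' @return A `dss_config` list.
#' @export
dss_config <- function(t = 10, x_min = -9, x_max = -5, variant = "DSS2") {
  stopifnot(t >= 0, t < 100, x_min < x_max)
  variant <- match.arg(variant, c("DSS2", "DSS1"))
  structure(list(t = t, x_min = x_min, x_max = x_max, variant = variant),
            class = "dss_config")
}

#' Closed-form drug sensitivity score
#'
#' Computes the area of the fitted 4PL curve above the activity threshold
#' analytically. With bottom fixed at 0 the curve is
#' \eqn{y(x) = a / (1 + 10^{b(c-x)})}; it crosses the threshold `t` at
#' \eqn{x_t = c - (1/b)\log_{10}(a/t - 1)} and the area above `t` from
#' \eqn{x_1 = \max(x_{min}, x_t)} to \eqn{x_{max}} is
#' \deqn{I = \frac{a}{b}\left[\log_{10}(1+10^{b(x_{max}-c)}) -
#'   \log_{10}(1+10^{b(x_1-c)})\right] - t\,(x_{max}-x_1).}
#' DSS1 normalizes by the maximal area
#' \eqn{(100-t)(x_{max}-x_{min})} (scaled to 0-100); DSS2 further divides by
#' `log10(a)`. A curve whose top asymptote does not exceed `t` scores 0, and
#' under DSS2 tops at or below 1.01 score 0 (the `log10(a) <= 0` region is
#' meaningless and always below threshold).
#'
#' @param p A [logistic4p()] with `d = 0` and `a <= 100`.
#' @param cfg A [dss_config()].
#' @return A `dss_result` list: `dss`, `area` (raw area above threshold,
#'   %·log10 units), `x1` (lower integration limit used), `variant`, `config`.
#' @examples
#' dss_closed_form(logistic4p(80, 1, -7), dss_config())
#' @export
dss_closed_form <- function(p, cfg = dss_config()) {
  stopifnot(inherits(p, "logistic4p"), inherits(cfg, "dss_config"))
  if (p$d != 0) stop("dss_closed_form: bottom asymptote must be 0")
  if (p$a > 100) stop("dss_closed_form: top asymptote must be <= 100")
  a <- p$a; b <- p$b; cc <- p$c; t <- cfg$t
  if (a <= t || (cfg$variant == "DSS2" && a <= 1.01)) {
    return(structure(list(dss = 0, area = 0, x1 = cfg$x_max,
                          variant = cfg$variant, config = cfg),
                     class = "dss_result"))
  }
  x_t <- cc - (1 / b) * log10(a / t - 1)
  x1 <- min(max(cfg$x_min, x_t), cfg$x_max)
  area <- (a / b) * (log10(1 + 10^(b * (cfg$x_max - cc))) -
                     log10(1 + 10^(b * (x1 - cc)))) -
          t * (cfg$x_max - x1)
  area <- max(area, 0)
  dss1 <- 100 * area / ((100 - t) * (cfg$x_max - cfg$x_min))
  dss <- if (cfg$variant == "DSS1") dss1 else dss1 / log10(a)
  structure(list(dss = max(dss, 0), area = area, x1 = x1,
                 variant = cfg$variant, config = cfg),
            class = "dss_result")
}

#' Numeric-quadrature drug sensitivity score (verification oracle)
#'
#' Same normalization as [dss_closed_form()] but the area above threshold is
#' computed by the trapezoid rule on \eqn{\max(y - t, 0)} over a dense grid.
#' Kept as an independent route for validating the closed form.
#'
#' @inheritParams dss_closed_form
#' @param n_grid Number of grid points (>= 1000).
#' @return The score (single number).
#' @export
dss_numeric <- function(p, cfg = dss_config(), n_grid = 1e5) {
  stopifnot(inherits(p, "logistic4p"), inherits(cfg, "dss_config"),
            n_grid >= 1000)
  if (p$a <= cfg$t || (cfg$variant == "DSS2" && p$a <= 1.01)) return(0)
  x <- seq(cfg$x_min, cfg$x_max, length.out = n_grid)
  f <- pmax(predict_inhibition(p, x) - cfg$t, 0)
  h <- (cfg$x_max - cfg$x_min) / (n_grid - 1)
  area <- h * (sum(f) - (f[1] + f[n_grid]) / 2)
  dss1 <- 100 * area / ((100 - cfg$t) * (cfg$x_max - cfg$x_min))
  max(if (cfg$variant == "DSS1") dss1 else dss1 / log10(p$a), 0)
}

#' Selective drug sensitivity score
#'
#' Difference between a tumor model's DSS and the DSS of the same compound
#' in the healthy-control model screened under an identical configuration.
#' Negative values flag compounds more toxic to the control than the tumor.
#'
#' @param dss_tumor,dss_control `dss_result` objects (or bare scores with
#'   `check_config = FALSE`).
#' @param check_config Require identical scoring configurations (default).
#' @return The selective score, a single number.
#' @export
sdss <- function(dss_tumor, dss_control, check_config = TRUE) {
  if (inherits(dss_tumor, "dss_result") && inherits(dss_control, "dss_result")) {
    if (check_config && !identical(dss_tumor$config, dss_control$config))
      stop("sdss: tumor and control scores were computed under different ",
           "configurations; rescore with a shared dss_config")
    return(dss_tumor$dss - dss_control$dss)
  }
  if (check_config)
    stop("sdss: bare numeric scores carry no configuration; ",
         "pass dss_result objects or set check_config = FALSE")
  as.numeric(dss_tumor) - as.numeric(dss_control)
}

#' Z-prime factor screen quality statistic
#'
#' \deqn{Z' = 1 - \frac{3(\sigma_{pos} + \sigma_{neg})}{|\mu_{pos} - \mu_{neg}|}}
#' with sample standard deviations, comparing the positive-control (killed)
#' and negative-control (DMSO) well populations of a plate. Values above 0.5
#' indicate an excellent assay window.
#'
#' @param neg,pos Numeric vectors of raw signals for negative (DMSO) and
#'   positive control wells; at least 2 values each.
#' @return A `zprime` list: `z`, `mu_neg`, `sd_neg`, `mu_pos`, `sd_pos`,
#'   `n_neg`, `n_pos`.
#' @examples
#' zfactor(rnorm(32, 10000, 300), rnorm(32, 400, 50))$z
#' @export
zfactor <- function(neg, pos) {
  neg <- as.numeric(neg); pos <- as.numeric(pos)
  if (length(neg) < 2 || length(pos) < 2)
    stop("zfactor: need >= 2 wells per control group")
  mu_n <- mean(neg); mu_p <- mean(pos)
  if (mu_n == mu_p)
    stop("zfactor: control means are equal; Z' undefined")
  z <- 1 - 3 * (stats::sd(pos) + stats::sd(neg)) / abs(mu_p - mu_n)
  structure(list(z = z, mu_neg = mu_n, sd_neg = stats::sd(neg),
                 mu_pos = mu_p, sd_pos = stats::sd(pos),
                 n_neg = length(neg), n_pos = length(pos)),
            class = "zprime")
}

#' @export
print.zprime <- function(x, ...) {
  cat(sprintf("Z' = %.3f  (neg: %.4g +/- %.3g, n=%d; pos: %.4g +/- %.3g, n=%d)\n",
              x$z, x$mu_neg, x$sd_neg, x$n_neg, x$mu_pos, x$sd_pos, x$n_pos))
  invisible(x)
}
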