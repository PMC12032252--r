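#' Minimum cross-entropy (MCE) automatic threshold
#'
#' Li-style binarization threshold: for a candidate threshold `T`, pixels
#' split into background (`g < T`, mean `mu_b`) and foreground (`g >= T`,
#' mean `mu_f`), and the cross entropy
#' \deqn{CE(T) = \sum_{g<T} g\,h(g)\log\frac{g}{\mu_b(T)} +
#'              \sum_{g\ge T} g\,h(g)\log\frac{g}{\mu_f(T)}}
#' is minimized by exhaustive search over the observed gray levels (terms
#' with `g = 0` vanish in the limit and contribute nothing). Exhaustive
#' search guarantees the global minimum rather than the local fixed point of
#' the iterative scheme; ties go to the smallest threshold.
#'
#' @param channel Numeric matrix (or vector) of non-negative intensities
#'   with at least 2 distinct gray levels.
#' @return The threshold value; pixels `>= threshold` are foreground.
#' @examples
#' img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
#' mce_threshold(img)
#' @export
mce_threshold <- function(channel) {
  g <- as.numeric(channel)
  g <- g[is.finite(g)]
  if (!length(g)) stop("mce_threshold: no finite pixels")
  if (any(g < 0)) stop("mce_threshold: intensities must be non-negative")
  u <- sort(unique(g))
  if (length(u) < 2)
    stop("mce_threshold: constant image, threshold undefined")
  h <- tabulate(match(g, u), length(u))
  w <- u * h                       # intensity mass per level
  glg <- ifelse(u > 0, w * log(u), 0)

  cs_h <- cumsum(h);   cs_w <- cumsum(w);   cs_glg <- cumsum(glg)
  tot_h <- cs_h[length(u)]; tot_w <- cs_w[length(u)]; tot_glg <- cs_glg[length(u)]

  # candidate thresholds u[k], k = 2..K: background = levels 1..k-1
  k <- 2:length(u)
  sb_h <- cs_h[k - 1]; sb_w <- cs_w[k - 1]; sb_glg <- cs_glg[k - 1]
  sf_h <- tot_h - sb_h; sf_w <- tot_w - sb_w; sf_glg <- tot_glg - sb_glg
  mu_b <- sb_w / sb_h; mu_f <- sf_w / sf_h
  ce <- (sb_glg - sb_w * ifelse(mu_b > 0, log(mu_b), 0)) +
        (sf_glg - sf_w * ifelse(mu_f > 0, log(mu_f), 0))
  u[k[which.min(ce)]]
}
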