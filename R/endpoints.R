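#' Caliper tumor volume
#'
#' Standard ellipsoid approximation from two caliper diameters:
#' \deqn{TV\,(mm^3) = \frac{L \times W^2}{2}}
#' with `L` the longest and `W` the shortest diameter. If width exceeds
#' length the two are swapped with a warning (the formula assumes the
#' ordering).
#'
#' @param length_mm,width_mm Positive caliper diameters in mm (vectorized).
#' @return Tumor volume(s) in mm^3.
#' @examples
#' tumor_volume(10, 5)  # 125
#' @export
tumor_volume <- function(length_mm, width_mm) {
  if (any(!is.finite(length_mm)) || any(!is.finite(width_mm)) ||
      any(length_mm <= 0) || any(width_mm <= 0))
    stop("tumor_volume: diameters must be positive and finite")
  swap <- width_mm > length_mm
  if (any(swap)) {
    warning("tumor_volume: width > length for ", sum(swap),
            " measurement(s); swapping")
    tmp <- length_mm[swap]
    length_mm[swap] <- width_mm[swap]
    width_mm[swap] <- tmp
  }
  length_mm * width_mm^2 / 2
}

#' Treated-versus-control tumor volume ratio
#'
#' Antitumoral effect at a timepoint: the ratio of mean tumor volume in the
#' treated arm to the mean in the control arm.
#'
#' @param treated,control Numeric tumor volumes (mm^3), one value per animal.
#' @return The T/C ratio (dimensionless).
#' @export
tc_ratio <- function(treated, control) {
  if (!length(treated) || !length(control))
    stop("tc_ratio: need >= 1 animal per group")
  mc <- mean(control)
  if (mc == 0) stop("tc_ratio: control group mean volume is zero")
  mean(treated) / mc
}

#' Relative expression by the 2^-ddCt method
#'
#' Normalizes a target gene's Ct to the reference genes (the arithmetic mean
#' of reference Cts, equivalent to the log of the geometric mean of the
#' linear quantities) within each condition, then expresses the treated
#' condition relative to control:
#' \deqn{\Delta Ct = \overline{Ct}_{target} - \overline{Ct}_{refs}, \quad
#'   fold = 2^{-(\Delta Ct_{treated} - \Delta Ct_{control})}}
#'
#' @param ct Data.frame with columns `condition`, `gene`, `ct` (technical
#'   replicates as repeated rows).
#' @param target Target gene name.
#' @param refs Reference gene names (default the Cyclophilin/GAPDH/PPIB
#'   trio).
#' @param treated,control Condition labels.
#' @return List with `fold`, `ddct`, and per-condition `dct`.
#' @examples
#' ct <- data.frame(
#'   condition = rep(c("si", "nt"), each = 4),
#'   gene = rep(c("KIF11", "Cyclophilin", "GAPDH", "PPIB"), 2),
#'   ct = c(24.3, 20, 19, 21, 22, 20, 19, 21))
#' ddct_fold(ct, "KIF11", treated = "si", control = "nt")$fold
#' @export
ddct_fold <- function(ct, target, refs = c("Cyclophilin", "GAPDH", "PPIB"),
                      treated, control) {
  stopifnot(all(c("condition", "gene", "ct") %in% names(ct)))
  dct_of <- function(cond) {
    sub <- ct[ct$condition == cond, , drop = FALSE]
    if (!any(sub$gene == target))
      stop("ddct_fold: target gene '", target, "' not measured in condition '",
           cond, "'")
    ref_means <- vapply(refs, function(g) {
      v <- sub$ct[sub$gene == g]
      if (!length(v))
        stop("ddct_fold: reference gene '", g,
             "' not measured in condition '", cond, "'")
      mean(v)
    }, numeric(1))
    mean(sub$ct[sub$gene == target]) - mean(ref_means)
  }
  dct_t <- dct_of(treated); dct_c <- dct_of(control)
  ddct <- dct_t - dct_c
  list(fold = 2^(-ddct), ddct = ddct,
       dct = c(stats::setNames(dct_t, treated), stats::setNames(dct_c, control)))
}

#' Two-sample Student's t-test
#'
#' Two-sided, equal-variance by default (classic Student's test, pooled
#' variance, `df = nA + nB - 2`); Welch's unequal-variance form available
#' behind a flag. A thin wrapper over [stats::t.test()] returning the three
#' quantities the endpoint tables need.
#'
#' @param a,b Numeric vectors, >= 2 values each.
#' @param welch Use Welch's correction instead of pooled variance.
#' @return List with `t`, `df`, `p`.
#' @export
ttest_two <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop("ttest_two: need >= 2 values per group")
  res <- stats::t.test(a, b, var.equal = !welch, alternative = "two.sided")
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Relative viability / caspase readout
#'
#' Confirmatory assays are reported relative to control: the treated group's
#' mean signal as a fraction of the control mean, alongside the percent
#' decrease `100 * (1 - fraction)` (the scale on which e.g. an 80% viability
#' drop is reported).
#'
#' @param treated,control Numeric readouts (ATP luminescence, caspase
#'   activity, ...).
#' @return List with `fraction`, `fold` (same number, named for the
#'   increase direction), and `percent_decrease`.
#' @export
relative_signal <- function(treated, control) {
  if (!length(control) || mean(control) <= 0)
    stop("relative_signal: control mean must be positive")
  fr <- mean(treated) / mean(control)
  list(fraction = fr, fold = fr, percent_decrease = 100 * (1 - fr))
}
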