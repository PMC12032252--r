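#' Score a full screen: normalization, curve fits, DSS, sDSS, plate QC
#'
#' Runs the complete scoring chain over a set of plates: per-plate control
#' statistics and percent-inhibition normalization, per-compound dose-series
#' extraction, constrained 4PL fitting, closed-form DSS, and — when a
#' healthy-control model is present — the selective score
#' `sDSS = DSS(tumor) - DSS(control)` per compound and tumor model.
#' Z-prime is computed per plate from its own control wells.
#'
#' @param plate_maps List of plate maps ([read_plate_map()] objects or raw
#'   tables).
#' @param raw_plates List of raw plates, parallel to `plate_maps`.
#' @param control_model Model id of the healthy-control screen, or `NULL`
#'   when no selectivity scoring is wanted.
#' @param dss_cfg A [dss_config()]; when `NULL` the integration window
#'   defaults to each series' tested range (identical across series for a
#'   shared library layout).
#' @return List with `scores` (data.frame: one row per compound x model with
#'   fitted `a`, `b`, `c`, `d`, `rss`, `r2`, `converged`, `identifiable`,
#'   `ec50`, `ic50_abs`, `dss`, `dss_variant`, `sdss`), `plate_qc`
#'   (data.frame with per-plate Z-prime and control stats), `series` (the
#'   extracted dose series, keyed `"<compound>@<model>"`), and `dss_cfg`.
#' @examples
#' sim <- simulate_screen(screen_sim_config(n_compounds = 6, n_models = 1,
#'                                          noise_cv = 0))
#' res <- score_screen(sim$plate_maps, sim$raw_plates, sim$control_model)
#' head(res$scores)
#' @export
score_screen <- function(plate_maps, raw_plates, control_model = NULL,
                         dss_cfg = NULL) {
  stopifnot(length(plate_maps) == length(raw_plates))
  inhib <- list(); qc <- list()
  for (i in seq_along(plate_maps)) {
    map <- plate_maps[[i]]
    if (!inherits(map, "plate_map")) map <- read_plate_map(map)
    raw <- raw_plates[[i]]
    if (!inherits(raw, "raw_plate")) raw <- read_raw_plate(raw, map)
    cs <- control_stats(map, raw)
    sig <- stats::setNames(raw$signal, raw$well)
    zp <- zfactor(sig[map$well[map$content_type == "neg_control"]],
                  sig[map$well[map$content_type == "pos_control"]])
    qc[[i]] <- data.frame(plate_id = attr(map, "plate_id"),
                          model_id = attr(map, "model_id"),
                          z = zp$z, mu_neg = cs$mu_neg, sd_neg = cs$sd_neg,
                          mu_pos = cs$mu_pos, sd_pos = cs$sd_pos,
                          stringsAsFactors = FALSE)
    inhib[[i]] <- percent_inhibition(map, raw, cs)
  }
  inhib <- do.call(rbind, inhib)
  series <- extract_dose_series(inhib)

  rows <- lapply(series, function(s) {
    fit <- fit_logistic(s)
    cfg <- if (is.null(dss_cfg))
      dss_config(x_min = min(s$x), x_max = max(s$x)) else dss_cfg
    dres <- dss_closed_form(fit$params, cfg)
    pot <- if (fit$converged) potency(fit) else
      list(ec50 = NA_real_, ic50_abs = NA_real_)
    data.frame(compound_id = s$compound_id, model_id = s$model_id,
               a = fit$params$a, b = fit$params$b, c = fit$params$c,
               d = fit$params$d, rss = fit$rss, r2 = fit$r2,
               converged = fit$converged, identifiable = fit$identifiable,
               ec50 = pot$ec50, ic50_abs = pot$ic50_abs,
               dss = dres$dss, dss_variant = dres$variant,
               stringsAsFactors = FALSE)
  })
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL

  scores$sdss <- NA_real_
  if (!is.null(control_model) && control_model %in% scores$model_id) {
    ctrl <- scores[scores$model_id == control_model, , drop = FALSE]
    ctrl_dss <- stats::setNames(ctrl$dss, ctrl$compound_id)
    is_tum <- scores$model_id != control_model
    scores$sdss[is_tum] <- scores$dss[is_tum] -
      ctrl_dss[scores$compound_id[is_tum]]
  }
  list(scores = scores, plate_qc = do.call(rbind, qc), series = series,
       dss_cfg = dss_cfg)
}
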