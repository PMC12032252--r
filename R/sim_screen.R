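#' Screen simulator configuration
#'
#' Describes a synthetic multi-dose viability screen: a compound library
#' laid out on 384-well plates (one model per plate, compounds columnwise,
#' DMSO negative controls in the two leftmost columns, killed positive
#' controls in the two rightmost), screened against `n_models` tumor models
#' plus one healthy-control model. Raw luminescence for a compound well is
#' `baseline * (1 - PI_true/100) * eps` with `eps` multiplicative lognormal
#' noise of the given coefficient of variation (luminescence is positive and
#' right-skewed); negative wells sit at `baseline * eps`, positive wells at
#' `floor * eps`.
#'
#' @param n_compounds Library size (default 60: one full plate per model).
#' @param n_models Number of tumor models (a control model is always added).
#' @param doses_per_compound Concentrations per compound (default 5).
#' @param dilution_factor Fold dilution between consecutive doses (default 10).
#' @param top_concentration Highest tested concentration, molar (default 1e-5).
#' @param frac_active Fraction of compounds with a true dose response.
#' @param frac_selective Fraction of active compounds with no activity in the
#'   control model.
#' @param noise_cv Coefficient of variation of the multiplicative signal noise.
#' @param baseline_signal,floor_signal DMSO-level and killed-level
#'   luminescence (units of the plate reader).
#' @param drift Optional linear row/column signal drift amplitude (fraction
#'   of baseline peak-to-peak; 0 disables it). Provided to stress plate QC.
#' @param seed Integer seed; all simulator randomness flows from it.
#' @return A `screen_sim_config` list.
#' @export
screen_sim_config <- function(n_compounds = 60, n_models = 3,
                              doses_per_compound = 5, dilution_factor = 10,
                              top_concentration = 1e-5,
                              frac_active = 0.4, frac_selective = 0.5,
                              noise_cv = 0.05,
                              baseline_signal = 10000, floor_signal = 400,
                              drift = 0, seed = 1) {
  stopifnot(n_compounds >= 1, n_models >= 1,
            doses_per_compound >= 2, dilution_factor > 1,
            frac_active >= 0, frac_active <= 1,
            frac_selective >= 0, frac_selective <= 1,
            noise_cv >= 0, floor_signal < baseline_signal,
            floor_signal > 0, drift >= 0)
  if (doses_per_compound > 16)
    stop("screen_sim_config: a dose series cannot exceed one plate column (16 wells)")
  structure(as.list(environment()), class = "screen_sim_config")
}

# restore the caller's RNG state afterwards; all simulator draws flow from
# one seed
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# lognormal multiplier with mean 1 and coefficient of variation cv
.lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a multi-dose drug screen with planted ground truth
#'
#' Plants a true 4PL curve per compound and model, lays the library out on
#' 384-well plates, and renders noisy raw luminescence. Active compounds get
#' a randomly drawn curve (top asymptote 30-100, slope 0.7-2.5, log10 EC50
#' inside the tested window) in every tumor model; the selective subset is
#' flat in the control model while the rest keep their activity there.
#' Inactive compounds are flat everywhere. The planted truth records the
#' true parameters and the true DSS evaluated in closed form over the tested
#' concentration window.
#'
#' @param cfg A [screen_sim_config()].
#' @return List with `plate_maps` (list of plate-map tables), `raw_plates`
#'   (list of raw signal tables), `truth` (data.frame: one row per compound
#'   x model with true `a`, `b`, `c`, `true_dss`, `active`, `selective`),
#'   `models` (tumor model ids), `control_model`, `dss_cfg` (the scoring
#'   window implied by the dose range), and `cfg`.
#' @examples
#' sim <- simulate_screen(screen_sim_config(n_compounds = 6, noise_cv = 0))
#' head(sim$truth)
#' @export
simulate_screen <- function(cfg = screen_sim_config()) {
  stopifnot(inherits(cfg, "screen_sim_config"))
  .with_seed(cfg$seed, {
    nd <- cfg$doses_per_compound
    conc <- cfg$top_concentration / cfg$dilution_factor^((nd - 1):0)
    xg <- log10(conc)
    dss_cfg <- dss_config(x_min = min(xg), x_max = max(xg))

    models <- sprintf("tumor_%02d", seq_len(cfg$n_models))
    all_models <- c(models, "control")
    ids <- sprintf("CPD-%03d", seq_len(cfg$n_compounds))

    n_active <- round(cfg$frac_active * cfg$n_compounds)
    active <- ids %in% sample(ids, n_active)
    act_ids <- ids[active]
    n_sel <- round(cfg$frac_selective * n_active)
    selective <- ids %in% sample(act_ids, n_sel)

    # planted curves: one independent draw per compound x model
    truth <- do.call(rbind, lapply(ids, function(id) {
      rows <- lapply(all_models, function(m) {
        is_ctrl <- m == "control"
        flat <- !active[ids == id] || (is_ctrl && selective[ids == id])
        if (flat) {
          a <- 0; b <- 1; cc <- mean(range(xg))
        } else {
          a <- stats::runif(1, 30, 100)
          b <- stats::runif(1, 0.7, 2.5)
          cc <- stats::runif(1, min(xg) + 0.5, max(xg) - 0.5)
        }
        true_dss <- if (a == 0) 0 else
          dss_closed_form(logistic4p(a, b, cc), dss_cfg)$dss
        data.frame(compound_id = id, model_id = m, a = a, b = b, c = cc,
                   true_dss = true_dss, active = active[ids == id] && !flat,
                   selective = selective[ids == id],
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }))

    layout <- .library_layout(ids, conc)
    plate_maps <- list(); raw_plates <- list()
    for (m in all_models) {
      for (p in unique(layout$plate)) {
        pid <- sprintf("%s_P%02d", m, p)
        lay <- layout[layout$plate == p, , drop = FALSE]
        map <- .plate_map_table(pid, m, lay)
        plate_maps[[pid]] <- map
        raw_plates[[pid]] <- .render_raw(map, truth, cfg)
      }
    }
    list(plate_maps = plate_maps, raw_plates = raw_plates, truth = truth,
         models = models, control_model = "control", dss_cfg = dss_cfg,
         cfg = cfg)
  })
}

# columnwise placement: compound columns 3..22 (0-based 2..21), each holding
# floor(16/doses) series stacked top-down; controls occupy the outer-adjacent
# columns (neg: cols 1-2, pos: cols 23-24)
.library_layout <- function(ids, conc) {
  nd <- length(conc)
  per_col <- 16L %/% nd
  per_plate <- 20L * per_col
  out <- lapply(seq_along(ids), function(i) {
    k <- i - 1L
    plate <- k %/% per_plate + 1L
    within <- k %% per_plate
    col <- 2L + within %/% per_col
    slot <- within %% per_col
    data.frame(compound_id = ids[i], plate = plate,
               row = slot * nd + seq_len(nd) - 1L, col = col,
               concentration_molar = conc, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.plate_map_table <- function(plate_id, model_id, lay) {
  ctrl_rows <- 0:15
  neg <- expand.grid(row = ctrl_rows, col = 0:1)
  pos <- expand.grid(row = ctrl_rows, col = 22:23)
  map <- rbind(
    data.frame(well = rc_to_well(lay$row, lay$col), content_type = "compound",
               compound_id = lay$compound_id,
               concentration_molar = lay$concentration_molar),
    data.frame(well = rc_to_well(neg$row, neg$col), content_type = "neg_control",
               compound_id = "DMSO", concentration_molar = NA_real_),
    data.frame(well = rc_to_well(pos$row, pos$col), content_type = "pos_control",
               compound_id = "BzCl", concentration_molar = NA_real_))
  map <- data.frame(plate_id = plate_id, map, model_id = model_id,
                    stringsAsFactors = FALSE)
  read_plate_map(map)
}

.render_raw <- function(map, truth, cfg) {
  n <- nrow(map)
  pi_true <- numeric(n)
  is_cpd <- map$content_type == "compound"
  if (any(is_cpd)) {
    key <- paste0(map$compound_id[is_cpd], "@", map$model_id[is_cpd])
    tkey <- paste0(truth$compound_id, "@", truth$model_id)
    idx <- match(key, tkey)
    stopifnot(!anyNA(idx))
    pars <- truth[idx, , drop = FALSE]
    x <- log10(map$concentration_molar[is_cpd])
    # bottom is fixed at 0 in the generative model
    pi_true[is_cpd] <- mapply(function(a, b, cc, xx)
      if (a == 0) 0 else a / (1 + 10^(b * (cc - xx))),
      pars$a, pars$b, pars$c, x)
  }
  # expected signal interpolates the control anchors: PI = 0 sits at the
  # DMSO baseline, PI = 100 at the positive-control floor, so control-based
  # normalization recovers the planted inhibition exactly at zero noise
  mean_sig <- rep(cfg$baseline_signal, n)
  mean_sig[is_cpd] <- cfg$floor_signal +
    (cfg$baseline_signal - cfg$floor_signal) * (1 - pi_true[is_cpd] / 100)
  mean_sig[map$content_type == "pos_control"] <- cfg$floor_signal
  if (cfg$drift > 0) {
    g <- (map$row / 15 + map$col / 23) / 2
    mean_sig <- mean_sig * (1 + cfg$drift * (g - 0.5))
  }
  sig <- mean_sig * .lognoise(n, cfg$noise_cv)
  read_raw_plate(data.frame(plate_id = map$plate_id, well = map$well,
                            signal = sig, stringsAsFactors = FALSE))
}

#' Deterministic fixture screen with documented planted hit sets
#'
#' A small zero-noise screen of 24 compounds against two tumor models and
#' one healthy-control model, with hand-planted curves giving known hit
#' sets:
#' * 8 compounds selectively active in both tumor models (flat in control),
#' * 4 selective only in `tumor_01`, 2 selective only in `tumor_02`,
#' * 2 effective in both tumors but equally active in control (not
#'   selective),
#' * 2 strongly active in tumors and toxic to the control at low doses
#'   (the control curve crosses 50 percent inhibition below the top dose),
#' * 6 inactive everywhere.
#'
#' The truth data.frame carries the exact planted parameters and closed-form
#' DSS; `planted_sets` lists the compound ids of each documented group, with
#' effectiveness/selectivity derived from the planted scores at the standard
#' thresholds (DSS >= 10, sDSS >= 10).
#'
#' @return As [simulate_screen()], plus `planted_sets`.
#' @export
make_fixture_screen <- function() {
  ids <- sprintf("FIX-%02d", 1:24)
  grp <- c(rep("sel_both", 8), rep("sel_t1", 4), rep("sel_t2", 2),
           rep("eff_nonsel", 2), rep("toxic_low", 2), rep("inactive", 6))
  strong <- list(a = 90, b = 1.5, c = -7.5)   # DSS2 well above 10
  weak   <- list(a = 0,  b = 1,   c = -7)     # flat
  ctrl_toxic <- list(a = 60, b = 2, c = -8.5) # >50% PI at the 2nd-lowest dose

  curve_for <- function(g, model) {
    switch(g,
      sel_both   = if (model == "control") weak else strong,
      sel_t1     = if (model == "tumor_01") strong else weak,
      sel_t2     = if (model == "tumor_02") strong else weak,
      eff_nonsel = strong,
      toxic_low  = if (model == "control") ctrl_toxic
                   else list(a = 100, b = 2, c = -8.5),
      inactive   = weak)
  }

  conc <- 1e-5 / 10^(4:0)
  xg <- log10(conc)
  dss_cfg <- dss_config(x_min = min(xg), x_max = max(xg))
  all_models <- c("tumor_01", "tumor_02", "control")

  truth <- do.call(rbind, lapply(seq_along(ids), function(i) {
    do.call(rbind, lapply(all_models, function(m) {
      p <- curve_for(grp[i], m)
      true_dss <- if (p$a == 0) 0 else
        dss_closed_form(logistic4p(p$a, p$b, p$c), dss_cfg)$dss
      data.frame(compound_id = ids[i], model_id = m, group = grp[i],
                 a = p$a, b = p$b, c = p$c, true_dss = true_dss,
                 active = p$a > 0, selective = grp[i] %in%
                   c("sel_both", "sel_t1", "sel_t2"),
                 stringsAsFactors = FALSE)
    }))
  }))

  cfg <- screen_sim_config(n_compounds = 24, n_models = 2, noise_cv = 0,
                           seed = 424243)
  layout <- .library_layout(ids, conc)
  plate_maps <- list(); raw_plates <- list()
  for (m in all_models) {
    pid <- sprintf("%s_P01", m)
    map <- .plate_map_table(pid, m, layout)
    plate_maps[[pid]] <- map
    raw_plates[[pid]] <- .render_raw(map, truth, cfg)
  }

  # planted hit sets derive from the planted curves and closed-form scores
  # at the standard thresholds, so recovery tests compare pipeline output
  # against truth, not against construction labels
  ctrl <- truth[truth$model_id == "control", , drop = FALSE]
  ctrl_dss <- stats::setNames(ctrl$true_dss, ctrl$compound_id)
  tum <- truth[truth$model_id != "control", , drop = FALSE]
  tum$true_sdss <- tum$true_dss - ctrl_dss[tum$compound_id]
  sel_by_model <- lapply(split(tum, tum$model_id), function(d)
    sort(d$compound_id[d$true_sdss >= 10]))
  below_top <- xg[-length(xg)]
  toxic <- vapply(seq_len(nrow(ctrl)), function(i) {
    if (ctrl$a[i] == 0) return(FALSE)
    any(predict_inhibition(logistic4p(ctrl$a[i], ctrl$b[i], ctrl$c[i]),
                           below_top) >= 50)
  }, logical(1))
  planted_sets <- list(
    groups = split(ids, grp),
    effective = lapply(split(tum, tum$model_id), function(d)
      sort(d$compound_id[d$true_dss >= 10])),
    selective = sel_by_model,
    selective_in_all = sort(Reduce(intersect, sel_by_model)),
    low_dose_toxic = sort(ctrl$compound_id[toxic]))

  list(plate_maps = plate_maps, raw_plates = raw_plates, truth = truth,
       models = c("tumor_01", "tumor_02"), control_model = "control",
       dss_cfg = dss_cfg, cfg = cfg, planted_sets = planted_sets)
}
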