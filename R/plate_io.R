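#' @title Well address helpers (384-well geometry)
#' @description 384-well plates are 16 rows (A-P) by 24 columns (1-24).
#'   Addresses are letter+number ("A01"); internally rows/cols are 0-based.
#' @param well Character vector of well addresses, e.g. `"A01"`, `"P24"`.
#' @return `well_to_rc`: data.frame with 0-based `row` and `col`;
#'   `rc_to_well`: character addresses.
#' @export
well_to_rc <- function(well) {
  well <- toupper(trimws(well))
  ok <- grepl("^[A-P]([0-9]{1,2})$", well)
  if (any(!ok))
    stop("malformed well address(es): ", paste(unique(well[!ok]), collapse = ", "))
  row <- match(substr(well, 1, 1), LETTERS[1:16]) - 1L
  col <- as.integer(sub("^[A-P]", "", well)) - 1L
  if (any(col < 0L | col > 23L))
    stop("well column out of 1-24 range: ",
         paste(unique(well[col < 0L | col > 23L]), collapse = ", "))
  data.frame(row = row, col = col)
}

#' @rdname well_to_rc
#' @param row,col 0-based row (0-15) and column (0-23) indices.
#' @export
rc_to_well <- function(row, col) {
  stopifnot(all(row >= 0 & row <= 15), all(col >= 0 & col <= 23))
  sprintf("%s%02d", LETTERS[row + 1L], col + 1L)
}

#' Read and validate a plate-map table
#'
#' A plate map assigns every used well of a 384-well plate a content type
#' (`compound`, `neg_control`, `pos_control`, `empty`), and for compound
#' wells a compound id and molar concentration. Exactly one model is screened
#' per plate.
#'
#' @param table A data.frame with columns `plate_id`, `well`, `content_type`,
#'   `compound_id`, `concentration_molar`, `model_id`, or a path to such a
#'   CSV file.
#' @return A `plate_map`: validated data.frame with 0-based `row`/`col`
#'   added, plus attributes `plate_id` and `model_id`.
#' @export
read_plate_map <- function(table) {
  if (is.character(table) && length(table) == 1)
    table <- utils::read.csv(table, stringsAsFactors = FALSE)
  req <- c("plate_id", "well", "content_type", "compound_id",
           "concentration_molar", "model_id")
  miss <- setdiff(req, names(table))
  if (length(miss))
    stop("plate map is missing column(s): ", paste(miss, collapse = ", "))
  if (length(unique(table$plate_id)) != 1)
    stop("plate map must describe exactly one plate; found: ",
         paste(unique(table$plate_id), collapse = ", "))
  if (length(unique(table$model_id)) != 1)
    stop("plate ", table$plate_id[1], ": exactly one model per plate; found: ",
         paste(unique(table$model_id), collapse = ", "))
  dup <- table$well[duplicated(table$well)]
  if (length(dup))
    stop("plate ", table$plate_id[1], ": duplicate well(s): ",
         paste(unique(dup), collapse = ", "))
  bad_type <- setdiff(unique(table$content_type),
                      c("compound", "neg_control", "pos_control", "empty"))
  if (length(bad_type))
    stop("unknown content_type(s): ", paste(bad_type, collapse = ", "))
  rc <- well_to_rc(table$well)
  is_cpd <- table$content_type == "compound"
  conc <- suppressWarnings(as.numeric(table$concentration_molar))
  if (any(is_cpd & (!is.finite(conc) | conc <= 0))) {
    bad <- table$well[is_cpd & (!is.finite(conc) | conc <= 0)]
    stop("plate ", table$plate_id[1],
         ": compound wells need a positive molar concentration: ",
         paste(bad, collapse = ", "))
  }
  out <- data.frame(plate_id = table$plate_id, well = table$well,
                    row = rc$row, col = rc$col,
                    content_type = table$content_type,
                    compound_id = table$compound_id,
                    concentration_molar = conc,
                    model_id = table$model_id,
                    stringsAsFactors = FALSE)
  structure(out, class = c("plate_map", "data.frame"),
            plate_id = table$plate_id[1], model_id = table$model_id[1])
}

#' Read and validate a raw signal table
#'
#' @param table A data.frame with columns `plate_id`, `well`, `signal`
#'   (luminescence, finite and non-negative), or a path to a CSV file.
#' @param map Optional [read_plate_map()] result; if given, every mapped
#'   non-empty well must carry a signal.
#' @return A `raw_plate` data.frame (`plate_id`, `well`, `signal`).
#' @export
read_raw_plate <- function(table, map = NULL) {
  if (is.character(table) && length(table) == 1)
    table <- utils::read.csv(table, stringsAsFactors = FALSE)
  req <- c("plate_id", "well", "signal")
  miss <- setdiff(req, names(table))
  if (length(miss))
    stop("raw plate is missing column(s): ", paste(miss, collapse = ", "))
  sig <- suppressWarnings(as.numeric(table$signal))
  bad <- !is.finite(sig) | sig < 0
  if (any(bad))
    stop("non-numeric or negative signal in well(s): ",
         paste(table$well[bad], collapse = ", "))
  well_to_rc(table$well)  # validates addresses
  if (!is.null(map)) {
    need <- map$well[map$content_type != "empty"]
    absent <- setdiff(need, table$well)
    if (length(absent))
      stop("raw plate ", table$plate_id[1], " is missing mapped well(s): ",
           paste(absent, collapse = ", "))
  }
  structure(data.frame(plate_id = table$plate_id, well = table$well,
                       signal = sig, stringsAsFactors = FALSE),
            class = c("raw_plate", "data.frame"))
}

#' Per-plate control statistics
#'
#' Means and sample standard deviations of the plate's own DMSO
#' (negative) and killed (positive) control wells. Normalization is strictly
#' per plate: plates are the batch unit and controls are never pooled across
#' plates.
#'
#' @param map A [read_plate_map()] result.
#' @param raw A [read_raw_plate()] result for the same plate.
#' @return A `control_stats` list: `mu_neg`, `sd_neg`, `mu_pos`, `sd_pos`,
#'   `n_neg`, `n_pos`.
#' @export
control_stats <- function(map, raw) {
  sig <- stats::setNames(raw$signal, raw$well)
  neg <- sig[map$well[map$content_type == "neg_control"]]
  pos <- sig[map$well[map$content_type == "pos_control"]]
  neg <- neg[is.finite(neg)]; pos <- pos[is.finite(pos)]
  if (length(neg) < 2)
    stop("plate ", attr(map, "plate_id"), ": fewer than 2 negative-control wells")
  if (length(pos) < 2)
    stop("plate ", attr(map, "plate_id"), ": fewer than 2 positive-control wells")
  structure(list(mu_neg = mean(neg), sd_neg = stats::sd(neg),
                 mu_pos = mean(pos), sd_pos = stats::sd(pos),
                 n_neg = length(neg), n_pos = length(pos)),
            class = "control_stats")
}

#' Per-well percent inhibition
#'
#' Control-anchored normalization of raw luminescence:
#' \deqn{PI(w) = 100\,\frac{\mu_{neg} - S_w}{\mu_{neg} - \mu_{pos}}}
#' so DMSO-level signal maps to 0 and positive-control (fully killed) level
#' to 100. Values are deliberately not clamped here; clamping happens via
#' the curve-fit constraints downstream. Control wells are excluded from the
#' output.
#'
#' @inheritParams control_stats
#' @param stats A [control_stats()] result (computed from `map`/`raw` when
#'   omitted).
#' @return Data.frame of compound wells: `plate_id`, `well`, `compound_id`,
#'   `concentration_molar`, `model_id`, `signal`, `pi`.
#' @export
percent_inhibition <- function(map, raw, stats = NULL) {
  if (is.null(stats)) stats <- control_stats(map, raw)
  if (stats$mu_neg == stats$mu_pos)
    stop("plate ", attr(map, "plate_id"),
         ": degenerate plate, control means are equal")
  sig <- stats::setNames(raw$signal, raw$well)
  cw <- map[map$content_type == "compound", , drop = FALSE]
  s <- sig[cw$well]
  data.frame(plate_id = cw$plate_id, well = cw$well,
             compound_id = cw$compound_id,
             concentration_molar = cw$concentration_molar,
             model_id = cw$model_id, signal = as.numeric(s),
             pi = 100 * (stats$mu_neg - as.numeric(s)) /
                  (stats$mu_neg - stats$mu_pos),
             stringsAsFactors = FALSE)
}

#' Collect per-compound dose series
#'
#' Groups normalized wells by compound and model into ascending
#' log10-concentration series. Replicate wells at the same dose are averaged
#' on the percent-inhibition scale (keeping per-plate normalization
#' coherent). Series with fewer than 2 distinct doses are skipped with a
#' warning.
#'
#' @param inhib Row-bound output of [percent_inhibition()] across plates.
#' @return Named list of `dose_series` objects (list with `compound_id`,
#'   `model_id`, `x` = log10 molar ascending, `pi`), named
#'   `"<compound>@<model>"`.
#' @export
extract_dose_series <- function(inhib) {
  stopifnot(all(c("compound_id", "model_id", "concentration_molar", "pi")
                %in% names(inhib)))
  key <- paste0(inhib$compound_id, "@", inhib$model_id)
  out <- list()
  for (k in unique(key)) {
    sub <- inhib[key == k, , drop = FALSE]
    x_all <- log10(sub$concentration_molar)
    xs <- sort(unique(x_all))
    if (length(xs) < 2) {
      warning("series ", k, " has fewer than 2 distinct doses; skipped")
      next
    }
    pi_mean <- vapply(xs, function(v) mean(sub$pi[x_all == v]), numeric(1))
    out[[k]] <- structure(list(compound_id = sub$compound_id[1],
                               model_id = sub$model_id[1],
                               x = xs, pi = pi_mean),
                          class = "dose_series")
  }
  out
}

#' Write plate tables to CSV
#'
#' Round-trip companions of [read_plate_map()] / [read_raw_plate()].
#'
#' @param map,raw Plate map / raw plate objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_map <- function(map, path) {
  utils::write.csv(map[, c("plate_id", "well", "content_type", "compound_id",
                           "concentration_molar", "model_id")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plate_map
#' @export
write_raw_plate <- function(raw, path) {
  utils::write.csv(raw[, c("plate_id", "well", "signal")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
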