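#' Flag effective and selective compounds
#'
#' Applies the screen's selection thresholds to scored rows: a compound is
#' *effective* in a model when `dss >= dss_threshold` and *selective* when
#' `sdss >= sdss_threshold` (both inclusive, the convention under which a
#' score of exactly 10 counts as a hit). Rows without a selective score
#' (e.g. the control model itself, or a missing control screen) get
#' `selective = NA` and are marked unevaluable.
#'
#' @param scores Data.frame with at least `compound_id`, `model_id`, `dss`,
#'   `sdss` (the `scores` element of [score_screen()]).
#' @param dss_threshold,sdss_threshold Inclusive thresholds (default 10).
#' @return The input with logical columns `effective`, `selective` and
#'   `sdss_unevaluable` added.
#' @export
call_hits <- function(scores, dss_threshold = 10, sdss_threshold = 10) {
  stopifnot(all(c("compound_id", "model_id", "dss") %in% names(scores)))
  if (is.null(scores$sdss)) scores$sdss <- NA_real_
  scores$effective <- scores$dss >= dss_threshold
  scores$selective <- ifelse(is.na(scores$sdss), NA,
                             scores$sdss >= sdss_threshold)
  scores$sdss_unevaluable <- is.na(scores$sdss)
  scores
}

#' Low-dose toxicity rule
#'
#' Flags compounds that inhibit the healthy-control model strongly already
#' at sub-maximal concentrations. The default rule: control percent
#' inhibition at or above `control_pi_threshold` at any tested dose strictly
#' below the top concentration. Such compounds may still pass the sDSS
#' cutoff yet are poor candidates; the rule reports a flag, never a silent
#' removal.
#'
#' @param control_series A `dose_series` of the compound in the control
#'   model (see [extract_dose_series()]).
#' @param control_pi_threshold Percent inhibition threshold (default 50).
#' @param dose_scope `"below_top_dose"` (default) restricts the check to
#'   doses strictly below the top concentration; `"any_dose"` checks all.
#' @return `TRUE`/`FALSE`, or `NA` when no control series is available.
#' @export
low_dose_toxicity_flag <- function(control_series, control_pi_threshold = 50,
                                   dose_scope = c("below_top_dose", "any_dose")) {
  dose_scope <- match.arg(dose_scope)
  if (is.null(control_series)) return(NA)
  stopifnot(control_pi_threshold > 0, control_pi_threshold <= 100)
  x <- control_series$x; pi <- control_series$pi
  if (dose_scope == "below_top_dose") {
    keep <- x < max(x)
    x <- x[keep]; pi <- pi[keep]
  }
  if (!length(pi)) return(FALSE)
  any(pi >= control_pi_threshold)
}

#' Summarize hit calls across models
#'
#' Per-model counts of effective and selective compounds, the union and
#' intersection of the selective sets across tumor models (the Venn view),
#' and the top-N compounds per model ranked by selective score with ties
#' broken by compound id.
#'
#' @param hits Output of [call_hits()].
#' @param models Character vector of tumor model ids to summarize (defaults
#'   to all models with a selective score).
#' @param n_top Size of the per-model ranking (default 10).
#' @return List with `counts` (data.frame per model), `selective_in_any`,
#'   `selective_in_all` (sorted compound id vectors), `top` (named list of
#'   data.frames), and `control_toxic_count` when a `low_dose_toxic` column
#'   is present.
#' @export
summarize_hits <- function(hits, models = NULL, n_top = 10) {
  stopifnot(all(c("compound_id", "model_id", "effective", "selective")
                %in% names(hits)))
  evaluable <- hits[!is.na(hits$selective), , drop = FALSE]
  if (is.null(models)) models <- sort(unique(evaluable$model_id))
  unknown <- setdiff(models, hits$model_id)
  if (length(unknown))
    stop("summarize_hits: unknown model(s): ", paste(unknown, collapse = ", "))

  by_model <- lapply(models, function(m)
    evaluable[evaluable$model_id == m, , drop = FALSE])
  names(by_model) <- models

  counts <- do.call(rbind, c(list(
    data.frame(model_id = character(0), n_compounds = integer(0),
               n_effective = integer(0), n_selective = integer(0))),
    lapply(models, function(m) {
      d <- by_model[[m]]
      data.frame(model_id = m, n_compounds = nrow(d),
                 n_effective = sum(d$effective, na.rm = TRUE),
                 n_selective = sum(d$selective, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    })))

  sel_sets <- lapply(by_model, function(d) sort(d$compound_id[d$selective]))
  sel_any <- sort(Reduce(union, sel_sets, accumulate = FALSE))
  sel_all <- if (length(sel_sets)) sort(Reduce(intersect, sel_sets))
             else character(0)

  top <- lapply(by_model, function(d) {
    d <- d[order(-d$sdss, d$compound_id), , drop = FALSE]
    utils::head(d[, intersect(c("compound_id", "model_id", "dss", "sdss",
                                "effective", "selective"), names(d))], n_top)
  })

  out <- list(counts = counts, selective_in_any = sel_any,
              selective_in_all = sel_all, top = top)
  if ("low_dose_toxic" %in% names(hits)) {
    tox <- unique(hits$compound_id[isTRUE_vec(hits$low_dose_toxic)])
    out$control_toxic <- sort(tox)
    out$control_toxic_count <- length(tox)
  }
  out
}

# vectorized isTRUE: NA-safe logical
isTRUE_vec <- function(x) !is.na(x) & x

#' Annotate hit rows with the low-dose toxicity flag
#'
#' Convenience wrapper applying [low_dose_toxicity_flag()] to every
#' compound's control-model dose series and joining the flag onto the hit
#' table.
#'
#' @param hits Output of [call_hits()].
#' @param series Named series list from [score_screen()] (`"<compound>@<model>"`).
#' @param control_model Control model id.
#' @inheritParams low_dose_toxicity_flag
#' @return `hits` with a logical `low_dose_toxic` column.
#' @export
annotate_toxicity <- function(hits, series, control_model,
                              control_pi_threshold = 50,
                              dose_scope = "below_top_dose") {
  key <- paste0(hits$compound_id, "@", control_model)
  hits$low_dose_toxic <- vapply(key, function(k)
    low_dose_toxicity_flag(series[[k]], control_pi_threshold, dose_scope),
    logical(1))
  hits
}
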