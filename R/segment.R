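#' Segmentation configuration
#'
#' @param min_diameter_px,max_diameter_px Equivalent-circular-diameter
#'   bounds for retained nuclei (defaults 40 and 240 px; objects outside
#'   are discarded). "Diameter" is the diameter of the circle with the
#'   object's area, `sqrt(4A/pi)`.
#' @param maxima_min_distance Minimum separation (px) between distance
#'   transform peaks used as watershed markers.
#' @param propagation_lambda Regularization weight of the propagation-based
#'   cell segmentation (0 = purely intensity-guided; larger values weight
#'   spatial distance more).
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(min_diameter_px = 40, max_diameter_px = 240,
                                maxima_min_distance = 20,
                                propagation_lambda = 0.05) {
  stopifnot(min_diameter_px > 0, min_diameter_px < max_diameter_px,
            maxima_min_distance >= 1, propagation_lambda >= 0)
  structure(list(min_diameter_px = min_diameter_px,
                 max_diameter_px = max_diameter_px,
                 maxima_min_distance = maxima_min_distance,
                 propagation_lambda = propagation_lambda),
            class = "segmentation_config")
}

# distance-transform peaks at least min_dist apart, as a marker label image:
# local maxima plateaus are labeled, then components are greedily accepted in
# order of decreasing peak height (ties by label) and suppressed within
# min_dist of an accepted peak
.distance_markers <- function(dist, min_dist) {
  brush_size <- 2 * floor(min_dist / 2) + 1  # odd
  dil <- EBImage::dilate(dist, EBImage::makeBrush(max(brush_size, 3), "disc"))
  is_max <- (dist >= dil) & (dist > 0)
  comp <- EBImage::bwlabel(EBImage::Image(is_max + 0))
  comp <- .as_mat(comp)
  n <- max(comp)
  if (n == 0) return(matrix(0L, nrow(dist), ncol(dist)))
  peaks <- do.call(rbind, lapply(seq_len(n), function(k) {
    idx <- which(comp == k, arr.ind = TRUE)
    data.frame(label = k, r = mean(idx[, 1]), c = mean(idx[, 2]),
               h = max(dist[comp == k]))
  }))
  peaks <- peaks[order(-peaks$h, peaks$label), , drop = FALSE]
  acc <- peaks[0, ]
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    if (!nrow(acc) ||
        all(sqrt((acc$r - p$r)^2 + (acc$c - p$c)^2) >= min_dist))
      acc <- rbind(acc, p)
  }
  out <- matrix(0L, nrow(dist), ncol(dist))
  for (i in seq_len(nrow(acc)))
    out[comp == acc$label[i]] <- i
  out
}

# unwrap an EBImage Image to a plain matrix
.as_mat <- function(x) {
  if (inherits(x, "Image")) EBImage::imageData(x) else x
}

#' Segment nuclei by marker-based watershed
#'
#' The DNA (Hoechst) channel is binarized by minimum cross-entropy
#' thresholding, the binary foreground is distance transformed, local maxima
#' of the distance map (separated by at least `maxima_min_distance`) seed a
#' marker-based watershed on the negated distance map restricted to the
#' foreground, the label image is masked with the binary, and objects with
#' equivalent diameter outside `[min_diameter_px, max_diameter_px]` are
#' discarded. Surviving labels are compacted to 1..n.
#'
#' @param dna Numeric matrix, DNA channel intensities.
#' @param cfg A [segmentation_config()].
#' @return Integer label matrix (0 background). Empty foreground gives an
#'   all-zero mask, not an error.
#' @export
segment_nuclei <- function(dna, cfg = segmentation_config()) {
  stopifnot(is.matrix(dna) || inherits(dna, "Image"))
  dna <- .as_mat(dna)
  if (length(unique(as.numeric(dna))) < 2)
    return(matrix(0L, nrow(dna), ncol(dna)))
  thr <- mce_threshold(dna)
  fg <- dna >= thr
  if (!any(fg)) return(matrix(0L, nrow(dna), ncol(dna)))
  dist <- .as_mat(EBImage::distmap(EBImage::Image(fg + 0)))
  markers <- .distance_markers(dist, cfg$maxima_min_distance)
  if (max(markers) == 0) return(matrix(0L, nrow(dna), ncol(dna)))
  lab <- .marker_watershed_cpp(-dist, markers, fg)
  lab[!fg] <- 0L
  filter_diameter(lab, cfg$min_diameter_px, cfg$max_diameter_px)
}

#' Filter labeled objects by equivalent circular diameter
#'
#' @param labels Integer label matrix.
#' @param min_d,max_d Diameter bounds in px (`sqrt(4A/pi)` from object area).
#' @return Label matrix with out-of-range objects removed and surviving
#'   labels compacted to 1..n (in order of their original labels).
#' @export
filter_diameter <- function(labels, min_d = 40, max_d = 240) {
  labels <- .as_mat(labels)
  mode(labels) <- "integer"
  if (max(labels) == 0) return(labels)
  areas <- tabulate(labels[labels > 0], max(labels))
  eqd <- sqrt(4 * areas / pi)
  keep <- which(areas > 0 & eqd >= min_d & eqd <= max_d)
  relab <- integer(max(labels))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(labels), ncol(labels))
  pos <- labels > 0
  out[pos] <- relab[labels[pos]]
  out
}

#' Segment cells by propagation from nuclei
#'
#' The ER channel is binarized by MCE thresholding and each foreground pixel
#' is assigned to the nucleus reachable at minimal accumulated cost, where a
#' step's cost combines the local intensity difference with the
#' regularization weight `propagation_lambda` (the propagate-style seeded
#' region growing of the Cell Painting tool family, via
#' [EBImage::propagate()]). Nucleus pixels always belong to their own cell:
#' the propagation mask is the union of the ER foreground and the nuclei, so
#' a nucleus outside the ER foreground becomes its own cell. Output labels
#' equal nucleus labels.
#'
#' @param nuclei Integer label matrix from [segment_nuclei()].
#' @param er Numeric matrix, endoplasmic-reticulum channel.
#' @param cfg A [segmentation_config()].
#' @return Integer label matrix of cells, labels matching `nuclei`.
#' @export
segment_cells <- function(nuclei, er, cfg = segmentation_config()) {
  nuclei <- .as_mat(nuclei); er <- .as_mat(er)
  stopifnot(all(dim(nuclei) == dim(er)))
  if (max(nuclei) == 0) return(matrix(0L, nrow(er), ncol(er)))
  thr <- mce_threshold(er)
  mask <- (er >= thr) | (nuclei > 0)
  lab <- EBImage::propagate(EBImage::Image(er), EBImage::Image(nuclei),
                            mask = mask, lambda = cfg$propagation_lambda)
  out <- .as_mat(lab)
  mode(out) <- "integer"
  out
}
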