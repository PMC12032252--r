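#' The single-cell feature catalog
#'
#' Names of every feature produced by [extract_features()], in stable order.
#' Per cell, three compartments (`nucleus`, `cell`, `cytoplasm` = cell minus
#' nucleus) are measured:
#' * intensity, per channel x compartment: mean, sd, mad, min, max,
#'   integrated, quantiles 5/10/25/50/75/90/95 (13 features x 4 channels x
#'   3 compartments = 156);
#' * texture, per channel x compartment: gray-level co-occurrence contrast,
#'   correlation, energy, homogeneity, entropy at pixel offsets 1 and 5,
#'   direction-averaged over 4 orientations on 16 requantized gray levels
#'   (10 x 4 x 3 = 120);
#' * shape, per compartment: area, perimeter, equivalent diameter,
#'   eccentricity, solidity, extent, form factor `4*pi*A/P^2`, major and
#'   minor axis length, connected-component count (10 x 3 = 30).
#'
#' 306 features in total; the catalog is deterministic across runs and
#' platforms.
#'
#' @return Character vector of feature names.
#' @export
feature_catalog <- function() {
  channels <- c("DNA", "ER", "AGP", "Mito")
  comps <- c("nucleus", "cell", "cytoplasm")
  int_f <- c("mean", "sd", "mad", "min", "max", "integrated",
             "q05", "q10", "q25", "q50", "q75", "q90", "q95")
  tex_f <- as.vector(outer(c("contrast", "correlation", "energy",
                             "homogeneity", "entropy"),
                           c("d1", "d5"), paste, sep = "_"))
  shp_f <- c("area", "perimeter", "equivalent_diameter", "eccentricity",
             "solidity", "extent", "form_factor", "major_axis", "minor_axis",
             "n_components")
  out <- character(0)
  for (ch in channels) for (cp in comps)
    out <- c(out, paste("int", ch, cp, int_f, sep = "_"))
  for (ch in channels) for (cp in comps)
    out <- c(out, paste("tex", ch, cp, tex_f, sep = "_"))
  for (cp in comps)
    out <- c(out, paste("shape", cp, shp_f, sep = "_"))
  out
}

.intensity_features <- function(v) {
  if (!length(v))
    return(c(mean = 0, sd = 0, mad = 0, min = 0, max = 0, integrated = 0,
             q05 = 0, q10 = 0, q25 = 0, q50 = 0, q75 = 0, q90 = 0, q95 = 0))
  q <- stats::quantile(v, c(.05, .10, .25, .50, .75, .90, .95), names = FALSE,
                       type = 7)
  c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
    mad = stats::mad(v), min = min(v), max = max(v), integrated = sum(v),
    q05 = q[1], q10 = q[2], q25 = q[3], q50 = q[4], q75 = q[5], q90 = q[6],
    q95 = q[7])
}

# shape descriptors of a pixel set given as arr.ind coordinates
.shape_features <- function(coords) {
  zero <- c(area = 0, perimeter = 0, equivalent_diameter = 0,
            eccentricity = 0, solidity = 0, extent = 0, form_factor = 0,
            major_axis = 0, minor_axis = 0, n_components = 0)
  if (is.null(coords) || !nrow(coords)) return(zero)
  a <- nrow(coords)
  r0 <- min(coords[, 1]); c0 <- min(coords[, 2])
  h <- max(coords[, 1]) - r0 + 1L; w <- max(coords[, 2]) - c0 + 1L
  m <- matrix(FALSE, h, w)
  m[cbind(coords[, 1] - r0 + 1L, coords[, 2] - c0 + 1L)] <- TRUE

  # perimeter: count of 4-neighbor object/background pixel edges
  pad <- matrix(FALSE, h + 2, w + 2); pad[2:(h + 1), 2:(w + 1)] <- m
  per <- sum(pad & !rbind(pad[-1, ], FALSE)) +
         sum(pad & !rbind(FALSE, pad[-(h + 2), ])) +
         sum(pad & !cbind(pad[, -1], FALSE)) +
         sum(pad & !cbind(FALSE, pad[, -(w + 2)]))

  # second central moments -> axis lengths and eccentricity
  cy <- mean(coords[, 1]); cx <- mean(coords[, 2])
  mu20 <- mean((coords[, 1] - cy)^2) + 1 / 12
  mu02 <- mean((coords[, 2] - cx)^2) + 1 / 12
  mu11 <- mean((coords[, 1] - cy) * (coords[, 2] - cx))
  tr2 <- (mu20 + mu02) / 2
  det_rt <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- tr2 + det_rt; l2 <- max(tr2 - det_rt, 0)
  ecc <- if (l1 > 0) sqrt(1 - l2 / l1) else 0

  # solidity via the convex hull of pixel centers (shoelace area + boundary
  # correction A + P/2 + 1 for the discrete hull)
  hull_area <- a
  if (a >= 3) {
    hp <- grDevices::chull(coords[, 2], coords[, 1])
    if (length(hp) >= 3) {
      hx <- coords[hp, 2]; hy <- coords[hp, 1]
      shoe <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
      hper <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
      hull_area <- max(shoe + hper / 2 + 1, a)
    }
  }
  ncomp <- max(EBImage::bwlabel(EBImage::Image(m + 0)))

  c(area = a, perimeter = per, equivalent_diameter = sqrt(4 * a / pi),
    eccentricity = ecc, solidity = a / hull_area, extent = a / (h * w),
    form_factor = if (per > 0) 4 * pi * a / per^2 else 0,
    major_axis = 4 * sqrt(l1), minor_axis = 4 * sqrt(l2),
    n_components = ncomp)
}

# direction-averaged gray-level co-occurrence statistics on 16 requantized
# levels at the given pixel offsets; constant regions give all-zero texture
.texture_features <- function(ch, coords, offsets = c(1L, 5L), n_levels = 16L) {
  nm <- as.vector(outer(c("contrast", "correlation", "energy", "homogeneity",
                          "entropy"), paste0("d", offsets), paste, sep = "_"))
  zero <- stats::setNames(numeric(length(nm)), nm)
  if (is.null(coords) || nrow(coords) < 2) return(zero)
  r0 <- min(coords[, 1]); c0 <- min(coords[, 2])
  h <- max(coords[, 1]) - r0 + 1L; w <- max(coords[, 2]) - c0 + 1L
  sub <- matrix(NA_real_, h, w)
  rc <- cbind(coords[, 1] - r0 + 1L, coords[, 2] - c0 + 1L)
  v <- ch[coords]
  rng <- range(v)
  if (diff(rng) == 0) return(zero)
  q <- pmin(floor((v - rng[1]) / diff(rng) * n_levels) + 1L, n_levels)
  sub[rc] <- q

  out <- numeric(0)
  for (d in offsets) {
    counts <- matrix(0, n_levels, n_levels)
    for (dir in list(c(0L, d), c(d, 0L), c(d, d), c(d, -d))) {
      dr <- dir[1]; dc <- dir[2]
      if (h <= abs(dr) || w <= abs(dc)) next
      ra <- (1 + max(0, -dr)):(h - max(0, dr))
      ca <- (1 + max(0, -dc)):(w - max(0, dc))
      A <- sub[ra, ca, drop = FALSE]
      B <- sub[ra + dr, ca + dc, drop = FALSE]
      ok <- !is.na(A) & !is.na(B)
      if (!any(ok)) next
      idx <- (A[ok] - 1) * n_levels + B[ok]
      tb <- tabulate(idx, n_levels^2)
      counts <- counts + matrix(tb, n_levels, n_levels, byrow = TRUE) +
        t(matrix(tb, n_levels, n_levels, byrow = TRUE))  # symmetric
    }
    tot <- sum(counts)
    if (tot == 0) { out <- c(out, zero[1:5]); next }
    P <- counts / tot
    i <- row(P); j <- col(P)
    mu_i <- sum(P * i); mu_j <- sum(P * j)
    sd_i <- sqrt(sum(P * (i - mu_i)^2)); sd_j <- sqrt(sum(P * (j - mu_j)^2))
    corr <- if (sd_i > 0 && sd_j > 0)
      sum(P * (i - mu_i) * (j - mu_j)) / (sd_i * sd_j) else 0
    pz <- P[P > 0]
    out <- c(out,
             contrast = sum(P * (i - j)^2), correlation = corr,
             energy = sum(P^2), homogeneity = sum(P / (1 + abs(i - j))),
             entropy = -sum(pz * log(pz)))
  }
  stats::setNames(out, nm)
}

#' Extract the single-cell morphological feature table
#'
#' Measures the full [feature_catalog()] (306 intensity, texture and shape
#' features) for every segmented cell of a four-channel field. Compartments
#' are the nucleus, the whole cell, and the cytoplasm (cell minus nucleus);
#' a cell whose nucleus fills it entirely gets all-zero cytoplasm features
#' and `cytoplasm_empty = TRUE`.
#'
#' @param channels Named list of numeric matrices (`DNA`, `ER`, `AGP`,
#'   `Mito`), identical shapes.
#' @param nuclei,cells Integer label matrices with matching labels (cell k
#'   contains nucleus k).
#' @param plate,well,treatment,dose Metadata recycled onto every row.
#' @return Data.frame: metadata columns (`plate`, `well`, `treatment`,
#'   `dose`, `cell_id`, `cytoplasm_empty`) followed by the catalog features;
#'   no missing values.
#' @export
extract_features <- function(channels, nuclei, cells,
                             plate = NA_character_, well = NA_character_,
                             treatment = NA_character_, dose = NA_real_) {
  stopifnot(all(c("DNA", "ER", "AGP", "Mito") %in% names(channels)))
  channels <- lapply(channels, .as_mat)
  nuclei <- .as_mat(nuclei); cells <- .as_mat(cells)
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, identical, logical(1), dim(cells))) ||
      !identical(dim(nuclei), dim(cells)))
    stop("extract_features: channel and mask shapes differ")
  labels <- sort(setdiff(unique(as.integer(cells)), 0L))
  cat_names <- feature_catalog()
  chn <- c("DNA", "ER", "AGP", "Mito")

  rows <- lapply(labels, function(k) {
    idx_cell <- which(cells == k)
    idx_nuc <- which(nuclei == k)
    idx_cyto <- setdiff(idx_cell, idx_nuc)
    comp_idx <- list(nucleus = idx_nuc, cell = idx_cell, cytoplasm = idx_cyto)
    comp_coords <- lapply(comp_idx, function(ii)
      if (length(ii)) arrayInd(ii, dim(cells)) else NULL)

    feats <- numeric(0)
    for (ch in chn) for (cp in names(comp_idx)) {
      f <- .intensity_features(channels[[ch]][comp_idx[[cp]]])
      names(f) <- paste("int", ch, cp, names(f), sep = "_")
      feats <- c(feats, f)
    }
    for (ch in chn) for (cp in names(comp_idx)) {
      f <- .texture_features(channels[[ch]], comp_coords[[cp]])
      names(f) <- paste("tex", ch, cp, names(f), sep = "_")
      feats <- c(feats, f)
    }
    for (cp in names(comp_idx)) {
      f <- .shape_features(comp_coords[[cp]])
      names(f) <- paste("shape", cp, names(f), sep = "_")
      feats <- c(feats, f)
    }
    feats <- feats[cat_names]
    stopifnot(!anyNA(feats))
    cbind(data.frame(plate = plate, well = well, treatment = treatment,
                     dose = dose, cell_id = k,
                     cytoplasm_empty = length(idx_cyto) == 0,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(feats)))
  })
  if (!length(rows)) {
    empty <- as.data.frame(matrix(numeric(0), 0, length(cat_names)))
    names(empty) <- cat_names
    return(cbind(data.frame(plate = character(0), well = character(0),
                            treatment = character(0), dose = numeric(0),
                            cell_id = integer(0), cytoplasm_empty = logical(0)),
                 empty))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
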