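#' Image simulator configuration
#'
#' Describes a synthetic four-channel Cell Painting field: ellipse-shaped
#' cells with elliptical nuclei (normal phenotype) or clusters of small
#' nuclear fragments (the fragmented, mitotic-catastrophe-like phenotype),
#' rendered into DNA / ER / AGP (membrane-actin-nucleic-acid composite) /
#' Mito channels, then degraded by Gaussian blur (point-spread proxy),
#' Poisson shot noise and Gaussian read noise. Ground-truth masks are the
#' pre-blur, pre-noise labels.
#'
#' @param field_shape Field size in pixels, `c(rows, cols)`.
#' @param n_cells Number of cells to place (>= 0).
#' @param nucleus_diameter_range Equivalent-diameter range of nuclei, px.
#' @param phenotype `"normal"` or `"fragmented"`.
#' @param fragments_per_nucleus Integer range of fragments per nucleus
#'   (fragmented phenotype only).
#' @param cell_scale Cell-body axes relative to the nucleus (default 1.6).
#' @param psf_sigma Gaussian blur sigma, px (0 disables).
#' @param poisson_scale Photons per intensity unit for shot noise (0
#'   disables).
#' @param gaussian_read_sd Additive read-noise SD, intensity units.
#' @param seed Integer seed.
#' @return An `image_sim_config` list.
#' @export
image_sim_config <- function(field_shape = c(512, 512), n_cells = 12,
                             nucleus_diameter_range = c(50, 150),
                             phenotype = c("normal", "fragmented"),
                             fragments_per_nucleus = c(3, 8),
                             cell_scale = 1.6,
                             psf_sigma = 1.5, poisson_scale = 0.5,
                             gaussian_read_sd = 2, seed = 1) {
  phenotype <- match.arg(phenotype)
  stopifnot(length(field_shape) == 2, all(field_shape >= 32), n_cells >= 0,
            length(nucleus_diameter_range) == 2,
            nucleus_diameter_range[1] > 0,
            nucleus_diameter_range[1] <= nucleus_diameter_range[2],
            length(fragments_per_nucleus) == 2,
            fragments_per_nucleus[1] >= 1, cell_scale >= 1,
            psf_sigma >= 0, poisson_scale >= 0, gaussian_read_sd >= 0)
  structure(as.list(environment()), class = "image_sim_config")
}

# pixel mask of a filled rotated ellipse on an nr x nc grid
.ellipse_mask <- function(nr, nc, cy, cx, ry, rx, theta) {
  y0 <- max(1, floor(cy - max(ry, rx) - 1)); y1 <- min(nr, ceiling(cy + max(ry, rx) + 1))
  x0 <- max(1, floor(cx - max(ry, rx) - 1)); x1 <- min(nc, ceiling(cx + max(ry, rx) + 1))
  if (y0 > y1 || x0 > x1) return(NULL)
  ys <- y0:y1; xs <- x0:x1
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  u <- dy * cos(theta) + dx * sin(theta)
  v <- -dy * sin(theta) + dx * cos(theta)
  inside <- (u / ry)^2 + (v / rx)^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  cbind(row = ys[idx[, 1]], col = xs[idx[, 2]])
}

#' Synthesize a four-channel Cell Painting field with ground truth
#'
#' Cells are placed by rejection sampling so that cell bodies do not
#' overlap; the placement fails with an error after bounded retries when
#' `n_cells` does not fit the field. Per cell, the DNA channel renders the
#' nucleus (one ellipse, or `fragments_per_nucleus` small non-touching
#' ellipses for the fragmented phenotype), ER and AGP render the textured
#' cell body (AGP with a bright membrane rim), and Mito renders punctate
#' spots inside the cell. Truth masks (nucleus and cell label images, one
#' label per cell, identical label sets) are recorded before blur and noise.
#'
#' @param cfg An [image_sim_config()].
#' @return List with `channels` (named list `DNA`, `ER`, `AGP`, `Mito` of
#'   numeric matrices), `truth` (list: `nuclei`, `cells` label matrices,
#'   `phenotype` per cell, `dna_pre_blur` pre-degradation DNA raster), and
#'   `cfg`.
#' @examples
#' f <- synthesize_image(image_sim_config(n_cells = 3, field_shape = c(256, 256),
#'                                        nucleus_diameter_range = c(40, 60)))
#' range(f$truth$nuclei)
#' @export
synthesize_image <- function(cfg = image_sim_config()) {
  stopifnot(inherits(cfg, "image_sim_config"))
  .with_seed(cfg$seed, {
    nr <- cfg$field_shape[1]; nc <- cfg$field_shape[2]
    dna <- matrix(2, nr, nc); er <- matrix(2, nr, nc)
    agp <- matrix(2, nr, nc); mito <- matrix(2, nr, nc)
    nuc_mask <- matrix(0L, nr, nc); cell_mask <- matrix(0L, nr, nc)

    placed <- data.frame(cy = numeric(0), cx = numeric(0), rmax = numeric(0))
    n_try <- 0; max_try <- max(200 * cfg$n_cells, 1000)
    k <- 0
    while (k < cfg$n_cells) {
      n_try <- n_try + 1
      if (n_try > max_try)
        stop("synthesize_image: could not place ", cfg$n_cells,
             " non-overlapping cells in a ", nr, "x", nc,
             " field after ", max_try, " attempts")
      de <- stats::runif(1, cfg$nucleus_diameter_range[1],
                         cfg$nucleus_diameter_range[2])
      aspect <- stats::runif(1, 0.7, 1)
      theta <- stats::runif(1, 0, pi)
      ry <- de / 2 / sqrt(aspect); rx <- de / 2 * sqrt(aspect)
      rcell <- max(ry, rx) * cfg$cell_scale
      cy <- stats::runif(1, rcell + 2, nr - rcell - 1)
      cx <- stats::runif(1, rcell + 2, nc - rcell - 1)
      if (nrow(placed) &&
          any(sqrt((placed$cy - cy)^2 + (placed$cx - cx)^2) <
              (placed$rmax + rcell + 2))) next
      k <- k + 1
      placed <- rbind(placed, data.frame(cy = cy, cx = cx, rmax = rcell))

      cell_px <- .ellipse_mask(nr, nc, cy, cx, ry * cfg$cell_scale,
                               rx * cfg$cell_scale, theta)
      cell_mask[cell_px] <- k
      # cell body: ER and AGP with smooth multiplicative texture
      tex <- 1 + 0.15 * sin(cell_px[, 1] / 7) * cos(cell_px[, 2] / 9)
      er[cell_px] <- 120 * tex
      agp[cell_px] <- 90 * tex
      # AGP membrane rim: pixels near the cell edge
      inner <- .ellipse_mask(nr, nc, cy, cx, ry * cfg$cell_scale - 3,
                             rx * cfg$cell_scale - 3, theta)
      if (!is.null(inner)) {
        rim_mask <- matrix(FALSE, nr, nc)
        rim_mask[cell_px] <- TRUE
        rim_mask[inner] <- FALSE
        agp[rim_mask] <- 180
      }

      # nucleus / fragments on the DNA channel
      if (cfg$phenotype == "normal") {
        nuc_px <- .ellipse_mask(nr, nc, cy, cx, ry, rx, theta)
        dna[nuc_px] <- 180
        nuc_mask[nuc_px] <- k
        agp[nuc_px] <- pmax(agp[nuc_px], 110)  # nucleic-acid component
      } else {
        nfrag <- if (cfg$fragments_per_nucleus[1] == cfg$fragments_per_nucleus[2])
          cfg$fragments_per_nucleus[1] else
          sample(cfg$fragments_per_nucleus[1]:cfg$fragments_per_nucleus[2], 1)
        rfrag <- de / 2 / sqrt(nfrag) * 0.42
        centers <- data.frame(fy = numeric(0), fx = numeric(0))
        tries <- 0
        while (nrow(centers) < nfrag && tries < 5000) {
          tries <- tries + 1
          ang <- stats::runif(1, 0, 2 * pi)
          rad <- sqrt(stats::runif(1)) * 0.85
          u <- rad * cos(ang) * (ry - rfrag - 1)
          v <- rad * sin(ang) * (rx - rfrag - 1)
          fy <- cy + u * cos(theta) - v * sin(theta)
          fx <- cx + u * sin(theta) + v * cos(theta)
          if (nrow(centers) &&
              any(sqrt((centers$fy - fy)^2 + (centers$fx - fx)^2) <
                  2 * rfrag + 1.5)) next
          centers <- rbind(centers, data.frame(fy = fy, fx = fx))
        }
        if (nrow(centers) < nfrag)
          stop("synthesize_image: could not place ", nfrag,
               " non-touching fragments inside a nucleus")
        for (i in seq_len(nfrag)) {
          fr <- .ellipse_mask(nr, nc, centers$fy[i], centers$fx[i],
                              rfrag, rfrag * stats::runif(1, 0.8, 1),
                              stats::runif(1, 0, pi))
          dna[fr] <- 180
          nuc_mask[fr] <- k
          agp[fr] <- pmax(agp[fr], 110)
        }
      }

      # punctate mitochondria in the cytoplasm
      cyto <- cell_px[nuc_mask[cell_px] == 0, , drop = FALSE]
      mito[cell_px] <- pmax(mito[cell_px], 15)
      if (nrow(cyto) > 4) {
        npt <- max(3, nrow(cyto) %/% 150)
        pts <- cyto[sample(nrow(cyto), npt), , drop = FALSE]
        for (i in seq_len(nrow(pts))) {
          yy <- pts[i, 1] + (-1:1); xx <- pts[i, 2] + (-1:1)
          yy <- yy[yy >= 1 & yy <= nr]; xx <- xx[xx >= 1 & xx <= nc]
          mito[as.matrix(expand.grid(yy, xx))] <- 200
        }
      }
    }

    dna_pre <- dna
    channels <- list(DNA = dna, ER = er, AGP = agp, Mito = mito)
    channels <- lapply(channels, .degrade, cfg = cfg)
    list(channels = channels,
         truth = list(nuclei = nuc_mask, cells = cell_mask,
                      phenotype = rep(cfg$phenotype, cfg$n_cells),
                      dna_pre_blur = dna_pre),
         cfg = cfg)
  })
}

# optical and detection degradation: blur, shot noise, read noise
.degrade <- function(x, cfg) {
  if (cfg$psf_sigma > 0)
    x <- .as_mat(EBImage::gblur(EBImage::Image(x), sigma = cfg$psf_sigma))
  if (cfg$poisson_scale > 0)
    x <- matrix(stats::rpois(length(x), pmax(x, 0) * cfg$poisson_scale) /
                  cfg$poisson_scale, nrow(x), ncol(x))
  if (cfg$gaussian_read_sd > 0)
    x <- x + matrix(stats::rnorm(length(x), 0, cfg$gaussian_read_sd),
                    nrow(x), ncol(x))
  pmax(x, 0)
}

#' Write / read a multi-channel field as per-channel TIFF files
#'
#' Files are named `<prefix>_<channel>.tiff` with the channel suffix
#' convention `DNA`, `ER`, `AGP`, `Mito`. Intensities are stored as 16-bit
#' after scaling by `scale`.
#'
#' @param channels Named list of numeric matrices.
#' @param prefix Path prefix.
#' @param scale Intensity units per 16-bit count (default 1/256 of range).
#' @return `write_channels`: the written paths; `read_channels`: named list
#'   of matrices.
#' @export
write_channels <- function(channels, prefix, scale = 2^16 - 1) {
  paths <- character(0)
  for (nm in names(channels)) {
    p <- paste0(prefix, "_", nm, ".tiff")
    img <- EBImage::Image(pmin(pmax(channels[[nm]], 0) / scale, 1))
    EBImage::writeImage(img, p, type = "tiff", bits.per.sample = 16L)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_channels
#' @param suffixes Channel suffixes to read.
#' @export
read_channels <- function(prefix, suffixes = c("DNA", "ER", "AGP", "Mito"),
                          scale = 2^16 - 1) {
  out <- lapply(suffixes, function(nm) {
    p <- paste0(prefix, "_", nm, ".tiff")
    if (!file.exists(p)) stop("missing channel file: ", p)
    .as_mat(EBImage::readImage(p)) * scale
  })
  stats::setNames(out, suffixes)
}
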