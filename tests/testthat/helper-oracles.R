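# Independent oracles and shared fixtures for the suite. Oracles are written
# from the defining formulas, not by calling the code paths they check.

# naive minimum-cross-entropy search: loop over candidate thresholds, compute
# the criterion directly from its definition on the observed gray levels
oracle_mce <- function(img) {
  g <- as.numeric(img)
  u <- sort(unique(g))
  best_t <- NA_real_; best_ce <- Inf
  for (k in 2:length(u)) {
    t <- u[k]
    b <- g[g < t]; f <- g[g >= t]
    mu_b <- mean(b); mu_f <- mean(f)
    ce <- 0
    for (v in b) if (v > 0) ce <- ce + v * log(v / mu_b)
    for (v in f) if (v > 0) ce <- ce + v * log(v / mu_f)
    if (ce < best_ce - 1e-12) { best_ce <- ce; best_t <- t }
  }
  best_t
}

# pooled-variance two-sample t-test from the textbook formulas
oracle_ttest <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# per-planted-object intersection-over-union against a segmentation
iou_per_object <- function(truth, seg) {
  vapply(seq_len(max(truth)), function(k) {
    tm <- truth == k
    labs <- seg[tm]; labs <- labs[labs > 0]
    if (!length(labs)) return(0)
    l <- as.integer(names(which.max(table(labs))))
    sm <- seg == l
    sum(tm & sm) / sum(tm | sm)
  }, numeric(1))
}

# arr.ind coordinates of a rasterized disc
disc_coords <- function(nr, nc, cy, cx, r) {
  which(outer((1:nr - cy)^2, (1:nc - cx)^2, "+") <= r^2, arr.ind = TRUE)
}

# random valid 4PL parameter draws for property tests
random_params <- function(n, seed) {
  set.seed(seed)
  data.frame(a = runif(n, 2, 100), b = runif(n, 0.2, 8),
             c = runif(n, -10, -4))
}

# heavy fixtures computed once per test session
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# a 20-cell field sized so nuclei of 60-120 px equivalent diameter fit
# without touching, plus its nuclei segmentation
seg_field <- function() cached("seg_field", {
  f <- synthesize_image(image_sim_config(
    field_shape = c(900, 900), n_cells = 20,
    nucleus_diameter_range = c(60, 120), phenotype = "normal", seed = 3))
  list(field = f, seg = segment_nuclei(f$channels$DNA))
})

# paired normal/fragmented fields for two models (one plate per model)
phenotype_fields <- function() cached("phenotype_fields", {
  out <- list()
  seeds <- list(m1 = c(normal = 11, fragmented = 12),
                m2 = c(normal = 13, fragmented = 14))
  for (m in names(seeds)) for (ph in c("normal", "fragmented")) {
    f <- synthesize_image(image_sim_config(
      field_shape = c(650, 650), n_cells = 6,
      nucleus_diameter_range = c(60, 100), phenotype = ph,
      fragments_per_nucleus = c(4, 6), seed = seeds[[m]][[ph]]))
    ft <- extract_features(f$channels, f$truth$nuclei, f$truth$cells,
                           plate = m, well = "A01",
                           treatment = if (ph == "normal") "DMSO" else "drug")
    ft$model <- m; ft$phenotype <- ph
    out[[paste(m, ph, sep = "_")]] <- ft
  }
  do.call(rbind, out)
})
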