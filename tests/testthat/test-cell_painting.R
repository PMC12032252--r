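test_that("MCE threshold separates bimodal images and equals the naive oracle", {
  two <- matrix(c(rep(10, 60), rep(200, 40)), 10, 10)
  thr <- mce_threshold(two)
  expect_gt(thr, 10); expect_lte(thr, 200)
  expect_true(all(two[two >= thr] == 200))
  expect_error(mce_threshold(matrix(7, 5, 5)), "constant")

  set.seed(30)
  mix <- round(pmin(pmax(c(rnorm(3000, 30, 10), rnorm(2000, 180, 10)), 0), 255))
  expect_equal(mce_threshold(mix), oracle_mce(mix))
})

test_that("nuclei segmentation recovers planted non-touching nuclei", {
  sf <- seg_field()
  expect_equal(max(sf$seg), 20)
  ious <- iou_per_object(sf$field$truth$nuclei, sf$seg)
  expect_true(all(ious >= 0.8))
})

test_that("the 40-240 px diameter filter removes undersized objects", {
  sf <- seg_field()
  dna <- sf$field$channels$DNA
  # paint a 30 px diameter nucleus into a free corner and re-segment
  dna[disc_coords(nrow(dna), ncol(dna), 20, 20, 15)] <- 180
  seg2 <- segment_nuclei(dna)
  expect_equal(max(seg2), 20)
  expect_true(all(seg2[1:40, 1:40] == 0))
  # the same image without the filter keeps 21 objects
  seg3 <- segment_nuclei(dna, segmentation_config(min_diameter_px = 1))
  expect_equal(max(seg3), 21)
  # all retained objects satisfy the diameter bounds
  areas <- tabulate(seg2[seg2 > 0], max(seg2))
  eqd <- sqrt(4 * areas / pi)
  expect_true(all(eqd >= 40 & eqd <= 240))
})

test_that("touching nuclei with two distance maxima split into two labels", {
  img <- matrix(2, 200, 200)
  img[disc_coords(200, 200, 100, 70, 32)] <- 180
  img[disc_coords(200, 200, 100, 130, 32)] <- 180  # overlap 60 px apart
  seg <- segment_nuclei(img, segmentation_config(maxima_min_distance = 15))
  expect_equal(max(seg), 2)
  # each disc center carries a distinct label
  expect_true(seg[100, 70] != seg[100, 130])
  expect_true(all(seg[100, c(70, 130)] > 0))
})

test_that("cell propagation partitions uniform foreground at the midline", {
  er <- matrix(2, 120, 160)
  er[20:100, 20:140] <- 100                      # uniform foreground slab
  nuc <- matrix(0L, 120, 160)
  nuc[disc_coords(120, 160, 60, 50, 10)] <- 1L
  nuc[disc_coords(120, 160, 60, 110, 10)] <- 2L
  cells <- segment_cells(nuc, er)
  # away from the equidistant boundary, label = nearer nucleus
  fg <- which(er >= 100, arr.ind = TRUE)
  d1 <- sqrt((fg[, 1] - 60)^2 + (fg[, 2] - 50)^2)
  d2 <- sqrt((fg[, 1] - 60)^2 + (fg[, 2] - 110)^2)
  clear <- abs(d1 - d2) > 4
  got <- cells[fg[clear, , drop = FALSE]]
  expect_true(all(got == ifelse(d1[clear] < d2[clear], 1L, 2L)))

  # single nucleus claims its whole connected foreground component
  nuc1 <- matrix(0L, 120, 160)
  nuc1[disc_coords(120, 160, 60, 80, 10)] <- 1L
  cells1 <- segment_cells(nuc1, er)
  expect_true(all(cells1[er >= 100] == 1L))
})

test_that("nuclei are always contained in their propagated cells", {
  sf <- seg_field()
  cells <- segment_cells(sf$seg, sf$field$channels$ER)
  nz <- sf$seg > 0
  expect_true(all(cells[nz] == sf$seg[nz]))
  expect_setequal(unique(as.integer(cells[cells > 0])),
                  unique(as.integer(sf$seg[nz])))
})

test_that("feature extraction matches pixel-level oracles on a uniform disk", {
  nr <- 80; nc <- 80
  coords <- disc_coords(nr, nc, 40, 40, 10)
  nuc <- matrix(0L, nr, nc); nuc[coords] <- 1L
  chan <- matrix(0, nr, nc); chan[coords] <- 7.5
  channels <- list(DNA = chan, ER = chan, AGP = chan, Mito = chan)
  ft <- extract_features(channels, nuc, nuc)   # cell == nucleus
  expect_equal(nrow(ft), 1)
  expect_equal(ft$int_DNA_nucleus_mean, 7.5)
  expect_equal(ft$int_DNA_nucleus_sd, 0)
  expect_equal(ft$int_DNA_nucleus_integrated, 7.5 * nrow(coords))
  expect_equal(ft$shape_nucleus_area, nrow(coords))   # brute-force pixel count
  expect_equal(ft$shape_nucleus_equivalent_diameter,
               sqrt(4 * nrow(coords) / pi))
  expect_lt(ft$shape_nucleus_eccentricity, 0.1)       # near-circular
  expect_true(ft$cytoplasm_empty)
  expect_equal(ft$int_DNA_cytoplasm_mean, 0)          # empty set convention
})

test_that("the feature catalog is large, unique, and deterministic", {
  cat1 <- feature_catalog()
  expect_gte(length(cat1), 300)
  expect_equal(anyDuplicated(cat1), 0)
  expect_identical(cat1, feature_catalog())
  ft <- phenotype_fields()
  expect_true(all(cat1 %in% names(ft)))
  expect_false(anyNA(ft[, cat1]))
})

test_that("plate-wise DMSO scaling centers controls and flags constants", {
  ft <- phenotype_fields()
  nz <- normalize_platewise(ft)
  for (p in unique(nz$plate)) {
    ref <- nz$plate == p & nz$treatment == "DMSO"
    flagged <- attr(nz, "flagged_constant")
    fl <- flagged$feature[flagged$plate == p]
    live <- setdiff(intersect(feature_catalog(), names(nz)), fl)
    mu <- colMeans(nz[ref, live]); sdv <- sapply(nz[ref, live], sd)
    expect_true(all(abs(mu) < 1e-9))
    expect_true(all(abs(sdv - 1) < 1e-9))
    expect_true(all(nz[nz$plate == p, fl] == 0))
  }
  # the hand case: f = 12 against DMSO mean 10, sample SD 4 gives z = 0.5
  f1 <- feature_catalog()[1]
  toy <- data.frame(plate = "P", treatment = c("DMSO", "DMSO", "DMSO", "drug"))
  toy[[f1]] <- c(6, 10, 14, 12)
  toyz <- normalize_platewise(toy)
  expect_equal(toyz[[f1]][4], 0.5)
  # a plate without DMSO cells errors by name
  bad <- ft; bad$treatment <- "drug"
  expect_error(normalize_platewise(bad), "m1")
})

test_that("the 2-D embedding is deterministic and separates planted blobs", {
  set.seed(61)
  X <- rbind(matrix(rnorm(45 * 8, 0), 45, 8), matrix(rnorm(45 * 8, 8), 45, 8))
  e1 <- embed_2d(X, seed = 7); e2 <- embed_2d(X, seed = 7)
  expect_identical(e1, e2)
  expect_equal(nrow(e1), 90)
  km <- kmeans(e1, 2, nstart = 10)
  truth <- rep(1:2, each = 45)
  acc <- max(mean(km$cluster == truth), mean(km$cluster == 3 - truth))
  expect_gte(acc, 0.95)
  expect_error(embed_2d(X[1:10, ], n_neighbors = 15), "n_neighbors")
})

test_that("profile clustering uses Euclidean average linkage deterministically", {
  ft <- data.frame(g = c("a", "a", "b", "c"))
  f1 <- feature_catalog()[1]; f2 <- feature_catalog()[2]
  ft[[f1]] <- c(0, 0, 3, 0); ft[[f2]] <- c(0, 0, 4, 0)
  cp <- cluster_profiles(ft, ft$g)
  expect_equal(as.matrix(cp$dist)["a", "b"], 5)       # 3-4-5 triangle
  expect_equal(as.matrix(cp$dist)["a", "c"], 0)       # duplicate profiles
  expect_equal(min(cp$hc$height), 0)                  # duplicates merge first

  # planted phenotypes separate into two pure clusters per model
  feats <- normalize_platewise(phenotype_fields())
  grp <- paste(feats$model, feats$phenotype, sep = "_")
  cpp <- cluster_profiles(feats, grp)
  k2 <- cutree(cpp$hc, 2)
  split_by <- split(names(k2), k2)
  phen <- lapply(split_by, function(g) unique(sub(".*_", "", g)))
  expect_true(all(lengths(phen) == 1))
  expect_setequal(unlist(phen), c("normal", "fragmented"))
})
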