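test_that("simulation is bit-identical under the same seed", {
  cfg <- screen_sim_config(n_compounds = 8, n_models = 1, noise_cv = 0.1,
                           seed = 99)
  s1 <- simulate_screen(cfg); s2 <- simulate_screen(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(lapply(s1$raw_plates, function(r) r$signal),
                   lapply(s2$raw_plates, function(r) r$signal))
})

test_that("zero-noise wells sit exactly on the generative anchors", {
  sim <- simulate_screen(screen_sim_config(n_compounds = 6, n_models = 1,
                                           noise_cv = 0, seed = 4))
  for (pid in names(sim$plate_maps)) {
    map <- sim$plate_maps[[pid]]; raw <- sim$raw_plates[[pid]]
    sig <- setNames(raw$signal, raw$well)
    expect_true(all(sig[map$well[map$content_type == "neg_control"]] == 10000))
    expect_true(all(sig[map$well[map$content_type == "pos_control"]] == 400))
    # compound wells interpolate the anchors by the planted inhibition
    cw <- map[map$content_type == "compound", ]
    key <- paste0(cw$compound_id, "@", map$model_id[1])
    tr <- sim$truth[match(key, paste0(sim$truth$compound_id, "@",
                                      sim$truth$model_id)), ]
    pi_true <- ifelse(tr$a == 0, 0,
      tr$a / (1 + 10^(tr$b * (tr$c - log10(cw$concentration_molar)))))
    expect_equal(unname(sig[cw$well]), 400 + 9600 * (1 - pi_true / 100),
                 tolerance = 1e-10)
  }
})

test_that("negative-control CV converges to the configured noise level", {
  sim <- simulate_screen(screen_sim_config(n_compounds = 180, n_models = 1,
                                           noise_cv = 0.08, seed = 21))
  neg <- unlist(lapply(names(sim$plate_maps), function(pid) {
    map <- sim$plate_maps[[pid]]
    sig <- setNames(sim$raw_plates[[pid]]$signal, sim$raw_plates[[pid]]$well)
    sig[map$well[map$content_type == "neg_control"]]
  }))
  cv <- sd(neg) / mean(neg)
  expect_gt(cv, 0.08 * 0.8); expect_lt(cv, 0.08 * 1.2)
})

test_that("every compound occupies the configured doses and controls are present", {
  cfg <- screen_sim_config(n_compounds = 70, n_models = 2, seed = 2)
  sim <- simulate_screen(cfg)
  for (pid in names(sim$plate_maps)) {
    map <- sim$plate_maps[[pid]]
    expect_gte(sum(map$content_type == "neg_control"), 16)
    expect_gte(sum(map$content_type == "pos_control"), 16)
    cnt <- table(map$compound_id[map$content_type == "compound"])
    expect_true(all(cnt == cfg$doses_per_compound))
  }
  # 70 compounds at 60 per plate -> 2 plates per model, 3 models incl. control
  expect_equal(length(sim$plate_maps), 6)
  expect_error(screen_sim_config(doses_per_compound = 20), "column")
})

test_that("the fixture screen regenerates byte-identically with documented sets", {
  f1 <- make_fixture_screen(); f2 <- make_fixture_screen()
  expect_identical(f1$truth, f2$truth)
  expect_identical(lapply(f1$raw_plates, function(r) r$signal),
                   lapply(f2$raw_plates, function(r) r$signal))
  expect_length(f1$planted_sets$selective_in_all, 10)
  expect_length(f1$planted_sets$groups$sel_both, 8)
  expect_true(all(f1$planted_sets$groups$sel_both %in%
                    f1$planted_sets$selective_in_all))
  expect_true(all(f1$planted_sets$groups$toxic_low %in%
                    f1$planted_sets$low_dose_toxic))
})

test_that("zero-noise fixture fits recover the planted parameters to 1e-4", {
  fx <- make_fixture_screen()
  res <- score_screen(fx$plate_maps, fx$raw_plates, fx$control_model)
  m <- merge(res$scores, fx$truth, by = c("compound_id", "model_id"),
             suffixes = c("_fit", "_true"))
  act <- m[m$a_true > 0, ]
  expect_equal(act$a_fit, act$a_true, tolerance = 1e-4)
  expect_equal(act$b_fit, act$b_true, tolerance = 1e-4)
  expect_equal(act$c_fit, act$c_true, tolerance = 1e-4)
})

test_that("image fields honor counts, masks and phenotype geometry", {
  # empty field
  f0 <- synthesize_image(image_sim_config(n_cells = 0, field_shape = c(128, 128),
                                          seed = 1))
  expect_equal(max(f0$truth$nuclei), 0)
  expect_equal(max(f0$truth$cells), 0)
  expect_true(all(f0$channels$DNA >= 0))

  f <- seg_field()$field
  expect_equal(max(f$truth$nuclei), 20)
  expect_equal(sort(unique(as.integer(f$truth$cells[f$truth$cells > 0]))), 1:20)
  # nuclei pixelwise inside their cells, same label
  nz <- f$truth$nuclei > 0
  expect_true(all(f$truth$cells[nz] == f$truth$nuclei[nz]))

  # fragmented: pre-blur DNA components per cell equal the fragment count
  ff <- synthesize_image(image_sim_config(
    field_shape = c(700, 700), n_cells = 5, phenotype = "fragmented",
    nucleus_diameter_range = c(70, 110), fragments_per_nucleus = c(5, 5),
    seed = 9))
  for (k in 1:5) {
    m <- (ff$truth$dna_pre_blur > 100) & (ff$truth$cells == k)
    comp <- EBImage::bwlabel(EBImage::Image(m + 0))
    expect_equal(max(comp), 5)
  }

  # overfull field fails with a placement error
  expect_error(synthesize_image(image_sim_config(
    field_shape = c(128, 128), n_cells = 30,
    nucleus_diameter_range = c(50, 60), seed = 1)), "could not place")
})
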