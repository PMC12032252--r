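map_df <- function() {
  data.frame(
    plate_id = "P1",
    well = c("A01", "A02", "B01", "B02", "C01", "C02", "C03"),
    content_type = c("compound", "compound", "neg_control", "neg_control",
                     "pos_control", "pos_control", "compound"),
    compound_id = c("X", "X", "DMSO", "DMSO", "BzCl", "BzCl", "Y"),
    concentration_molar = c(1e-7, 1e-6, NA, NA, NA, NA, 1e-7),
    model_id = "M1", stringsAsFactors = FALSE)
}

test_that("plate maps parse, index wells 0-based, and reject bad input", {
  m <- read_plate_map(map_df())
  expect_s3_class(m, "plate_map")
  expect_equal(m$row[m$well == "A01"], 0)
  expect_equal(m$col[m$well == "A01"], 0)
  expect_equal(attr(m, "model_id"), "M1")

  dup <- rbind(map_df(), map_df()[1, ])
  expect_error(read_plate_map(dup), "A01")
  bad <- map_df(); bad$concentration_molar[1] <- 0
  expect_error(read_plate_map(bad), "positive molar")
  two <- map_df(); two$model_id[1] <- "M2"
  expect_error(read_plate_map(two), "one model")
  expect_error(well_to_rc("Q01"), "malformed")
  expect_equal(rc_to_well(15, 23), "P24")
})

test_that("raw plates validate signals and completeness", {
  m <- read_plate_map(map_df())
  raw_df <- data.frame(plate_id = "P1", well = m$well,
                       signal = c(5200, 800, 9000, 11000, 400, 400, 7000))
  r <- read_raw_plate(raw_df, m)
  expect_equal(nrow(r), 7)
  expect_error(read_raw_plate(raw_df[-1, ], m), "A01")
  neg <- raw_df; neg$signal[1] <- -5
  expect_error(read_raw_plate(neg), "negative")
})

test_that("control statistics use sample SD over the plate's own controls", {
  m <- read_plate_map(map_df())
  raw <- read_raw_plate(data.frame(plate_id = "P1", well = m$well,
    signal = c(5200, 800, 9000, 11000, 400, 400, 7000)))
  cs <- control_stats(m, raw)
  expect_equal(cs$mu_neg, 10000)
  expect_equal(cs$sd_neg, sqrt(((9000 - 10000)^2 + (11000 - 10000)^2) / 1))
  expect_equal(round(cs$sd_neg, 1), 1414.2)
  expect_equal(cs$mu_pos, 400)
  expect_equal(cs$sd_pos, 0)

  no_pos <- map_df(); no_pos$content_type[no_pos$content_type == "pos_control"] <- "empty"
  expect_error(control_stats(read_plate_map(no_pos), raw), "positive-control")
})

test_that("percent inhibition anchors to the controls and is affine invariant", {
  m <- read_plate_map(map_df())
  sig <- c(5200, 800, 9000, 11000, 400, 400, 10000)
  raw <- read_raw_plate(data.frame(plate_id = "P1", well = m$well, signal = sig))
  pi_tab <- percent_inhibition(m, raw)
  expect_equal(pi_tab$pi[pi_tab$well == "A01"], 50.0)
  expect_equal(pi_tab$pi[pi_tab$well == "C03"], 0)     # at mu_neg
  expect_false(any(pi_tab$well %in% c("B01", "C01"))) # controls excluded

  raw_k <- read_raw_plate(data.frame(plate_id = "P1", well = m$well,
                                     signal = 3.7 * sig))
  expect_equal(percent_inhibition(m, raw_k)$pi, pi_tab$pi, tolerance = 1e-12)

  flat <- read_raw_plate(data.frame(plate_id = "P1", well = m$well,
                                    signal = rep(500, 7)))
  expect_error(percent_inhibition(m, flat), "degenerate")
})

test_that("dose series are ascending, averaged over replicates, per model", {
  inhib <- data.frame(
    compound_id = c("X", "X", "X", "X", "X", "X"),
    model_id = c("M1", "M1", "M1", "M1", "M1", "M2"),
    concentration_molar = c(1e-8, 1e-7, 1e-7, 1e-6, 1e-5, 1e-6),
    pi = c(5, 40, 60, 80, 95, 50))
  expect_warning(series <- extract_dose_series(inhib), "fewer than 2")
  s <- series[["X@M1"]]
  expect_equal(s$x, log10(c(1e-8, 1e-7, 1e-6, 1e-5)))
  expect_equal(s$pi[2], 50)  # mean of the replicate pair at 1e-7
  expect_false("X@M2" %in% names(series))  # single dose skipped
})

test_that("plate tables survive a write/read round trip", {
  m <- read_plate_map(map_df())
  raw <- read_raw_plate(data.frame(plate_id = "P1", well = m$well,
                                   signal = c(5200, 800, 9000, 11000, 400, 400, 7000)))
  fm <- tempfile(fileext = ".csv"); fr <- tempfile(fileext = ".csv")
  write_plate_map(m, fm); write_raw_plate(raw, fr)
  m2 <- read_plate_map(fm); r2 <- read_raw_plate(fr)
  expect_equal(as.data.frame(m2), as.data.frame(m))
  expect_equal(r2$signal, raw$signal)
  unlink(c(fm, fr))
})
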