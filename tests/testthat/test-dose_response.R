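test_that("4PL prediction matches hand-evaluated values and symmetries", {
  p <- logistic4p(a = 80, b = 1, c = -7, d = 0)
  expect_equal(predict_inhibition(p, -6), 80 / (1 + 10^-1), tolerance = 1e-12)
  expect_equal(predict_inhibition(p, -7), (80 + 0) / 2)           # inflection
  expect_lt(predict_inhibition(p, -30), 1e-10)                    # lower asymptote
  expect_equal(predict_inhibition(p, 30), 80)                     # upper asymptote
})

test_that("prediction is monotone increasing in dose for random valid params", {
  pars <- random_params(50, seed = 101)
  x <- seq(-11, -3, length.out = 40)
  for (i in seq_len(nrow(pars))) {
    y <- predict_inhibition(logistic4p(pars$a[i], pars$b[i], pars$c[i]), x)
    expect_true(all(diff(y) >= 0))  # non-strict at numerical saturation
    expect_gt(y[40], y[1])
  }
})

test_that("parameter constructor rejects invalid configurations", {
  expect_error(logistic4p(110, 1, -7), "<= 100")
  expect_error(logistic4p(80, 0, -7), "slope")
  expect_error(logistic4p(80, 12, -7), "slope")
  expect_error(logistic4p(50, 1, -7, d = 60), "d <= a")
})

test_that("zero-noise series round-trip parameters to 1e-4", {
  cases <- list(c(80, 1, -7), c(40, 2, -6.5), c(95, 0.7, -7.8), c(25, 3, -6))
  for (cs in cases) {
    p <- logistic4p(cs[1], cs[2], cs[3])
    s <- list(x = -9:-5, pi = predict_inhibition(p, -9:-5))
    fit <- fit_logistic(s)
    expect_true(fit$converged)
    expect_equal(fit$params$a, cs[1], tolerance = 1e-4)
    expect_equal(fit$params$b, cs[2], tolerance = 1e-4)
    expect_equal(fit$params$c, cs[3], tolerance = 1e-4)
  }
})

test_that("flat and saturated series are fit but flagged unidentifiable", {
  flat <- fit_logistic(list(x = -9:-5, pi = rep(0, 5)))
  expect_lt(flat$params$a, 1e-6)
  expect_false(flat$identifiable)
  sat <- fit_logistic(list(x = -9:-5, pi = rep(100, 5)))
  expect_equal(sat$params$a, 100, tolerance = 1e-6)
  expect_false(sat$identifiable)
})

test_that("replicate-free preconditions are enforced", {
  expect_error(fit_logistic(list(x = c(-7, -7), pi = c(10, 20))), "distinct")
})

test_that("potency summaries match the closed-form hand values", {
  p <- logistic4p(80, 1, -7)
  fit <- fit_logistic(list(x = -9:-5, pi = predict_inhibition(p, -9:-5)))
  pot <- potency(fit)
  expect_equal(pot$ec50, 1e-7, tolerance = 1e-4)
  expect_equal(pot$ic50_abs, 10^(-7 - log10(0.6)), tolerance = 1e-4)

  # top below 50%: half-maximal inhibition never reached
  p40 <- logistic4p(40, 1, -7)
  fit40 <- fit_logistic(list(x = -9:-5, pi = predict_inhibition(p40, -9:-5)))
  expect_true(is.na(potency(fit40)$ic50_abs))

  # a = 100, d = 0: absolute IC50 coincides with the inflection EC50
  p100 <- logistic4p(100, 1.5, -7)
  fit100 <- fit_logistic(list(x = -9:-5, pi = predict_inhibition(p100, -9:-5)))
  pot100 <- potency(fit100)
  expect_equal(pot100$ic50_abs, pot100$ec50, tolerance = 1e-4)
})

test_that("noisy-series EC50 recovery stays within 0.1 log10 units (median)", {
  set.seed(202)
  errs <- replicate(60, {
    a <- runif(1, 40, 100); b <- runif(1, 0.7, 2.5); cc <- runif(1, -8.5, -5.5)
    p <- logistic4p(a, b, cc)
    y <- predict_inhibition(p, -9:-5) * rlnorm(5, 0, 0.05)
    fit <- fit_logistic(list(x = -9:-5, pi = y))
    abs(fit$params$c - cc)
  })
  expect_lt(median(errs), 0.1)
})
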