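p24 <- c(R0 = 0.266, Rhyp = 0.174, n = 0.50, EC50 = 0.185)
p48 <- c(R0 = 0.289, Rhyp = 0.223, n = 0.67, EC50 = 0.844)
recovery_doses <- c(0, 10^seq(-2, log10(30), length.out = 8))

test_that("Hill model evaluates exactly at its anchor points", {
  expect_equal(hill_response(0, p24), 0.266)
  # half-maximal at the EC50 by construction
  expect_equal(hill_response(0.185, p24), 0.266 + 0.174 / 2)
  expect_equal(hill_response(1e9, p24), 0.266 + 0.174, tolerance = 1e-4)
  expect_error(hill_response(-1, p24), "non-negative")
})

test_that("Hill response is monotone non-decreasing in dose", {
  set.seed(3)
  for (i in 1:20) {
    p <- c(R0 = runif(1, 0.1, 1), Rhyp = runif(1, 0, 1),
           n = runif(1, 0.2, 4), EC50 = 10^runif(1, -2, 2))
    d <- sort(10^runif(50, -3, 3))
    expect_true(all(diff(hill_response(d, p)) >= -1e-12))
  }
})

test_that("noiseless self-generated data are recovered to high precision", {
  for (p in list(p24, p48)) {
    resp <- hill_response(recovery_doses, p)
    fit <- fit_dose_response(rep(recovery_doses, 2), rep(resp, 2))
    expect_lt(max(abs(coef(fit) - p) / p), 1e-6)
    expect_true(fit$converged)
  }
  # property: random bounded parameter sets round-trip
  set.seed(12)
  for (i in 1:5) {
    p <- c(R0 = runif(1, 0.1, 1), Rhyp = runif(1, 0.05, 1),
           n = runif(1, 0.4, 3), EC50 = 10^runif(1, -1.5, 1.5))
    resp <- hill_response(recovery_doses, p)
    fit <- fit_dose_response(rep(recovery_doses, 2), rep(resp, 2))
    expect_lt(max(abs(coef(fit) - p) / p), 1e-5)
  }
})

test_that("dose-response fitting rejects inadequate designs", {
  expect_error(fit_dose_response(c(0, 1, 10), c(1, 2, 3)), "insufficient")
  expect_error(fit_dose_response(c(1, 2, 4, 8, 16), rep(1, 5)),
               "anchor")
})

test_that("EC50 is recovered from noisy replicated dose-response data", {
  err24 <- sapply(1:5, function(s) {
    d <- simulate_dose_response(p24, recovery_doses, n_rep = 16, cv = 0.03,
                                seed = s)
    abs(coef(fit_dose_response(d$dose, d$response))[["EC50"]] / 0.185 - 1)
  })
  err48 <- sapply(1:5, function(s) {
    d <- simulate_dose_response(p48, recovery_doses, n_rep = 16, cv = 0.03,
                                seed = s)
    abs(coef(fit_dose_response(d$dose, d$response))[["EC50"]] / 0.844 - 1)
  })
  expect_lt(median(err24), 0.25)
  expect_lt(median(err48), 0.25)
})

test_that("maximal growth percent reproduces the printed plateau values", {
  expect_equal(round(max_growth_percent(p48)), 177)
  expect_lte(max_growth_percent(p24), 166)
  expect_gt(max_growth_percent(p24), 165)
  expect_equal(max_growth_percent(c(R0 = 0.3, Rhyp = 0, n = 1, EC50 = 1)), 100)
  # invariant under common rescaling of R0 and Rhyp
  expect_equal(max_growth_percent(p48),
               max_growth_percent(p48 * c(7, 7, 1, 1)))
  expect_error(max_growth_percent(c(R0 = 0, Rhyp = 1, n = 1, EC50 = 1)),
               "invalid")
})

test_that("one-site inhibition fit recovers Ki", {
  doses <- c(0, 1, 3, 10, 30)
  clean <- 0 + (0.45 - 0) / (1 + doses / 9)
  fit <- fit_inhibition(rep(doses, 3), rep(clean, 3))
  expect_equal(coef(fit)[["Ki"]], 9, tolerance = 1e-6)
  expect_equal(predict(fit, 0), coef(fit)[["G0"]])
  # noisy recovery under the screening design: CV 5%, 25 wells per dose
  errs <- sapply(1:5, function(s) {
    set.seed(s)
    I <- rep(doses, each = 25)
    g <- (100 + 77 / (1 + I / 9)) * (1 + rnorm(length(I), 0, 0.05))
    abs(coef(fit_inhibition(I, g))[["Ki"]] / 9 - 1)
  })
  expect_lt(median(errs), 0.30)
  expect_error(fit_inhibition(c(0, 1, 3), c(1, 2, 3)), "insufficient")
  expect_error(fit_inhibition(c(1, 3, 10, 30), rep(1, 4)), "anchor")
})

test_that("growth onset is detected at the hinge point", {
  tp <- c(1, 2, 4, 8, 16, 24)
  set.seed(31)
  mk <- function(mu) lapply(mu, function(m) rnorm(8, m, 1))
  # flat to 4 h then linear rise with a 3 SD effect
  treated <- mk(ifelse(tp < 4, 10, 10 + 3 * (tp >= 4) * (1 + (tp - 4) / 10)))
  control <- mk(rep(10, 6))
  on <- detect_growth_onset(tp, treated, control)
  expect_equal(on$onset_time, 4)
  expect_gt(on$slope, 0)

  set.seed(32)
  flat <- detect_growth_onset(tp, mk(rep(10, 6)), mk(rep(10, 6)))
  expect_true(is.na(flat$onset_time))
  expect_true(is.na(flat$slope))

  set.seed(33)
  rising <- detect_growth_onset(tp, mk(10 + 5 * seq_along(tp)), mk(rep(10, 6)))
  expect_equal(rising$onset_time, 1)
})

test_that("onset detection controls the type-I rate on flat series", {
  set.seed(99)
  tp <- c(1, 2, 4, 8, 16, 24)
  hits <- replicate(1000, {
    tr <- lapply(tp, function(t) rnorm(8))
    ct <- lapply(tp, function(t) rnorm(8))
    !is.na(detect_growth_onset(tp, tr, ct)$onset_time)
  })
  expect_lte(mean(hits), 0.07)
})

test_that("exponential density decay fits exactly on clean data and clamps k", {
  dens <- c(500, 1500, 2500, 4000)
  idx <- 0.6 * exp(-2e-4 * dens)
  fit <- fit_density_decay(dens, idx)
  expect_equal(coef(fit)[["A"]], 0.6, tolerance = 1e-6)
  expect_equal(coef(fit)[["k"]], 2e-4, tolerance = 1e-6)

  flat <- fit_density_decay(dens, rep(0.4, 4))
  expect_equal(coef(flat)[["k"]], 0, tolerance = 1e-8)

  expect_warning(up <- fit_density_decay(dens, c(0.1, 0.2, 0.3, 0.4)),
                 "clamped")
  expect_equal(coef(up)[["k"]], 0, tolerance = 1e-8)
  expect_error(fit_density_decay(c(1, 2, 3), c(1, 2, 3)), "insufficient")
})
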