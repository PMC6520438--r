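test_that("partition splits a uniform SRB field exactly", {
  mask_img <- disc_image(50, 50, 25, 25, 8, value = 1000)
  mask <- build_nuclear_mask(mask_img, 1, min_area = 5)
  n_nuc <- sum(mask$labels > 0)
  srb <- matrix(7, 50, 50)
  part <- partition_srb(srb, mask, background = 0)
  expect_equal(part$esrb_total, 7 * (2500 - n_nuc))
  expect_equal(part$nsrb_mean, 7)
  expect_identical(part$n_nuclear_pixels, n_nuc)
})

test_that("partition conserves total corrected signal and is linear in gain", {
  spec <- small_field_spec(seed = 4)
  g <- generate_field_images(spec)
  mask <- build_nuclear_mask(g$field$hoechst, spec$pixel_size)
  part <- partition_srb(g$field$srb, mask)
  corrected <- pmax(g$field$srb - part$background, 0)
  expect_equal(part$esrb_total + part$nuclear_total, sum(corrected))
  # multiplying the image by k scales both components by k (background 0)
  p1 <- partition_srb(g$field$srb, mask, background = 0)
  pk <- partition_srb(g$field$srb * 3.5, mask, background = 0)
  expect_equal(pk$esrb_total, 3.5 * p1$esrb_total)
  expect_equal(pk$nsrb_mean, 3.5 * p1$nsrb_mean)
})

test_that("partition validates shapes and flags empty masks", {
  mask <- build_nuclear_mask(disc_image(40, 40, 20, 20, 6), 1)
  expect_error(partition_srb(matrix(1, 30, 30), mask), "shape")
  suppressWarnings(empty <- build_nuclear_mask(matrix(0, 40, 40), 1))
  part <- partition_srb(matrix(5, 40, 40), empty)
  expect_identical(part$flag, "no_nuclei")
  expect_true(is.na(part$nsrb_mean))
})

test_that("ratiometric index is eSRB over nSRB times cell count", {
  part <- structure(list(esrb_total = 6e5, nsrb_mean = 200,
                         nuclear_total = 0, background = 0,
                         n_nuclear_pixels = 10L, flag = "ok"),
                    class = "srb_partition")
  res <- ratiometric_index(part, 10)
  expect_equal(res$index, 300)
  expect_error(ratiometric_index(part, 0), "undefined")
  part$nsrb_mean <- 0
  expect_error(ratiometric_index(part, 10), "undefined")
})

test_that("index is invariant under multiplicative gain on both channels", {
  spec <- small_field_spec(seed = 3)
  g <- generate_field_images(spec)
  # pure rescaling of both channels, zero background: < 0.1% change
  mask1 <- build_nuclear_mask(g$field$hoechst, spec$pixel_size)
  i1 <- ratiometric_index(partition_srb(g$field$srb, mask1, background = 0),
                          200)$index
  for (k in c(0.5, 4, 10)) {
    mk <- build_nuclear_mask(g$field$hoechst * k, spec$pixel_size)
    ik <- ratiometric_index(partition_srb(g$field$srb * k, mk, background = 0),
                            200)$index
    expect_lt(abs(ik - i1) / i1, 0.001)
  }
  # full generator chain at 10x laser power, same seed: < 1% change
  r1 <- analyze_field(g$field)
  sp10 <- small_field_spec(seed = 3, gain = 10)
  r10 <- analyze_field(generate_field_images(sp10)$field)
  expect_lt(abs(r10$index - r1$index) / r1$index, 0.01)
})

test_that("field analysis matches the generator's analytic index", {
  spec <- small_field_spec(seed = 17)
  g <- generate_field_images(spec)
  res <- analyze_field(g$field)
  expect_lt(abs(res$index - g$truth$expected_index) / g$truth$expected_index,
            0.10)
  # determinism: identical field twice gives identical results
  res2 <- analyze_field(g$field)
  expect_identical(res$index, res2$index)
  # blank field propagates an undefined-index error with well context
  blank <- srb_field(matrix(0, 64, 64), matrix(0, 64, 64), 1, well_id = "B2")
  expect_error(suppressWarnings(analyze_field(blank)), "B2")
})

test_that("responses normalize to time-matched controls within isolation", {
  res <- data.frame(
    index = c(0.30, 0.45, 0.30, 0.42, 0.50, 0.48),
    condition = c("control", "PE", "control", "PE", "PE", "PE"),
    dose = c(0, 10, 0, 10, 10, 10),
    duration = c(24, 24, 48, 48, 48, 48),
    isolation = c(1, 1, 1, 1, 1, 1),
    is_control = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  out <- normalize_to_control(res)
  s <- out$summary
  expect_equal(s$response_mean[s$duration == 24 & s$condition == "PE"], 150)
  expect_equal(s$response_mean[s$duration == 24 & s$condition == "control"], 100)
  # treated 0.42/0.50/0.48 vs control 0.30 at 48 h
  expect_equal(s$response_mean[s$duration == 48 & s$condition == "PE"],
               100 * mean(c(0.42, 0.50, 0.48)) / 0.30)

  # two isolations: summary is the unweighted mean of isolation responses
  res2 <- data.frame(index = c(0.30, 0.42, 0.25, 0.40),
                     condition = c("control", "PE", "control", "PE"),
                     dose = c(0, 10, 0, 10), duration = 24,
                     isolation = c(1, 1, 2, 2),
                     is_control = c(TRUE, FALSE, TRUE, FALSE))
  s2 <- normalize_to_control(res2)$summary
  expect_equal(s2$response_mean[s2$condition == "PE"],
               mean(c(140, 160)))

  # a stratum with treated wells but no control raises a named error
  res3 <- res2
  res3$is_control[3] <- FALSE
  expect_error(normalize_to_control(res3), "isolation 2")
})
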