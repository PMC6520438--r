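test_that("generators are bit-reproducible given a seed", {
  spec <- synthetic_spec(seed = 77)
  a <- generate_particle_table(spec)
  b <- generate_particle_table(spec)
  expect_identical(a, b)

  sp <- small_field_spec(seed = 77)
  f1 <- generate_field_images(sp)
  f2 <- generate_field_images(sp)
  expect_identical(f1$field$hoechst, f2$field$hoechst)
  expect_identical(f1$field$srb, f2$field$srb)
})

test_that("multinomial cell-type draws match requested fractions", {
  spec <- synthetic_spec(seed = 19)
  out <- generate_particle_table(spec, n = 3000,
                                 fractions = c(0.77, 0.16, 0.07))
  emp <- prop.table(table(out$truth$type))
  for (i in seq_along(control_fractions)) {
    p <- control_fractions[i]
    se <- sqrt(p * (1 - p) / 3000)
    expect_lt(abs(emp[[names(control_fractions)[i]]] - p), 3 * se)
  }
})

test_that("generated areas follow the specified log-normal distributions", {
  spec <- synthetic_spec(n_cells_by_type = c(mononucleate = 2000,
                                             binucleate = 500,
                                             fibroblast = 500), seed = 23)
  out <- generate_particle_table(spec)
  for (ty in unique(out$truth$type)) {
    a <- out$particles$area[out$truth$type == ty]
    ks <- ks.test(a, plnorm, meanlog = log(spec$area_median[[ty]]),
                  sdlog = spec$area_logsd[[ty]])
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("spec validation rejects malformed inputs", {
  expect_error(synthetic_spec(pixel_size = -1), "validation")
  expect_error(synthetic_spec(n_cells_by_type = c(mononucleate = -5,
                                                  binucleate = 1,
                                                  fibroblast = 1)),
               "validation")
  expect_error(synthetic_spec(circ_median = c(mononucleate = 0.5,
                                              binucleate = 2,
                                              fibroblast = 1.1)),
               "validation")
})

test_that("rendered fields give the pipeline the true particle count", {
  g <- generate_field_images(small_field_spec(seed = 41))
  mask <- build_nuclear_mask(g$field$hoechst, g$field$pixel_size)
  expect_lt(abs(mask$n_particles - g$truth$n_cells) / g$truth$n_cells, 0.05)
})

test_that("nuclear SRB is independent of cell biomass by construction", {
  sp <- small_field_spec(seed = 47, noise_sd = 1e-9,
                         background = c(hoechst = 0, srb = 0))
  g <- generate_field_images(sp)
  lab <- g$truth$labels
  nuc <- lab > 0
  per_nsrb <- rowsum(as.numeric(g$field$srb[nuc]), lab[nuc])[, 1] /
    tabulate(lab[nuc], nbins = g$truth$n_cells)
  expect_lt(abs(cor(per_nsrb, g$truth$cells$biomass)), 0.1)
})

test_that("analytic index matches the pipeline on clean renders", {
  sp <- small_field_spec(seed = 5, noise_sd = 1e-9,
                         background = c(hoechst = 0, srb = 0))
  g <- generate_field_images(sp)
  res <- analyze_field(g$field)
  expect_lt(abs(res$index - g$truth$expected_index) / g$truth$expected_index,
            0.02)
})

test_that("hypertrophy factor moves the index proportionally", {
  i1 <- analyze_field(generate_field_images(
    small_field_spec(seed = 9))$field)$index
  i15 <- analyze_field(generate_field_images(
    small_field_spec(seed = 9, hypertrophy_factor = 1.5))$field)$index
  expect_gt(i15 / i1, 1.35)
  expect_lt(i15 / i1, 1.65)
})

test_that("overcrowded specifications raise a density error", {
  sp <- synthetic_spec(field_size = c(96L, 96L),
                       n_cells_by_type = c(mononucleate = 400,
                                           binucleate = 50,
                                           fibroblast = 50), seed = 2)
  expect_error(generate_field_images(sp, max_tries = 20), "density")
})

test_that("null plates reproduce the target intraclass correlation", {
  set.seed(61)
  icc_est <- replicate(100, {
    ds <- generate_plate_dataset(
      plate_design(doses = 0, n_isolations = 8, n_replicates = 6),
      target_icc = 0.5, seed = sample.int(1e6, 1))
    variance_components_icc(log(ds$wells$index), ds$wells$isolation)$icc
  })
  expect_lt(abs(mean(icc_est) - 0.5), 0.1)
})

test_that("zero-effect plates normalize to 100% of control", {
  des <- plate_design(doses = c(0, 1, 10), n_isolations = 6,
                      n_replicates = 4)
  ds <- generate_plate_dataset(des, seed = 8)
  s <- normalize_to_control(ds$wells)$summary
  trt <- s$response_mean[s$condition != "control"]
  expect_true(all(abs(trt - 100) < 5))
})

test_that("dose-ladder plates let the fit recover the generating EC50", {
  p24 <- c(R0 = 0.266, Rhyp = 0.174, n = 0.50, EC50 = 0.185)
  des <- plate_design(doses = c(0, 10^seq(-2, log10(30), length.out = 8)),
                      n_isolations = 4, n_replicates = 4)
  errs <- sapply(1:5, function(s) {
    ds <- generate_plate_dataset(des, effect = list(params = p24),
                                 well_sdlog = 0.03, seed = s)
    per <- normalize_to_control(ds$wells)$per_isolation
    abs(coef(fit_dose_response(per$dose, per$response))[["EC50"]] / 0.185 - 1)
  })
  expect_lt(median(errs), 0.25)
})

test_that("plate generation validates its design", {
  bad <- data.frame(well_id = c("a", "a"), condition = "c", dose = 0,
                    duration = 24, isolation = 1, is_control = TRUE)
  expect_error(generate_plate_dataset(bad), "duplicate")
  expect_error(generate_plate_dataset(data.frame(x = 1)), "columns")
})
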