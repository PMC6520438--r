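# Small rendered plate shared across pipeline tests: 3 doses x 2 isolations
# x 2 repeats, ~150 cells per 512 px field.
local_plate <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      des <- plate_design(doses = c(0, 1, 10), n_isolations = 2,
                          n_replicates = 2)
      spec <- synthetic_spec(field_size = c(512L, 512L),
                             n_cells_by_type = round(150 * control_fractions),
                             seed = 29)
      memo <<- generate_plate_dataset(des, spec,
                                      effect = list(params = c(
                                        R0 = 0.266, Rhyp = 0.174,
                                        n = 0.50, EC50 = 0.185)),
                                      seed = 29, mode = "images")
    }
    memo
  }
})

test_that("plate maps are validated in aggregate", {
  dir <- withr::local_tempdir()
  img <- matrix(0:99 * 100, 10)
  write_channel_tiff(img, file.path(dir, "h.tif"))
  write_channel_tiff(img, file.path(dir, "s.tif"))
  map <- data.frame(well_id = c("A1", "A2"),
                    hoechst_path = "h.tif", srb_path = "s.tif",
                    condition = c("control", "PE"), dose = c(0, 10),
                    duration = 24, isolation = 1,
                    is_control = c(TRUE, FALSE))
  path <- file.path(dir, "map.tsv")
  write.table(map, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_s3_class(read_plate_map(path), "srb_plate_map")

  # a stratum without controls is named in the validation error
  map2 <- map; map2$is_control <- FALSE
  write.table(map2, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_plate_map(path), "isolation 1.*no control")

  # missing files and duplicate ids are reported together
  map3 <- rbind(map, map[2, ])
  map3$srb_path[3] <- "absent.tif"
  write.table(map3, path, sep = "\t", row.names = FALSE, quote = FALSE)
  err <- tryCatch(read_plate_map(path), error = conditionMessage)
  expect_match(err, "duplicate")
  expect_match(err, "absent.tif|missing srb_path")
})

test_that("single wells run end to end from TIFF files", {
  dir <- withr::local_tempdir()
  g <- generate_field_images(small_field_spec(seed = 53))
  write_channel_tiff(g$field$hoechst, file.path(dir, "w_h.tif"))
  write_channel_tiff(g$field$srb, file.path(dir, "w_s.tif"))
  row <- data.frame(well_id = "C3",
                    hoechst_path = file.path(dir, "w_h.tif"),
                    srb_path = file.path(dir, "w_s.tif"))
  res <- run_well(row, config = list(pixel_size = 1.25))
  expect_s3_class(res, "srb_result")
  expect_lt(abs(res$index - g$truth$expected_index) / g$truth$expected_index,
            0.10)
  # identical input rows give identical results
  res2 <- run_well(row, config = list(pixel_size = 1.25))
  expect_identical(res$index, res2$index)
  # a missing channel file is a file error naming the well
  row$srb_path <- file.path(dir, "gone.tif")
  expect_error(run_well(row), "C3")
})

test_that("plate runs produce one result row per well with pooled models", {
  ds <- local_plate()
  plate <- run_plate(ds$wells, config = list(pixel_size = 1.25))
  expect_s3_class(plate, "srb_plate")
  expect_identical(nrow(plate$results), nrow(ds$wells))
  expect_true(all(is.finite(plate$results$index)))
  expect_false(plate$models$cutoff$degenerate)
  # treated indices exceed control on average (the generating effect at
  # 10 uM with the 24 h parameters is ~1.6x)
  r <- plate$results
  expect_gt(mean(r$index[r$dose == 10]), mean(r$index[r$is_control]))
  # manifest records the run
  expect_identical(plate$manifest$n_wells, nrow(ds$wells))
  # deterministic re-run
  plate2 <- run_plate(ds$wells, config = list(pixel_size = 1.25))
  expect_identical(plate$results$index, plate2$results$index)
})

test_that("plate results serialize to delimited text", {
  ds <- local_plate()
  plate <- run_plate(ds$wells, config = list(pixel_size = 1.25))
  dir <- withr::local_tempdir()
  paths <- write_plate_results(plate, dir)
  expect_true(file.exists(file.path(dir, "results.tsv")))
  tab <- read.delim(file.path(dir, "results.tsv"))
  expect_identical(nrow(tab), nrow(ds$wells))
  expect_true(all(c("well_id", "index", "n_cells") %in% names(tab)))
})

test_that("a 96-well synthetic plate yields 96 result rows and a dose fit", {
  des <- plate_design(doses = c(0, 0.03, 0.1, 0.3, 1, 10),
                      n_isolations = 4, n_replicates = 4)
  expect_identical(nrow(des), 96L)
  ds <- generate_plate_dataset(des, effect = list(params = c(
    R0 = 0.266, Rhyp = 0.174, n = 0.50, EC50 = 0.185)),
    well_sdlog = 0.03, seed = 3)
  # tables mode exercises the statistical tail of the pipeline
  resp <- normalize_to_control(ds$wells)
  expect_identical(nrow(ds$wells), 96L)
  fit <- fit_dose_response(resp$per_isolation$dose,
                           resp$per_isolation$response)
  expect_gt(coef(fit)[["EC50"]], 0.185 / 3)
  expect_lt(coef(fit)[["EC50"]], 0.185 * 3)
  an <- hierarchical_anova(ds$wells$index,
                           interaction(ds$wells$isolation, ds$wells$dose),
                           factor(ds$wells$dose))
  expect_lt(an$p, 0.01)
})
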