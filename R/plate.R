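#' Read and validate a plate map
#'
#' A plate map is a delimited text table (tab- or comma-separated, header
#' row) with one row per well and columns `well_id`, `hoechst_path`,
#' `srb_path`, `condition`, `dose` (uM), `duration` (hours), `isolation`,
#' `is_control` (logical; controls are flagged explicitly rather than
#' inferred from dose 0, so vehicle controls are supported). Validation
#' failures are reported in aggregate before any analysis.
#'
#' @param path plate-map file, or a data.frame already in memory.
#' @param base_dir directory image paths are resolved against (defaults to
#'   the plate-map directory).
#' @return validated plate-map data.frame of class `srb_plate_map`.
#' @export
read_plate_map <- function(path, base_dir = NULL) {
  if (is.data.frame(path)) {
    map <- path
    if (is.null(base_dir)) base_dir <- "."
  } else {
    first <- readLines(path, n = 1)
    sep <- if (grepl("\t", first)) "\t" else ","
    map <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
    if (is.null(base_dir)) base_dir <- dirname(path)
  }
  need <- c("well_id", "hoechst_path", "srb_path", "condition", "dose",
            "duration", "isolation", "is_control")
  problems <- character(0)
  missing_cols <- setdiff(need, names(map))
  if (length(missing_cols))
    problems <- c(problems, paste("missing columns:",
                                  paste(missing_cols, collapse = ", ")))
  if (!length(missing_cols)) {
    map$is_control <- as.logical(map$is_control)
    if (anyDuplicated(map$well_id))
      problems <- c(problems, paste("duplicate well_id:",
                                    paste(unique(map$well_id[duplicated(map$well_id)]),
                                          collapse = ", ")))
    resolve <- function(p) ifelse(file.exists(p), p, file.path(base_dir, p))
    map$hoechst_path <- resolve(map$hoechst_path)
    map$srb_path <- resolve(map$srb_path)
    for (col in c("hoechst_path", "srb_path")) {
      absent <- !file.exists(map[[col]])
      if (any(absent))
        problems <- c(problems, paste0("missing ", col, " file for wells: ",
                                       paste(map$well_id[absent], collapse = ", ")))
    }
    strata <- unique(map[, c("isolation", "duration")])
    for (k in seq_len(nrow(strata))) {
      s <- map[map$isolation == strata$isolation[k] &
                 map$duration == strata$duration[k], ]
      if (any(!s$is_control) && !any(s$is_control))
        problems <- c(problems,
                      sprintf("stratum (isolation %s, duration %s h) has no control well",
                              strata$isolation[k], strata$duration[k]))
    }
  }
  if (length(problems))
    stop("plate-map validation failed:\n  - ",
         paste(problems, collapse = "\n  - "))
  class(map) <- c("srb_plate_map", "data.frame")
  map
}

#' Analyze one plate-map row (well)
#'
#' Reads the two channel TIFFs and runs the full segmentation, census,
#' partition and index chain via [analyze_field()]. Deterministic: the same
#' row and config give an identical result.
#'
#' @param row one-row data.frame from a plate map.
#' @param config analysis config list (see [analyze_field()]); additionally
#'   `pixel_size` (um/px, default 1).
#' @return an `srb_result`.
#' @export
run_well <- function(row, config = list()) {
  stopifnot(nrow(row) == 1)
  for (col in c("hoechst_path", "srb_path")) {
    if (is.null(row[[col]]) || !file.exists(row[[col]]))
      stop("file error: well ", row$well_id, " is missing its ",
           sub("_path", "", col), " image (", row[[col]], ")")
  }
  pixel_size <- if (is.null(config$pixel_size)) 1 else config$pixel_size
  field <- srb_field(read_channel_tiff(row$hoechst_path),
                     read_channel_tiff(row$srb_path),
                     pixel_size = pixel_size, well_id = row$well_id)
  analyze_field(field, config)
}

#' Run a full plate analysis
#'
#' Validates the plate map, segments and measures every well, fits the
#' classification models (area cutoff and circularity mixture) on particles
#' pooled over control wells and applies them plate-wide (set
#' `config$per_well_models = TRUE` to fit per well instead), computes the
#' per-well census, SRB partition and ratiometric index, normalizes treated
#' wells to time-matched controls within isolation, and — where the design
#' allows — fits the Hill concentration-response on percent-of-control
#' responses and runs the hierarchical ANOVA across conditions. A run
#' manifest (package version, config, timestamp) accompanies the results.
#'
#' @param map plate map (path, data.frame, or `srb_plate_map`). Wells may
#'   alternatively carry in-memory fields in a `field` list column (as
#'   produced by [generate_plate_dataset()] image mode).
#' @param config analysis config list: `pixel_size`, `min_area`,
#'   `exclude_border`, `include_fibroblasts`, `fallback_cutoff`,
#'   `per_well_models`, `fit_dose_response` (logical).
#' @return object of class `srb_plate`: `results` (one row per well),
#'   `responses` (an `srb_responses`), `fits` (list, possibly empty),
#'   `anova` (an `srb_hanova` or `NULL`), `census` (per-well census table),
#'   `models` (pooled cutoff and mixture), `manifest`.
#' @export
run_plate <- function(map, config = list()) {
  if (!inherits(map, "srb_plate_map") && !("field" %in% names(map)))
    map <- read_plate_map(map)
  cfg <- modifyList(list(pixel_size = 1, min_area = 20,
                         exclude_border = FALSE, include_fibroblasts = TRUE,
                         fallback_cutoff = NULL, per_well_models = FALSE,
                         fit_dose_response = TRUE), config)
  warnings_log <- character(0)
  get_field <- function(i) {
    if ("field" %in% names(map)) {
      f <- map$field[[i]]
      if (!is.null(f$field)) f$field else f
    } else {
      srb_field(read_channel_tiff(map$hoechst_path[i]),
                read_channel_tiff(map$srb_path[i]),
                pixel_size = cfg$pixel_size, well_id = map$well_id[i])
    }
  }
  n <- nrow(map)
  seg <- vector("list", n)
  for (i in seq_len(n)) {
    field <- get_field(i)
    mask <- withCallingHandlers(
      build_nuclear_mask(field$hoechst, field$pixel_size,
                         min_area = cfg$min_area,
                         exclude_border = cfg$exclude_border),
      warning = function(w) {
        warnings_log <<- c(warnings_log,
                           paste0(map$well_id[i], ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    seg[[i]] <- list(field = field, mask = mask,
                     particles = measure_particles(mask, field$hoechst))
  }
  cutoff <- mixture <- NULL
  if (!cfg$per_well_models) {
    pooled <- do.call(rbind, lapply(which(map$is_control),
                                    function(i) seg[[i]]$particles))
    if (is.null(pooled) || nrow(pooled) == 0)
      pooled <- do.call(rbind, lapply(seg, `[[`, "particles"))
    cutoff <- determine_area_cutoff(pooled, cfg$fallback_cutoff)
    mixture <- fit_circularity_mixture(
      pooled[pooled$area > cutoff$cutoff, , drop = FALSE])
  }
  results <- map
  results$field <- NULL
  results$n_particles <- results$n_cells <- NA_integer_
  results$esrb_total <- results$nsrb_mean <- results$index <- NA_real_
  census_rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- seg[[i]]
    res <- tryCatch(
      analyze_field(s$field, modifyList(cfg, list(cutoff = cutoff,
                                                  mixture = mixture))),
      error = function(e) {
        warnings_log <<- c(warnings_log, conditionMessage(e))
        NULL
      })
    results$n_particles[i] <- s$mask$n_particles
    if (!is.null(res)) {
      results$n_cells[i] <- res$n_cells
      results$esrb_total[i] <- res$esrb_total
      results$nsrb_mean[i] <- res$nsrb_mean
      results$index[i] <- res$index
      cen <- res$details ; cc <- census_cells(cen$classification,
                                              cfg$include_fibroblasts)
      census_rows[[i]] <- data.frame(well_id = map$well_id[i],
                                     n_mono = cc$n_mono,
                                     n_binucleate = cc$n_binucleate,
                                     n_fibroblast = cc$n_fibroblast,
                                     n_cells = cc$n_cells)
    }
  }
  responses <- tryCatch(normalize_to_control(results),
                        error = function(e) {
                          warnings_log <<- c(warnings_log, conditionMessage(e))
                          NULL
                        })
  fits <- list()
  if (isTRUE(cfg$fit_dose_response) && !is.null(responses)) {
    per <- responses$per_isolation
    trt <- unique(per$condition[per$condition != "control"])
    for (cond in trt) {
      sub <- per[per$condition == cond | per$dose == 0, ]
      if (length(unique(sub$dose)) >= 5) {
        fits[[cond]] <- tryCatch(
          fit_dose_response(sub$dose, sub$response),
          error = function(e) {
            warnings_log <<- c(warnings_log,
                               paste0("dose-response fit (", cond, "): ",
                                      conditionMessage(e)))
            NULL
          })
      }
    }
  }
  anova_rep <- NULL
  cond <- interaction(results$condition, results$dose, drop = TRUE)
  if (nlevels(cond) >= 2) {
    # isolations are crossed with conditions on a plate, so the clustering
    # unit for the hierarchical test is the isolation-by-condition cell
    anova_rep <- tryCatch(
      hierarchical_anova(results$index,
                         interaction(results$isolation, cond, drop = TRUE),
                         cond),
      error = function(e) NULL)
  }
  manifest <- list(package = "srbratio",
                   version = as.character(packageVersion("srbratio")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   n_wells = n, config = cfg[setdiff(names(cfg),
                                                     c("cutoff", "mixture"))],
                   warnings = warnings_log)
  structure(list(results = results, responses = responses, fits = fits,
                 anova = anova_rep,
                 census = do.call(rbind, census_rows),
                 models = list(cutoff = cutoff, mixture = mixture),
                 manifest = manifest),
            class = "srb_plate")
}

#' @export
print.srb_plate <- function(x, ...) {
  cat("SRB plate analysis:", nrow(x$results), "wells\n")
  ok <- sum(!is.na(x$results$index))
  cat("  indices computed for", ok, "wells; median index",
      format(median(x$results$index, na.rm = TRUE), digits = 4), "\n")
  if (length(x$fits))
    for (nm in names(x$fits))
      cat("  dose-response fit (", nm, "): EC50 ",
          format(coef(x$fits[[nm]])[["EC50"]], digits = 3), " uM\n", sep = "")
  if (!is.null(x$anova))
    cat("  hierarchical ANOVA: p =", format.pval(x$anova$p, digits = 3), "\n")
  if (length(x$manifest$warnings))
    cat("  warnings:", length(x$manifest$warnings), "(see $manifest$warnings)\n")
  invisible(x)
}

#' Write plate results as delimited text
#'
#' Emits the per-well results table (well, condition, dose, duration,
#' isolation, eSRB, nSRB, n_cells, index), the per-well census and the
#' response summary as tab-separated files, and the run manifest as JSON if
#' jsonlite is available.
#'
#' @param plate an `srb_plate`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_plate_results <- function(plate, dir) {
  stopifnot(inherits(plate, "srb_plate"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wt <- function(obj, name) {
    p <- file.path(dir, name)
    write.table(obj, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  keep <- intersect(c("well_id", "condition", "dose", "duration", "isolation",
                      "is_control", "n_particles", "n_cells", "esrb_total",
                      "nsrb_mean", "index"), names(plate$results))
  wt(plate$results[, keep], "results.tsv")
  if (!is.null(plate$census)) wt(plate$census, "census.tsv")
  if (!is.null(plate$responses)) wt(plate$responses$summary, "responses.tsv")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    p <- file.path(dir, "manifest.json")
    jsonlite::write_json(plate$manifest, p, auto_unbox = TRUE, pretty = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a synthetic plate to disk in pipeline input format
#'
#' Renders each well of an image-mode synthetic plate as paired 16-bit
#' Hoechst/SRB TIFFs plus a tab-separated plate map and per-well ground
#' truth, i.e. exactly the formats [run_plate()] reads.
#'
#' @param dataset output of [generate_plate_dataset()] with
#'   `mode = "images"`.
#' @param dir output directory.
#' @return path of the written plate map.
#' @export
write_synthetic_plate <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wells <- dataset$wells
  map <- wells[, c("well_id", "condition", "dose", "duration", "isolation",
                   "is_control")]
  map$hoechst_path <- paste0(wells$well_id, "_hoechst.tif")
  map$srb_path <- paste0(wells$well_id, "_srb.tif")
  truth_rows <- vector("list", nrow(wells))
  for (i in seq_len(nrow(wells))) {
    f <- wells$field[[i]]$field
    tr <- wells$field[[i]]$truth
    write_channel_tiff(f$hoechst, file.path(dir, map$hoechst_path[i]))
    write_channel_tiff(f$srb, file.path(dir, map$srb_path[i]))
    truth_rows[[i]] <- data.frame(well_id = wells$well_id[i],
                                  n_cells = tr$n_cells,
                                  expected_index = tr$expected_index)
  }
  write.table(do.call(rbind, truth_rows), file.path(dir, "ground_truth.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  map_path <- file.path(dir, "plate_map.tsv")
  write.table(map, map_path, sep = "\t", row.names = FALSE, quote = FALSE)
  map_path
}
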