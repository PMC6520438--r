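#' Partition SRB fluorescence into nuclear and extra-nuclear components
#'
#' The SRB channel is background-corrected (histogram-mode background,
#' estimated independently of the Hoechst channel, clipped at zero) and its
#' pixels split by the nuclear mask. The extra-nuclear total (eSRB)
#' deliberately includes background-region pixels: no cytoplasm segmentation
#' is attempted. The nuclear reference (nSRB) is the unweighted mean over
#' particles of each particle's mean SRB, which de-weights large fibroblast
#' nuclei relative to a pixel-pooled mean.
#'
#' @param srb numeric matrix, SRB channel (same shape as the mask).
#' @param mask an `srb_mask`.
#' @param background optional fixed background level; estimated from the SRB
#'   channel when `NULL`.
#' @return object of class `srb_partition`: `esrb_total`, `nsrb_mean`,
#'   `nsrb_per_particle`, `nuclear_total`, `background`, `n_nuclear_pixels`,
#'   `flag` (`"ok"` or `"no_nuclei"`).
#' @export
partition_srb <- function(srb, mask, background = NULL) {
  stopifnot(inherits(mask, "srb_mask"))
  if (!identical(dim(srb), dim(mask$labels)))
    stop("invalid input: SRB image and mask differ in shape")
  if (is.null(background)) background <- estimate_background(srb)
  corr <- pmax(srb - background, 0)
  lab <- mask$labels
  nuclear <- lab > 0L
  nuclear_total <- sum(corr[nuclear])
  esrb_total <- sum(corr) - nuclear_total
  if (mask$n_particles > 0L) {
    l <- lab[nuclear]
    per <- rowsum(as.numeric(corr[nuclear]), l)[, 1] /
      tabulate(l, nbins = mask$n_particles)
    nsrb_mean <- mean(per)
    flag <- "ok"
  } else {
    per <- numeric(0)
    nsrb_mean <- NA_real_
    flag <- "no_nuclei"
  }
  structure(list(esrb_total = esrb_total, nsrb_mean = nsrb_mean,
                 nsrb_per_particle = per, nuclear_total = nuclear_total,
                 background = background,
                 n_nuclear_pixels = sum(nuclear), flag = flag),
            class = "srb_partition")
}

#' Ratiometric SRB hypertrophy index
#'
#' The index is eSRB / (mean nSRB x number of cells): the total extra-nuclear
#' protein signal normalized by the nuclear reference and the cell count.
#' Because gain, laser power and light-path factors scale both channels of
#' the ratio equally, the index is invariant under multiplicative rescaling
#' of the SRB image.
#'
#' @param partition an `srb_partition`.
#' @param census an `srb_census` (or a plain cell count).
#' @param well_id optional well identifier carried into the result.
#' @return object of class `srb_result`: `index`, `esrb_total`, `nsrb_mean`,
#'   `n_cells`, `well_id`, `census`.
#' @export
ratiometric_index <- function(partition, census, well_id = NA_character_) {
  stopifnot(inherits(partition, "srb_partition"))
  n_cells <- if (inherits(census, "srb_census")) census$n_cells else as.integer(census)
  if (is.na(partition$nsrb_mean) || partition$nsrb_mean <= 0)
    stop("undefined index: no nuclear SRB reference (nsrb_mean <= 0)")
  if (is.na(n_cells) || n_cells <= 0)
    stop("undefined index: zero cells in field")
  structure(list(index = partition$esrb_total / (partition$nsrb_mean * n_cells),
                 esrb_total = partition$esrb_total,
                 nsrb_mean = partition$nsrb_mean,
                 n_cells = n_cells,
                 well_id = well_id,
                 census = if (inherits(census, "srb_census")) census else NULL),
            class = "srb_result")
}

#' @export
print.srb_result <- function(x, ...) {
  cat("Ratiometric SRB index:", format(x$index, digits = 4),
      sprintf("(eSRB %.4g, nSRB %.4g, %d cells%s)\n", x$esrb_total,
              x$nsrb_mean, x$n_cells,
              if (!is.na(x$well_id)) paste0(", well ", x$well_id) else ""))
  invisible(x)
}

#' Analyze one fluorescence field end to end
#'
#' Runs the full chain on a paired Hoechst/SRB field: nuclear mask, particle
#' morphometry, cell-type classification (per-field models unless prefitted
#' ones are supplied in `config`), cell census, SRB partition and ratiometric
#' index. Deterministic; all intermediates are recorded for audit in
#' `$details`.
#'
#' @param field an `srb_field` (see [srb_field()]).
#' @param config named list of options: `min_area`, `exclude_border`,
#'   `include_fibroblasts`, `fallback_cutoff`, and optionally prefitted
#'   `cutoff` (`srb_area_cutoff`) and `mixture` (`srb_circ_mixture`) as
#'   fitted on pooled plate controls.
#' @return an `srb_result` with an added `details` list (mask, particles,
#'   cutoff, mixture, classification, partition).
#' @export
analyze_field <- function(field, config = list()) {
  stopifnot(inherits(field, "srb_field"))
  cfg <- modifyList(list(min_area = 20, exclude_border = FALSE,
                         include_fibroblasts = TRUE, fallback_cutoff = NULL,
                         cutoff = NULL, mixture = NULL), config)
  with_well <- function(expr) {
    tryCatch(expr, error = function(e)
      stop("well ", field$well_id, ": ", conditionMessage(e), call. = FALSE))
  }
  mask <- with_well(build_nuclear_mask(field$hoechst, field$pixel_size,
                                       min_area = cfg$min_area,
                                       exclude_border = cfg$exclude_border))
  particles <- with_well(measure_particles(mask, field$hoechst))
  cutoff <- cfg$cutoff
  if (is.null(cutoff))
    cutoff <- with_well(determine_area_cutoff(particles, cfg$fallback_cutoff))
  mixture <- cfg$mixture
  if (is.null(mixture)) {
    large <- particles[particles$area > cutoff$cutoff, , drop = FALSE]
    mixture <- with_well(fit_circularity_mixture(large))
  }
  cls <- classify_particles(particles, cutoff, mixture)
  census <- census_cells(cls, include_fibroblasts = cfg$include_fibroblasts)
  part <- with_well(partition_srb(field$srb, mask))
  res <- with_well(ratiometric_index(part, census, well_id = field$well_id))
  res$details <- list(mask = mask, particles = particles, cutoff = cutoff,
                      mixture = mixture, classification = cls,
                      partition = part)
  res
}

#' Construct a paired-channel fluorescence field
#'
#' @param hoechst,srb numeric matrices of non-negative intensities, same
#'   dimensions.
#' @param pixel_size micrometres per pixel (> 0).
#' @param well_id well identifier.
#' @param bit_depth image bit depth (8 or 16).
#' @return object of class `srb_field`.
#' @export
srb_field <- function(hoechst, srb, pixel_size = 1, well_id = "well",
                      bit_depth = 16L) {
  stopifnot(is.matrix(hoechst), is.matrix(srb))
  if (!identical(dim(hoechst), dim(srb)))
    stop("invalid input: channels differ in dimensions")
  if (pixel_size <= 0) stop("invalid input: pixel_size must be > 0")
  maxv <- 2^bit_depth - 1
  if (min(hoechst) < 0 || min(srb) < 0 || max(hoechst) > maxv || max(srb) > maxv)
    stop("invalid input: intensities outside bit-depth range")
  structure(list(hoechst = hoechst, srb = srb, pixel_size = pixel_size,
                 well_id = well_id, bit_depth = as.integer(bit_depth)),
            class = "srb_field")
}

#' Normalize well indices to time-matched controls
#'
#' Within each (isolation, duration) stratum the treated response is
#' 100 x mean treated index / mean control index, computed per
#' (condition, dose) within isolation and then summarized across isolations
#' (mean and SEM, each isolation counting once).
#'
#' @param results data.frame with columns `index`, `condition`, `dose`,
#'   `duration`, `isolation`, `is_control` (one row per well), e.g. the
#'   `$results` table of [run_plate()].
#' @return object of class `srb_responses`: `per_isolation` and `summary`
#'   data.frames.
#' @export
normalize_to_control <- function(results) {
  need <- c("index", "condition", "dose", "duration", "isolation", "is_control")
  if (!all(need %in% names(results)))
    stop("invalid input: results must have columns ",
         paste(need, collapse = ", "))
  results$is_control <- as.logical(results$is_control)
  strata <- unique(results[, c("isolation", "duration")])
  rows <- list()
  for (k in seq_len(nrow(strata))) {
    iso <- strata$isolation[k]
    dur <- strata$duration[k]
    s <- results[results$isolation == iso & results$duration == dur, , drop = FALSE]
    ctrl <- s[s$is_control, , drop = FALSE]
    trt <- s[!s$is_control, , drop = FALSE]
    if (nrow(trt) > 0 && nrow(ctrl) == 0)
      stop("missing control: stratum (isolation ", iso, ", duration ", dur,
           " h) has treated wells but no control well")
    if (nrow(ctrl) == 0) next
    ctrl_mean <- mean(ctrl$index)
    grp <- unique(s[, c("condition", "dose")])
    for (g in seq_len(nrow(grp))) {
      gg <- s[s$condition == grp$condition[g] & s$dose == grp$dose[g], , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        isolation = iso, duration = dur,
        condition = grp$condition[g], dose = grp$dose[g],
        n_wells = nrow(gg),
        response = 100 * mean(gg$index) / ctrl_mean)
    }
  }
  per_iso <- do.call(rbind, rows)
  agg <- aggregate(response ~ condition + dose + duration, per_iso, mean)
  names(agg)[names(agg) == "response"] <- "response_mean"
  agg$response_sem <- aggregate(response ~ condition + dose + duration, per_iso,
                                function(v) sd(v) / sqrt(length(v)))$response
  agg$n_isolations <- aggregate(response ~ condition + dose + duration, per_iso,
                                length)$response
  structure(list(per_isolation = per_iso, summary = agg),
            class = "srb_responses")
}

#' @export
print.srb_responses <- function(x, ...) {
  cat("Responses relative to time-matched controls (%):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
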