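#' Specification of a synthetic myocyte culture field
#'
#' Defaults emulate a control NRVM culture on a low-magnification plate
#' reader: ~2500 nuclear particles per field with cell-type fractions near
#' 77/16/7% (mononucleated myocytes / binucleated myocytes / fibroblasts),
#' myocyte nuclei smaller than fibroblast nuclei (log-normal area medians
#' 45 vs 120 um^2), an elongated binucleate circularity component
#' (median 2.2), size-independent nuclear SRB, cytoplasmic SRB whose
#' integrated intensity is proportional to per-cell biomass, additive
#' per-channel background, Gaussian noise, and a multiplicative gain (laser
#' power) applied to both channels last with saturation clipping at the
#' bit-depth maximum.
#'
#' @param field_size image dimensions in pixels (rows, columns).
#' @param pixel_size micrometres per pixel.
#' @param n_cells_by_type named counts for `mononucleate`, `binucleate`,
#'   `fibroblast`.
#' @param area_median,area_logsd log-normal nuclear-particle area parameters
#'   per type (um^2; the binucleate entry is used by the particle-table
#'   generator; rendered binucleate particles are fused ellipse pairs).
#' @param circ_median,circ_logsd log-normal circularity-ratio parameters per
#'   type (truncated at 1).
#' @param hoechst_nuclear_mean nuclear Hoechst intensity.
#' @param nuclear_srb_mean nuclear SRB intensity (size-independent).
#' @param biomass_per_cell integrated cytoplasmic SRB per cell
#'   (intensity x pixels).
#' @param biomass_logsd per-cell log-normal biomass variation.
#' @param halo_sigma cytoplasmic halo Gaussian sigma (um).
#' @param hypertrophy_factor multiplier on cytoplasmic biomass.
#' @param density_decay_k per-particle rate at which per-cell biomass falls
#'   with seeding density at fixed growth area (crowding limits cell
#'   expansion): effective biomass is scaled by
#'   `exp(-density_decay_k * (n_cells - density_ref))`. The default gives a
#'   greater than 2-fold index span between 1000 and 4500 particles per
#'   field.
#' @param density_ref reference particle count at which the biomass scale is
#'   exactly `biomass_per_cell`.
#' @param gain multiplicative gain applied to both channels.
#' @param background additive per-channel background, named `hoechst`, `srb`.
#' @param noise_sd additive Gaussian noise SD (intensity units, pre-gain).
#' @param bit_depth bit depth for saturation clipping.
#' @param seed integer seed; all generators are reproducible given
#'   (spec, seed).
#' @return object of class `srb_synth_spec`.
#' @export
synthetic_spec <- function(field_size = c(1600L, 1600L),
                           pixel_size = 1.25,
                           n_cells_by_type = c(mononucleate = 1925L,
                                               binucleate = 400L,
                                               fibroblast = 175L),
                           area_median = c(mononucleate = 45,
                                           binucleate = 90,
                                           fibroblast = 120),
                           area_logsd = c(mononucleate = 0.12,
                                          binucleate = 0.12,
                                          fibroblast = 0.12),
                           circ_median = c(mononucleate = 1.08,
                                           binucleate = 2.2,
                                           fibroblast = 1.10),
                           circ_logsd = c(mononucleate = 0.12,
                                          binucleate = 0.12,
                                          fibroblast = 0.12),
                           hoechst_nuclear_mean = 3000,
                           nuclear_srb_mean = 200,
                           biomass_per_cell = 6e4,
                           biomass_logsd = 0.2,
                           halo_sigma = 10,
                           hypertrophy_factor = 1,
                           density_decay_k = 2.3e-4,
                           density_ref = 2500,
                           gain = 1,
                           background = c(hoechst = 100, srb = 40),
                           noise_sd = 5,
                           bit_depth = 16L,
                           seed = 1L) {
  types <- c("mononucleate", "binucleate", "fibroblast")
  spec <- list(field_size = as.integer(field_size), pixel_size = pixel_size,
               n_cells_by_type = n_cells_by_type[types],
               area_median = area_median[types],
               area_logsd = area_logsd[types],
               circ_median = circ_median[types],
               circ_logsd = circ_logsd[types],
               hoechst_nuclear_mean = hoechst_nuclear_mean,
               nuclear_srb_mean = nuclear_srb_mean,
               biomass_per_cell = biomass_per_cell,
               biomass_logsd = biomass_logsd,
               halo_sigma = halo_sigma,
               hypertrophy_factor = hypertrophy_factor,
               density_decay_k = density_decay_k, density_ref = density_ref,
               gain = gain, background = background,
               noise_sd = noise_sd, bit_depth = as.integer(bit_depth),
               seed = as.integer(seed))
  if (anyNA(unlist(spec)))
    stop("validation error: missing or misnamed spec entries")
  if (any(spec$n_cells_by_type < 0))
    stop("validation error: cell counts must be non-negative")
  scl <- c(spec$pixel_size, spec$area_median, spec$area_logsd,
           spec$circ_logsd, spec$hoechst_nuclear_mean, spec$nuclear_srb_mean,
           spec$biomass_per_cell, spec$halo_sigma, spec$hypertrophy_factor,
           spec$gain)
  if (any(scl <= 0))
    stop("validation error: scales must be positive")
  if (any(spec$circ_median < 1))
    stop("validation error: circularity medians must be >= 1")
  structure(spec, class = "srb_synth_spec")
}

# Log-normal draw truncated below at `lower` (rejection sampling).
rlnorm_trunc <- function(n, median, sdlog, lower = 1) {
  out <- rlnorm(n, log(median), sdlog)
  bad <- out < lower
  while (any(bad)) {
    out[bad] <- rlnorm(sum(bad), log(median), sdlog)
    bad <- out < lower
  }
  out
}

#' Generate a synthetic nuclear-particle table with known types
#'
#' Draws per-type particle areas and circularity ratios from the spec's
#' log-normal distributions (circularity truncated at 1). Deterministic
#' given the spec's seed.
#'
#' @param spec an `srb_synth_spec`.
#' @param counts optional named per-type counts overriding the spec's.
#' @param n,fractions alternatively, a total particle count and cell-type
#'   fractions from which counts are drawn multinomially.
#' @return list with `particles` (data.frame `label`, `area`,
#'   `circularity_ratio`) and `truth` (data.frame `label`, `type`).
#' @export
generate_particle_table <- function(spec = synthetic_spec(), counts = NULL,
                                    n = NULL, fractions = NULL) {
  stopifnot(inherits(spec, "srb_synth_spec"))
  set.seed(spec$seed)
  if (!is.null(n) && !is.null(fractions)) {
    stopifnot(abs(sum(fractions) - 1) < 1e-8)
    counts <- setNames(as.integer(stats::rmultinom(1, n, fractions)),
                       names(spec$n_cells_by_type))
  }
  if (is.null(counts)) counts <- spec$n_cells_by_type
  types <- names(spec$n_cells_by_type)
  rows <- lapply(types, function(ty) {
    n <- counts[[ty]]
    if (n == 0) return(NULL)
    data.frame(type = ty,
               area = rlnorm(n, log(spec$area_median[[ty]]),
                             spec$area_logsd[[ty]]),
               circularity_ratio = rlnorm_trunc(n, spec$circ_median[[ty]],
                                                spec$circ_logsd[[ty]]))
  })
  tab <- do.call(rbind, rows)
  tab$label <- seq_len(nrow(tab))
  list(particles = tab[, c("label", "area", "circularity_ratio")],
       truth = tab[, c("label", "type")])
}

#' Simulate control-culture particle tables across wells
#'
#' Emulates pooling many control wells from several isolations: per-well
#' cell-type fractions are drawn from a Dirichlet distribution centred on
#' the control-culture means (default 77/16/7%, concentration 12 so the
#' mononucleate fraction varies with SD ~12 percentage points across wells),
#' well particle counts are Poisson, and particle geometry follows the
#' spec's per-type log-normals.
#'
#' @param n_wells number of wells.
#' @param mean_particles mean particles per well (Poisson).
#' @param fraction_mean mean cell-type fractions (mono, binucleate,
#'   fibroblast); must sum to 1.
#' @param concentration Dirichlet concentration (sum of alphas).
#' @param spec an `srb_synth_spec` supplying geometry distributions.
#' @param seed integer seed.
#' @return list with `particles` (data.frame `well`, `label`, `area`,
#'   `circularity_ratio`) and `truth` (data.frame with the true `type` and
#'   per-well `fractions` matrix).
#' @export
simulate_control_wells <- function(n_wells = 300, mean_particles = 600,
                                   fraction_mean = c(0.77, 0.16, 0.07),
                                   concentration = 12,
                                   spec = synthetic_spec(), seed = 1L) {
  stopifnot(abs(sum(fraction_mean) - 1) < 1e-8, n_wells >= 1)
  set.seed(seed)
  types <- names(spec$n_cells_by_type)
  alphas <- fraction_mean * concentration
  frac <- matrix(rgamma(n_wells * 3, shape = rep(alphas, each = n_wells)),
                 nrow = n_wells)
  frac <- frac / rowSums(frac)
  colnames(frac) <- types
  n_part <- stats::rpois(n_wells, mean_particles)
  rows <- vector("list", n_wells)
  for (w in seq_len(n_wells)) {
    cnt <- as.integer(stats::rmultinom(1, n_part[w], frac[w, ]))
    ty <- rep(types, cnt)
    rows[[w]] <- data.frame(
      well = sprintf("W%03d", w),
      type = ty,
      area = rlnorm(length(ty), log(spec$area_median[ty]),
                    spec$area_logsd[ty]),
      circularity_ratio = rlnorm_trunc_vec(ty, spec))
  }
  tab <- do.call(rbind, rows)
  tab$label <- seq_len(nrow(tab))
  list(particles = tab[, c("well", "label", "area", "circularity_ratio")],
       truth = list(types = tab[, c("well", "label", "type")],
                    fractions = frac))
}

# vectorized truncated log-normal circularity draw by type
rlnorm_trunc_vec <- function(types, spec) {
  out <- rlnorm(length(types), log(spec$circ_median[types]),
                spec$circ_logsd[types])
  bad <- which(out < 1)
  while (length(bad)) {
    out[bad] <- rlnorm(length(bad), log(spec$circ_median[types[bad]]),
                       spec$circ_logsd[types[bad]])
    bad <- bad[out[bad] < 1]
  }
  out
}

# Paint a filled rotated ellipse into `img`, returning modified pixels.
# cx, cy 0-based pixel coordinates; a, b semi-axes in pixels; theta radians.
ellipse_pixels <- function(dim_img, cx, cy, a, b, theta) {
  r0 <- max(floor(cy - a), 0); r1 <- min(ceiling(cy + a), dim_img[1] - 1)
  c0 <- max(floor(cx - a), 0); c1 <- min(ceiling(cx + a), dim_img[2] - 1)
  if (r1 < r0 || c1 < c0) return(integer(0))
  ys <- r0:r1; xs <- c0:c1
  dy <- matrix(ys - cy, length(ys), length(xs))
  dx <- matrix(xs - cx, length(ys), length(xs), byrow = TRUE)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  ri <- row(inside)[inside] + r0      # 1-based row index
  ci <- col(inside)[inside] + c0
  (ci - 1L) * dim_img[1] + ri          # linear indices
}

#' Render a synthetic paired Hoechst/SRB field with ground truth
#'
#' Nuclei are rendered as bright ellipses on the Hoechst channel (binucleate
#' cells as two overlapping ellipses forming one elongated connected
#' particle). The SRB channel carries the nuclear regions at the
#' size-independent nuclear SRB level plus per-cell cytoplasmic Gaussian
#' halos whose integrated intensity equals the per-cell biomass times the
#' hypertrophy factor; halos of neighbouring cells add. Background and
#' Gaussian noise are added, then the gain multiplies both channels and
#' values are clipped at the bit-depth maximum (so gain-invariance breakdown
#' under saturation can be probed). The analytic expected index is computed
#' from the noise-free, background-free render and the true labels.
#'
#' @param spec an `srb_synth_spec`.
#' @param max_tries placement retries per cell before a density error.
#' @return list with `field` (an `srb_field`) and `truth` (list: `n_cells`,
#'   `cells` data.frame with type/centre/biomass, `labels` true label
#'   matrix, `expected_index`, `esrb_clean`, `nsrb_clean`).
#' @export
generate_field_images <- function(spec = synthetic_spec(), max_tries = 200) {
  stopifnot(inherits(spec, "srb_synth_spec"))
  set.seed(spec$seed)
  ps <- spec$pixel_size
  dims <- spec$field_size
  types <- rep(names(spec$n_cells_by_type), spec$n_cells_by_type)
  n_cells <- length(types)
  if (n_cells == 0) stop("validation error: no cells requested")
  types <- sample(types)  # shuffle placement order
  # per-cell nuclear geometry (um)
  is_bi <- types == "binucleate"
  area <- rlnorm(n_cells, log(spec$area_median["mononucleate"]),
                 spec$area_logsd["mononucleate"])
  area[!is_bi] <- rlnorm(sum(!is_bi), log(spec$area_median[types[!is_bi]]),
                         spec$area_logsd[types[!is_bi]])
  circ <- rlnorm_trunc_vec(ifelse(is_bi, "mononucleate", types), spec)
  a_um <- sqrt(area * circ / pi)       # semi-major
  b_um <- sqrt(area / (pi * circ))     # semi-minor
  # binucleate: two mono-sized lobes offset along the pair axis
  lobe_sep <- ifelse(is_bi, 1.4 * sqrt(area / pi), 0)
  extent <- (a_um + lobe_sep) / ps     # px, collision radius
  theta <- runif(n_cells, 0, pi)
  # placement with pairwise separation
  margin <- max(extent) + 2
  cx <- numeric(n_cells); cy <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      px <- runif(1, margin, dims[2] - 1 - margin)
      py <- runif(1, margin, dims[1] - 1 - margin)
      if (i == 1) { ok <- TRUE } else {
        j <- seq_len(i - 1)
        ok <- all((px - cx[j])^2 + (py - cy[j])^2 >
                    (extent[i] + extent[j] + 2)^2)
      }
      if (ok) break
    }
    if (!ok) stop("density error: could not place cell ", i, " after ",
                  max_tries, " retries")
    cx[i] <- px; cy[i] <- py
  }
  # render nuclei and true labels
  labels <- matrix(0L, dims[1], dims[2])
  for (i in seq_len(n_cells)) {
    if (is_bi[i]) {
      off <- lobe_sep[i] / 2 / ps
      idx <- c(ellipse_pixels(dims, cx[i] - off * cos(theta[i]),
                              cy[i] - off * sin(theta[i]),
                              a_um[i] / ps, b_um[i] / ps, theta[i]),
               ellipse_pixels(dims, cx[i] + off * cos(theta[i]),
                              cy[i] + off * sin(theta[i]),
                              a_um[i] / ps, b_um[i] / ps, theta[i]))
    } else {
      idx <- ellipse_pixels(dims, cx[i], cy[i], a_um[i] / ps, b_um[i] / ps,
                            theta[i])
    }
    labels[idx] <- i
  }
  hoechst_clean <- matrix(0, dims[1], dims[2])
  hoechst_clean[labels > 0L] <- spec$hoechst_nuclear_mean
  # SRB: cytoplasmic halos (additive where cells overlap), deposited on
  # extra-nuclear pixels only, plus nuclear regions at the size-independent
  # nuclear level — so nuclear SRB is independent of biomass by construction
  density_scale <- exp(-spec$density_decay_k * (n_cells - spec$density_ref))
  biomass <- rlnorm(n_cells,
                    log(spec$biomass_per_cell * spec$hypertrophy_factor *
                          density_scale) - spec$biomass_logsd^2 / 2,
                    spec$biomass_logsd)
  sig_px <- spec$halo_sigma / ps
  half <- ceiling(3.5 * sig_px)
  srb_clean <- matrix(0, dims[1], dims[2])
  for (i in seq_len(n_cells)) {
    r0 <- max(floor(cy[i] - half), 0); r1 <- min(ceiling(cy[i] + half), dims[1] - 1)
    c0 <- max(floor(cx[i] - half), 0); c1 <- min(ceiling(cx[i] + half), dims[2] - 1)
    ys <- r0:r1; xs <- c0:c1
    gy <- exp(-((ys - cy[i])^2) / (2 * sig_px^2))
    gx <- exp(-((xs - cx[i])^2) / (2 * sig_px^2))
    srb_clean[ys + 1, xs + 1] <- srb_clean[ys + 1, xs + 1] +
      biomass[i] / (2 * pi * sig_px^2) * outer(gy, gx)
  }
  srb_clean[labels > 0L] <- spec$nuclear_srb_mean
  # analytic expected index from the clean render
  nuc <- labels > 0L
  esrb_clean <- sum(srb_clean[!nuc])
  l <- labels[nuc]
  nsrb_clean <- mean(rowsum(as.numeric(srb_clean[nuc]), l)[, 1] /
                       tabulate(l, nbins = n_cells))
  expected_index <- esrb_clean / (nsrb_clean * n_cells)
  # noise, background, gain, saturation
  maxv <- 2^spec$bit_depth - 1
  finish <- function(clean, bg) {
    img <- spec$gain * (clean + bg +
                          matrix(rnorm(length(clean), 0, spec$noise_sd),
                                 nrow(clean)))
    pmin(pmax(img, 0), maxv)
  }
  hoechst <- finish(hoechst_clean, spec$background[["hoechst"]])
  srb <- finish(srb_clean, spec$background[["srb"]])
  field <- srb_field(hoechst, srb, pixel_size = ps,
                     well_id = "synthetic", bit_depth = spec$bit_depth)
  truth <- list(n_cells = n_cells,
                cells = data.frame(id = seq_len(n_cells), type = types,
                                   x = cx, y = cy, biomass = biomass),
                labels = labels, expected_index = expected_index,
                esrb_clean = esrb_clean, nsrb_clean = nsrb_clean)
  list(field = field, truth = truth)
}

#' Build a factorial plate design
#'
#' @param doses treatment doses (uM); dose 0 rows become controls unless
#'   `control_condition` rows are added explicitly.
#' @param n_isolations biological isolations.
#' @param n_replicates technical repeats per isolation and dose.
#' @param condition condition label for treated wells.
#' @param duration treatment duration (hours).
#' @return data.frame with one row per well: `well_id`, `condition`, `dose`,
#'   `duration`, `isolation`, `is_control`.
#' @export
plate_design <- function(doses, n_isolations = 4, n_replicates = 4,
                         condition = "PE", duration = 48) {
  g <- expand.grid(replicate = seq_len(n_replicates),
                   dose = doses,
                   isolation = seq_len(n_isolations))
  g$condition <- ifelse(g$dose == 0, "control", condition)
  g$is_control <- g$dose == 0
  g$duration <- duration
  g$well_id <- sprintf("I%02d_D%g_R%d", g$isolation, g$dose, g$replicate)
  g[, c("well_id", "condition", "dose", "duration", "isolation", "is_control")]
}

#' Generate a synthetic plate dataset with known effects
#'
#' Simulates per-well ratiometric indices for a plate design: a baseline
#' index, a dose effect through a Hill model on the hypertrophy factor
#' (`effect$params` as `R0`, `Rhyp`, `n`, `EC50`; the multiplier at dose d is
#' `hill(d)/R0`), a log-normal isolation-level random effect whose variance
#' is set by `target_icc` relative to the well-level log-noise, and
#' log-normal well noise. With `mode = "images"` full image fields are
#' rendered per well instead (slow; intended for small designs).
#'
#' @param design a [plate_design()] data.frame.
#' @param spec base `srb_synth_spec`.
#' @param effect `NULL` (no condition effect) or
#'   `list(params = c(R0 =, Rhyp =, n =, EC50 =))`.
#' @param target_icc intraclass correlation of the isolation random effect.
#' @param well_sdlog well-level log-normal noise SD.
#' @param seed integer seed.
#' @param mode `"tables"` (per-well indices) or `"images"` (rendered
#'   fields).
#' @return list with `wells` (design plus `index`, or plus `field` list in
#'   image mode) and `truth` (isolation multipliers, dose multipliers,
#'   baseline index).
#' @export
generate_plate_dataset <- function(design, spec = synthetic_spec(),
                                   effect = NULL, target_icc = 0.5,
                                   well_sdlog = 0.05, seed = 1L,
                                   mode = c("tables", "images")) {
  mode <- match.arg(mode)
  need <- c("well_id", "condition", "dose", "duration", "isolation", "is_control")
  if (!all(need %in% names(design)))
    stop("validation error: design must have columns ",
         paste(need, collapse = ", "))
  if (anyDuplicated(design$well_id))
    stop("validation error: duplicate well_id in design")
  set.seed(seed)
  iso_sdlog <- if (target_icc <= 0) 0 else
    well_sdlog * sqrt(target_icc / (1 - target_icc))
  isos <- sort(unique(design$isolation))
  iso_mult <- setNames(rlnorm(length(isos), -iso_sdlog^2 / 2, iso_sdlog),
                       as.character(isos))
  h <- rep(1, nrow(design))
  if (!is.null(effect)) {
    p <- effect$params
    h <- hill_response(design$dose, p) / p[["R0"]]
  }
  base_index <- spec$biomass_per_cell / spec$nuclear_srb_mean
  wells <- design
  if (mode == "tables") {
    wells$index <- base_index * h * iso_mult[as.character(design$isolation)] *
      rlnorm(nrow(design), -well_sdlog^2 / 2, well_sdlog)
  } else {
    seeds <- sample.int(2^30, nrow(design))
    wells$field <- lapply(seq_len(nrow(design)), function(i) {
      sp <- spec
      sp$hypertrophy_factor <- spec$hypertrophy_factor * h[i] *
        iso_mult[[as.character(design$isolation[i])]]
      sp$seed <- seeds[i]
      out <- generate_field_images(sp)
      out$field$well_id <- design$well_id[i]
      out
    })
  }
  list(wells = wells,
       truth = list(base_index = base_index, iso_mult = iso_mult,
                    dose_mult = h, target_icc = target_icc))
}
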