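#' Estimate the background level of a fluorescence image
#'
#' The background is taken as the modal intensity of the image: in sparse
#' cultures most pixels are non-cell background, so the histogram mode is
#' the dominant non-cell level. The mode is located with the half-sample
#' method (recursively narrowing to the half of the sorted intensities with
#' the smallest range), which is exactly equivariant under multiplicative
#' gain — a fixed-bin histogram mode is not, and would break the
#' gain-invariance of the ratiometric index. Subtracting the background and
#' clipping at zero defines the corrected image used by all downstream
#' steps.
#'
#' @param image numeric matrix of non-negative intensities.
#' @return scalar background intensity.
#' @examples
#' estimate_background(matrix(5, 10, 10)) # 5
#' @export
estimate_background <- function(image) {
  if (!is.numeric(image) || length(image) == 0)
    stop("invalid input: 'image' must be a non-empty numeric matrix")
  v <- as.numeric(image)
  if (anyNA(v) || any(v < 0))
    stop("invalid input: intensities must be non-negative and non-missing")
  v <- sort(v)
  # half-sample mode (Bickel). Digitized images produce runs of tied
  # minimal-range windows; taking the middle tied window keeps the estimate
  # centred on the modal plateau (and deterministic) instead of drifting to
  # its low edge.
  while (length(v) > 3) {
    k <- ceiling(length(v) / 2)
    ranges <- v[k:length(v)] - v[seq_len(length(v) - k + 1)]
    tied <- which(ranges <= min(ranges))
    i <- tied[(length(tied) + 1L) %/% 2L]
    v <- v[i:(i + k - 1)]
  }
  mean(v)
}

#' Ridler-Calvard (isodata, intermeans) automatic threshold
#'
#' Iterates the intermeans recursion T[k+1] = (mean below T[k] + mean above
#' T[k]) / 2, starting from the global mean, until successive thresholds
#' differ by less than `tol`. At convergence the threshold lies strictly
#' between the two class means.
#'
#' @param image numeric matrix (or vector) with at least two distinct values.
#' @param tol convergence tolerance in intensity units.
#' @param max_iter maximum number of iterations.
#' @return scalar threshold.
#' @examples
#' ridler_calvard_threshold(c(rep(10, 50), rep(200, 50))) # 105
#' @export
ridler_calvard_threshold <- function(image, tol = 0.5, max_iter = 100) {
  v <- as.numeric(image)
  if (length(v) == 0 || anyNA(v))
    stop("invalid input: empty or missing intensities")
  if (diff(range(v)) == 0)
    stop("degenerate input: constant image has no threshold")
  thr <- mean(v)
  for (i in seq_len(max_iter)) {
    lo <- v[v <= thr]
    hi <- v[v > thr]
    # guard: keep both classes populated (thr can only leave [min, max)
    # through numeric pathology)
    if (length(lo) == 0 || length(hi) == 0) break
    new_thr <- (mean(lo) + mean(hi)) / 2
    if (abs(new_thr - thr) < tol) {
      thr <- new_thr
      break
    }
    thr <- new_thr
  }
  thr
}

# Merge 4-connected labels that touch diagonally, giving 8-connected
# components. Union-find over the (small) label graph.
label_components8 <- function(binary) {
  lab <- EBImage::bwlabel(binary)
  lab <- matrix(as.integer(lab), nrow(binary), ncol(binary))
  n <- max(lab)
  if (n <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]   # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]  # down-left diagonal
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

#' Build a labelled nuclear mask from a Hoechst image
#'
#' Background-subtracts the image (histogram mode, clipped at zero),
#' thresholds it with the Ridler-Calvard intermeans method, labels connected
#' components with 8-connectivity (touching nuclei, e.g. binucleate pairs,
#' form a single elongated particle) and discards components smaller than
#' `min_area`. A degenerate threshold (blank well) yields an empty mask with
#' a warning rather than an error.
#'
#' @param hoechst numeric matrix, Hoechst channel.
#' @param pixel_size micrometres per pixel (> 0).
#' @param min_area minimum particle area in square micrometres; smaller
#'   components are treated as debris.
#' @param exclude_border drop particles touching the image border
#'   (default `FALSE`: plate-reader fields are large and exclusion would
#'   bias density estimates).
#' @return an object of class `srb_mask`: list with `labels` (integer
#'   matrix, 0 = non-nuclear), `threshold`, `background`, `n_particles`,
#'   `pixel_size`.
#' @export
build_nuclear_mask <- function(hoechst, pixel_size = 1, min_area = 20,
                               exclude_border = FALSE) {
  stopifnot(is.matrix(hoechst), pixel_size > 0)
  bg <- estimate_background(hoechst)
  img <- pmax(hoechst - bg, 0)
  empty <- function(thr) {
    structure(list(labels = matrix(0L, nrow(hoechst), ncol(hoechst)),
                   threshold = thr, background = bg, n_particles = 0L,
                   pixel_size = pixel_size),
              class = "srb_mask")
  }
  thr <- tryCatch(ridler_calvard_threshold(img), error = function(e) NA_real_)
  if (is.na(thr)) {
    warning("degenerate threshold (blank or constant field): empty mask")
    return(empty(NA_real_))
  }
  lab <- label_components8(img > thr)
  if (max(lab) > 0L) {
    npx <- tabulate(lab[lab > 0L])
    keep <- which(npx * pixel_size^2 >= min_area)
    if (exclude_border) {
      border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
      keep <- setdiff(keep, border[border > 0L])
    }
    remap <- integer(max(lab))
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  structure(list(labels = lab, threshold = thr, background = bg,
                 n_particles = as.integer(max(lab)),
                 pixel_size = pixel_size),
            class = "srb_mask")
}

#' @export
print.srb_mask <- function(x, ...) {
  cat("Nuclear mask:", x$n_particles, "particles;",
      "threshold", format(x$threshold, digits = 4),
      "above background", format(x$background, digits = 4), "\n")
  invisible(x)
}

#' Measure geometry of nuclear particles
#'
#' For each labelled component: area (pixel count times squared pixel size),
#' centroid (0-based, x = column, y = row), and the major/minor axes of the
#' ellipse with the same normalized second central moments as the component
#' (pixels treated as unit squares, so a single pixel has equal finite axes).
#' The circularity ratio is the quotient of long-axis to short-axis diameter:
#' about 1 for round nuclei, much greater than 1 for elongated binucleate
#' particles.
#'
#' @param mask an `srb_mask`.
#' @param hoechst Hoechst image (same shape as the mask) used for the
#'   per-particle mean intensity; may be `NULL`.
#' @param pixel_size micrometres per pixel; defaults to the mask's.
#' @return data.frame with one row per particle: `label`, `area` (um^2),
#'   `x`, `y`, `long_axis` (um), `short_axis` (um), `circularity_ratio`,
#'   `mean_hoechst`, `n_pixels`.
#' @export
measure_particles <- function(mask, hoechst = NULL, pixel_size = NULL) {
  stopifnot(inherits(mask, "srb_mask"))
  if (is.null(pixel_size)) pixel_size <- mask$pixel_size
  lab <- mask$labels
  if (!is.null(hoechst) && !identical(dim(lab), dim(hoechst)))
    stop("invalid input: mask and image differ in shape")
  n <- mask$n_particles
  if (n == 0L) {
    return(data.frame(label = integer(0), area = numeric(0), x = numeric(0),
                      y = numeric(0), long_axis = numeric(0),
                      short_axis = numeric(0), circularity_ratio = numeric(0),
                      mean_hoechst = numeric(0), n_pixels = integer(0)))
  }
  idx <- which(lab > 0L)
  l <- lab[idx]
  if (!setequal(unique(l), seq_len(n)))
    stop("internal consistency error: mask labels are not 1..n_particles")
  row_i <- (idx - 1L) %% nrow(lab)       # 0-based y
  col_j <- (idx - 1L) %/% nrow(lab)      # 0-based x
  npx <- tabulate(l, nbins = n)
  sx <- rowsum(as.numeric(col_j), l)[, 1]
  sy <- rowsum(as.numeric(row_i), l)[, 1]
  sxx <- rowsum(as.numeric(col_j)^2, l)[, 1]
  syy <- rowsum(as.numeric(row_i)^2, l)[, 1]
  sxy <- rowsum(as.numeric(col_j) * row_i, l)[, 1]
  cx <- sx / npx
  cy <- sy / npx
  # central second moments with the unit-pixel-square term 1/12
  mxx <- sxx / npx - cx^2 + 1 / 12
  myy <- syy / npx - cy^2 + 1 / 12
  mxy <- sxy / npx - cx * cy
  tr <- mxx + myy
  det_ <- mxx * myy - mxy^2
  disc <- sqrt(pmax((tr / 2)^2 - det_, 0))
  lam1 <- tr / 2 + disc
  lam2 <- pmax(tr / 2 - disc, .Machine$double.eps)
  long_axis <- 4 * sqrt(lam1) * pixel_size
  short_axis <- 4 * sqrt(lam2) * pixel_size
  mh <- if (is.null(hoechst)) rep(NA_real_, n) else
    rowsum(as.numeric(hoechst[idx]), l)[, 1] / npx
  data.frame(label = seq_len(n),
             area = npx * pixel_size^2,
             x = cx, y = cy,
             long_axis = long_axis, short_axis = short_axis,
             circularity_ratio = long_axis / short_axis,
             mean_hoechst = mh,
             n_pixels = npx)
}

#' Read a single-channel grayscale TIFF as an intensity matrix
#'
#' Values are returned on the native integer scale of the file (8- or
#' 16-bit), not rescaled to `[0, 1]`.
#'
#' @param path TIFF file path.
#' @return numeric matrix of intensities.
#' @export
read_channel_tiff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  storage.mode(img) <- "double"
  img
}

#' Write an intensity matrix as a 16-bit grayscale TIFF
#'
#' @param image numeric matrix of intensities in `[0, 65535]`.
#' @param path output file path.
#' @export
write_channel_tiff <- function(image, path) {
  stopifnot(is.matrix(image))
  tiff::writeTIFF(pmin(pmax(image, 0), 65535) / 65535, path,
                  bits.per.sample = 16L, compression = "none")
  invisible(path)
}
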