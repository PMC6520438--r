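# Shared fixtures, all generated in code.

control_fractions <- c(mononucleate = 0.77, binucleate = 0.16,
                       fibroblast = 0.07)

# Small rendered field spec: ~200 cells on a 640 px (800 um) square.
small_field_spec <- function(seed = 3, ...) {
  synthetic_spec(field_size = c(640L, 640L),
                 n_cells_by_type = round(200 * control_fractions),
                 seed = seed, ...)
}

# Filled disc of radius r (pixels) at (cx, cy) in an nr x nc matrix.
disc_image <- function(nr, nc, cx, cy, r, value = 1000, background = 0) {
  m <- matrix(background, nr, nc)
  for (i in seq_len(nr)) {
    dx2 <- (seq_len(nc) - cx)^2
    m[i, dx2 + (i - cy)^2 <= r^2] <- value
  }
  m
}

# Circularity mixture object with known parameters (for classification
# oracles).
mixture_from_params <- function(weights, medians, log_sds) {
  structure(list(weights = weights, log_means = log(medians),
                 log_sds = log_sds, converged = TRUE, loglik = NA_real_,
                 loglik_trace = numeric(0), n_iter = 0L),
            class = "srb_circ_mixture")
}

area_cutoff_from_value <- function(cutoff) {
  structure(list(cutoff = cutoff, degenerate = FALSE,
                 method_detail = "fixed", component_params = NULL),
            class = "srb_area_cutoff")
}
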