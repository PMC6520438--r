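#' Two-component Gaussian mixture by EM (one-dimensional)
#'
#' Deterministic EM: components are initialized by splitting the data at the
#' median, the log-likelihood is tracked every iteration (it is
#' non-decreasing, an EM guarantee the tests exercise), and components are
#' ordered by mean on return. Used on log(area) for the size cutoff and on
#' log(circularity ratio) for the fibroblast/binucleate split, i.e. the data
#' are modelled as two log-normals.
#'
#' @param x numeric vector.
#' @param max_iter maximum EM iterations.
#' @param tol absolute tolerance on the log-likelihood increase.
#' @return list with `weights`, `means`, `sds` (component order: increasing
#'   mean), `loglik`, `loglik_trace`, `converged`, `n_iter`.
#' @keywords internal
em_mixture2 <- function(x, max_iter = 500, tol = 1e-8) {
  x <- as.numeric(x)
  n <- length(x)
  sd_floor <- max(sd(x), .Machine$double.eps) * 1e-4
  if (sd(x) == 0 || n < 4) {
    return(list(weights = c(0.5, 0.5), means = rep(mean(x), 2),
                sds = rep(sd_floor, 2), loglik = NA_real_,
                loglik_trace = numeric(0), converged = FALSE, n_iter = 0L))
  }
  med <- median(x)
  g <- x <= med
  if (all(g) || !any(g)) g <- x <= mean(x)
  mu <- c(mean(x[g]), mean(x[!g]))
  sg <- pmax(c(sd(x[g]), sd(x[!g])), sd_floor)
  sg[is.na(sg)] <- sd_floor
  w <- c(mean(g), 1 - mean(g))
  loglik <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    d1 <- log(w[1]) + dnorm(x, mu[1], sg[1], log = TRUE)
    d2 <- log(w[2]) + dnorm(x, mu[2], sg[2], log = TRUE)
    m <- pmax(d1, d2)
    ll <- sum(m + log(exp(d1 - m) + exp(d2 - m)))
    trace <- c(trace, ll)
    if (is.finite(loglik) && abs(ll - loglik) < tol) {
      loglik <- ll
      converged <- TRUE
      break
    }
    loglik <- ll
    r2 <- 1 / (1 + exp(d1 - d2))
    r1 <- 1 - r2
    w <- c(mean(r1), mean(r2))
    w <- pmin(pmax(w, 1e-10), 1 - 1e-10)
    mu <- c(sum(r1 * x) / sum(r1), sum(r2 * x) / sum(r2))
    sg <- sqrt(c(sum(r1 * (x - mu[1])^2) / sum(r1),
                 sum(r2 * (x - mu[2])^2) / sum(r2)))
    sg <- pmax(sg, sd_floor)
  }
  ord <- order(mu)
  list(weights = w[ord] / sum(w[ord]), means = mu[ord], sds = sg[ord],
       loglik = loglik, loglik_trace = trace, converged = converged,
       n_iter = iter)
}

# Equal-posterior crossing point of two weighted Gaussians, searched
# between the component means.
mixture_crossing <- function(weights, means, sds) {
  f <- function(x) {
    log(weights[1]) + dnorm(x, means[1], sds[1], log = TRUE) -
      log(weights[2]) - dnorm(x, means[2], sds[2], log = TRUE)
  }
  lo <- means[1]
  hi <- means[2]
  if (f(lo) > 0 && f(hi) < 0) {
    uniroot(f, c(lo, hi), tol = 1e-10)$root
  } else {
    grid <- seq(lo, hi, length.out = 2001)
    grid[which.min(abs(f(grid)))]
  }
}

#' Determine the mononucleate size cutoff from particle areas
#'
#' Fits a two-component Gaussian mixture to log(area) and places the cutoff
#' at the equal-posterior point between the lower (mononucleated myocyte) and
#' upper (fibroblast/binucleate) components. If the two components are
#' indistinguishable (|difference of means| < 0.5 pooled SD on the log
#' scale, or a single Gaussian is preferred by BIC), the fit is flagged
#' degenerate and a fixed fallback cutoff is used (default: twice the median
#' particle area).
#'
#' @param particles particle data.frame with an `area` column (um^2), or a
#'   numeric vector of areas.
#' @param fallback_cutoff fixed cutoff (um^2) used when the mixture is
#'   degenerate; default `2 * median(area)`.
#' @return object of class `srb_area_cutoff`: `cutoff` (um^2), `degenerate`,
#'   `method_detail`, `component_params`.
#' @export
determine_area_cutoff <- function(particles, fallback_cutoff = NULL) {
  area <- if (is.data.frame(particles)) particles$area else as.numeric(particles)
  if (length(area) < 50)
    stop("insufficient data: need >= 50 particles to fit the area mixture")
  if (any(area <= 0)) stop("invalid input: areas must be positive")
  if (is.null(fallback_cutoff)) fallback_cutoff <- 2 * median(area)
  la <- log(area)
  fit <- em_mixture2(la)
  pooled_sd <- sqrt(sum(fit$weights * fit$sds^2))
  # degenerate when the components are indistinguishable, or when a single
  # Gaussian explains log-area as well as the mixture (EM happily splits a
  # unimodal population into two overlapping components, which the
  # mean-separation rule alone does not catch)
  n <- length(la)
  ll1 <- sum(dnorm(la, mean(la), sqrt(var(la) * (n - 1) / n), log = TRUE))
  bic1 <- -2 * ll1 + 2 * log(n)
  bic2 <- -2 * fit$loglik + 5 * log(n)
  degenerate <- !is.finite(fit$loglik) ||
    abs(diff(fit$means)) < 0.5 * pooled_sd || bic2 >= bic1
  if (degenerate) {
    cutoff <- fallback_cutoff
    detail <- "degenerate mixture; fixed fallback cutoff"
  } else {
    cutoff <- exp(mixture_crossing(fit$weights, fit$means, fit$sds))
    detail <- "equal-posterior point of two-component log-area mixture"
  }
  structure(list(cutoff = cutoff, degenerate = degenerate,
                 method_detail = detail,
                 component_params = data.frame(
                   log_mean = fit$means, log_sd = fit$sds,
                   weight = fit$weights)),
            class = "srb_area_cutoff")
}

#' @export
print.srb_area_cutoff <- function(x, ...) {
  cat("Mononucleate area cutoff:", format(x$cutoff, digits = 4), "um^2",
      if (x$degenerate) "(degenerate fit, fallback used)" else "", "\n")
  invisible(x)
}

#' Fit the circularity mixture separating fibroblasts from binucleates
#'
#' EM fit of a two-component Gaussian mixture to log(circularity ratio) of
#' the particles above the area cutoff. Component 1 is the lower-mean
#' (more circular, fibroblast) component; component 2 the higher-mean
#' (elongated, binucleate-myocyte) component. Deterministic: initialization
#' is a median split, so `seed` only matters if callers add stochastic
#' restarts.
#'
#' @param large_particles particle data.frame with `circularity_ratio`, or a
#'   numeric vector of circularity ratios; particles above the area cutoff.
#' @param seed unused by the deterministic fit; kept for interface stability.
#' @param max_iter,tol EM controls.
#' @return object of class `srb_circ_mixture`: `weights`, `log_means`,
#'   `log_sds`, `converged`, `loglik`, `loglik_trace`.
#' @export
fit_circularity_mixture <- function(large_particles, seed = 1L,
                                    max_iter = 500, tol = 1e-8) {
  circ <- if (is.data.frame(large_particles)) large_particles$circularity_ratio
          else as.numeric(large_particles)
  if (length(circ) < 30)
    stop("insufficient data: need >= 30 particles above the area cutoff")
  if (any(circ < 1)) stop("invalid input: circularity ratios must be >= 1")
  fit <- em_mixture2(log(circ), max_iter = max_iter, tol = tol)
  structure(list(weights = fit$weights, log_means = fit$means,
                 log_sds = fit$sds, converged = fit$converged,
                 loglik = fit$loglik, loglik_trace = fit$loglik_trace,
                 n_iter = fit$n_iter),
            class = "srb_circ_mixture")
}

#' @export
print.srb_circ_mixture <- function(x, ...) {
  cat("Circularity mixture (log-normal components):\n")
  cat(sprintf("  fibroblast: median %.3f (log-sd %.3f), weight %.3f\n",
              exp(x$log_means[1]), x$log_sds[1], x$weights[1]))
  cat(sprintf("  binucleate: median %.3f (log-sd %.3f), weight %.3f\n",
              exp(x$log_means[2]), x$log_sds[2], x$weights[2]))
  if (!x$converged) cat("  [not converged]\n")
  invisible(x)
}

# Posterior probability of the binucleate (high-circularity) component.
posterior_binucleate <- function(circ, mixture) {
  x <- log(circ)
  d1 <- log(mixture$weights[1]) + dnorm(x, mixture$log_means[1],
                                        mixture$log_sds[1], log = TRUE)
  d2 <- log(mixture$weights[2]) + dnorm(x, mixture$log_means[2],
                                        mixture$log_sds[2], log = TRUE)
  1 / (1 + exp(d1 - d2))
}

#' Classify nuclear particles into cell types
#'
#' Particles at or below the area cutoff are mononucleated myocytes. Larger
#' particles are assigned fibroblast or binucleate myocyte by maximum
#' posterior under the circularity mixture, with ties broken toward
#' fibroblast.
#'
#' @param particles particle data.frame (`area`, `circularity_ratio`).
#' @param cutoff an `srb_area_cutoff` (or a numeric cutoff in um^2).
#' @param mixture an `srb_circ_mixture`.
#' @return factor with levels `mononucleate`, `binucleate`, `fibroblast`.
#' @export
classify_particles <- function(particles, cutoff, mixture) {
  co <- if (inherits(cutoff, "srb_area_cutoff")) cutoff$cutoff else cutoff
  stopifnot(inherits(mixture, "srb_circ_mixture"), is.numeric(co))
  out <- rep("mononucleate", nrow(particles))
  large <- particles$area > co
  if (any(large)) {
    p2 <- posterior_binucleate(particles$circularity_ratio[large], mixture)
    out[large] <- ifelse(p2 > 0.5, "binucleate", "fibroblast")
  }
  factor(out, levels = c("mononucleate", "binucleate", "fibroblast"))
}

#' Tally a cell census from particle classifications
#'
#' Each particle is one cell: a binucleate particle (fused or touching
#' nucleus pair) counts as a single binucleated myocyte. By default the
#' total cell count used in the ratiometric index includes fibroblasts (no
#' further correction factors are applied); set
#' `include_fibroblasts = FALSE` for myocyte-only counting.
#'
#' @param labels factor from [classify_particles()].
#' @param include_fibroblasts include fibroblasts in `n_cells`.
#' @return object of class `srb_census`: `n_mono`, `n_binucleate`,
#'   `n_fibroblast`, `n_cells`, `fractions`.
#' @export
census_cells <- function(labels, include_fibroblasts = TRUE) {
  labels <- factor(labels, levels = c("mononucleate", "binucleate", "fibroblast"))
  counts <- as.integer(table(labels))
  names(counts) <- levels(labels)
  total <- sum(counts)
  n_cells <- counts[["mononucleate"]] + counts[["binucleate"]] +
    if (include_fibroblasts) counts[["fibroblast"]] else 0L
  fractions <- if (total > 0) counts / total else setNames(rep(NA_real_, 3), names(counts))
  structure(list(n_mono = counts[["mononucleate"]],
                 n_binucleate = counts[["binucleate"]],
                 n_fibroblast = counts[["fibroblast"]],
                 n_cells = as.integer(n_cells),
                 fractions = fractions,
                 include_fibroblasts = include_fibroblasts),
            class = "srb_census")
}

#' @export
print.srb_census <- function(x, ...) {
  cat("Cell census:", x$n_cells, "cells\n")
  cat(sprintf("  mononucleate myocytes: %d (%.1f%%)\n", x$n_mono,
              100 * x$fractions[["mononucleate"]]))
  cat(sprintf("  binucleate myocytes:   %d (%.1f%%)\n", x$n_binucleate,
              100 * x$fractions[["binucleate"]]))
  cat(sprintf("  fibroblasts:           %d (%.1f%%)\n", x$n_fibroblast,
              100 * x$fractions[["fibroblast"]]))
  invisible(x)
}
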