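#' Hill concentration-response model
#'
#' Evaluates `R0 + Rhyp * dose^n / (EC50^n + dose^n)`: `R0` is the baseline
#' response, `Rhyp` the maximal increase, `n` the cooperativity and `EC50`
#' the dose of half-maximal effect. Dose 0 returns `R0` exactly.
#'
#' @param dose dose(s), micromolar, non-negative.
#' @param params an `srb_hill` fit or a named numeric vector with `R0`,
#'   `Rhyp`, `n`, `EC50`.
#' @return response at each dose.
#' @examples
#' hill_response(0.185, c(R0 = 0.266, Rhyp = 0.174, n = 0.50, EC50 = 0.185))
#' @export
hill_response <- function(dose, params) {
  p <- if (inherits(params, "srb_hill")) coef(params) else params
  stopifnot(all(c("R0", "Rhyp", "n", "EC50") %in% names(p)))
  if (any(dose < 0)) stop("invalid input: dose must be non-negative")
  dn <- dose^p[["n"]]
  p[["R0"]] + p[["Rhyp"]] * dn / (p[["EC50"]]^p[["n"]] + dn)
}

hill_bounds <- list(lower = c(R0 = 1e-12, Rhyp = 0, n = 1e-6, EC50 = 1e-4),
                    upper = c(R0 = Inf, Rhyp = Inf, n = 5, EC50 = 1e3))

# Inverse-variance weights per dose when >= 3 replicates everywhere and the
# per-dose variances are informative; otherwise unweighted.
replicate_weights <- function(doses, responses) {
  v <- tapply(responses, doses, var)
  n <- tapply(responses, doses, length)
  if (all(n >= 3) && all(is.finite(v)) && all(v > 0)) {
    as.numeric((1 / v)[match(as.character(doses), names(v))])
  } else rep(1, length(doses))
}

#' Fit the four-parameter Hill concentration-response model
#'
#' Bounded Levenberg-Marquardt least squares of the Hill model on
#' (dose, response) observations. Zero-dose control wells anchor `R0` at
#' dose 0 exactly (no pseudo-log dose). When every dose has at least three
#' replicates, observations are weighted by the inverse per-dose variance.
#' Starting values come from the data: `R0` = smallest per-dose mean,
#' `Rhyp` = span of per-dose means, `EC50` = dose nearest half-span,
#' `n` = 1. Bounds: `Rhyp >= 0`, `n` in (0, 5], `EC50` in [1e-4, 1e3] uM.
#'
#' @param doses doses in micromolar; at least 5 distinct values including 0
#'   (or a near-zero anchor below `EC50`/100 of the dose range).
#' @param responses responses (percent of control by convention, raw indices
#'   work equally).
#' @param weights optional observation weights; default as described.
#' @return object of class `srb_hill` with `coefficients`,
#'   `standard_errors`, `residual_ss`, `converged`, `at_bound`, and the
#'   underlying `nls` fit.
#' @export
fit_dose_response <- function(doses, responses, weights = NULL) {
  stopifnot(length(doses) == length(responses))
  if (length(unique(doses)) < 5)
    stop("insufficient data: need >= 5 distinct doses")
  if (min(doses) > max(doses) * 1e-4)
    stop("insufficient data: need a zero (or near-zero) dose anchor")
  if (is.null(weights)) weights <- replicate_weights(doses, responses)
  dmean <- tapply(responses, doses, mean)
  dlev <- as.numeric(names(dmean))
  r0_start <- max(min(dmean), 1e-9)
  span <- max(max(dmean) - min(dmean), 1e-9)
  half <- min(dmean) + span / 2
  ec_start <- dlev[dlev > 0][which.min(abs(dmean[dlev > 0] - half))]
  if (length(ec_start) == 0 || !is.finite(ec_start)) ec_start <- median(dlev[dlev > 0])
  start <- c(R0 = r0_start, Rhyp = span, n = 1, EC50 = as.numeric(ec_start))
  df <- data.frame(dose = doses, response = responses, w = weights)
  fit <- minpack.lm::nlsLM(
    response ~ R0 + Rhyp * dose^n / (EC50^n + dose^n),
    data = df, start = start, weights = df$w,
    lower = hill_bounds$lower, upper = hill_bounds$upper,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 4), names(cf)))
  at_bound <- names(cf)[cf <= hill_bounds$lower + 1e-10 |
                          cf >= hill_bounds$upper - 1e-10]
  at_bound <- setdiff(at_bound, "Rhyp"[cf[["Rhyp"]] > 1e-10])
  if (length(at_bound))
    warning("fit at parameter bound: ", paste(at_bound, collapse = ", "))
  structure(list(coefficients = cf, standard_errors = se,
                 residual_ss = deviance(fit), converged = fit$convInfo$isConv,
                 at_bound = at_bound, fit = fit, data = df),
            class = "srb_hill")
}

#' @export
coef.srb_hill <- function(object, ...) object$coefficients

#' @export
predict.srb_hill <- function(object, newdata = NULL, ...) {
  dose <- if (is.null(newdata)) object$data$dose else
    if (is.data.frame(newdata)) newdata$dose else newdata
  hill_response(dose, object)
}

#' @export
residuals.srb_hill <- function(object, ...) {
  object$data$response - predict(object)
}

#' @export
print.srb_hill <- function(x, digits = 4, ...) {
  cat("Hill concentration-response fit:\n")
  cat("  response = R0 + Rhyp * d^n / (EC50^n + d^n)\n")
  m <- rbind(estimate = x$coefficients, std.error = x$standard_errors)
  print(round(m, digits))
  cat("  residual SS:", format(x$residual_ss, digits = digits),
      if (!x$converged) " [not converged]" else "", "\n")
  invisible(x)
}

#' @export
summary.srb_hill <- function(object, ...) {
  out <- list(coefficients = object$coefficients,
              standard_errors = object$standard_errors,
              residual_ss = object$residual_ss,
              max_growth_percent = max_growth_percent(object),
              converged = object$converged, at_bound = object$at_bound)
  class(out) <- "summary.srb_hill"
  out
}

#' @export
print.summary.srb_hill <- function(x, digits = 4, ...) {
  m <- rbind(estimate = x$coefficients, std.error = x$standard_errors)
  print(round(m, digits))
  cat("Maximal growth:", format(x$max_growth_percent, digits = digits),
      "% of control\n")
  invisible(x)
}

#' @export
plot.srb_hill <- function(x, n_grid = 200, ...) {
  d <- x$data
  pos <- d$dose[d$dose > 0]
  grid <- c(0, exp(seq(log(min(pos)), log(max(pos)), length.out = n_grid)))
  plot(pmax(d$dose, min(pos) / 3), d$response, log = "x",
       xlab = "dose (uM)", ylab = "response", ...)
  lines(pmax(grid, min(pos) / 3), hill_response(grid, x))
  invisible(x)
}

#' Simulate replicate responses from a Hill model
#'
#' Generates `n_rep` noisy responses per dose with multiplicative Gaussian
#' noise of coefficient of variation `cv`, as used for parameter-recovery
#' studies.
#'
#' @param params named Hill parameters (or `srb_hill` fit).
#' @param doses dose levels (include 0 for the control anchor).
#' @param n_rep replicates per dose.
#' @param cv coefficient of variation of the noise.
#' @param seed integer seed.
#' @return data.frame with `dose` and `response`.
#' @export
simulate_dose_response <- function(params, doses, n_rep = 16, cv = 0.03,
                                   seed = 1L) {
  set.seed(seed)
  d <- rep(doses, each = n_rep)
  mu <- hill_response(d, params)
  data.frame(dose = d, response = mu * (1 + rnorm(length(d), 0, cv)))
}

#' @export
simulate.srb_hill <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  sigma <- sqrt(object$residual_ss / max(1, nobs(object$fit) - 4))
  out <- replicate(nsim, mu + rnorm(length(mu), 0, sigma), simplify = FALSE)
  names(out) <- paste0("sim_", seq_len(nsim))
  as.data.frame(out)
}

#' Maximal growth as percent of control
#'
#' `100 * (R0 + Rhyp) / R0`: the plateau of the Hill model expressed as
#' percent of the untreated baseline.
#'
#' @param fit an `srb_hill` fit or named parameters with positive `R0`.
#' @return percent of control.
#' @examples
#' max_growth_percent(c(R0 = 0.289, Rhyp = 0.223, n = 0.67, EC50 = 0.844))
#' @export
max_growth_percent <- function(fit) {
  p <- if (inherits(fit, "srb_hill")) coef(fit) else fit
  if (!is.finite(p[["R0"]]) || p[["R0"]] <= 0)
    stop("invalid fit: R0 must be positive")
  100 * (p[["R0"]] + p[["Rhyp"]]) / p[["R0"]]
}

#' Fit a one-site inhibition model to a growth screen
#'
#' Fits `growth(I) = floor + (G0 - floor) / (1 + I / Ki)` by least squares:
#' `G0` is the uninhibited growth, `Ki` the inhibition constant (at
#' `I = Ki` the inhibitable component is halved) and `floor` the residual
#' growth at full inhibition. The floor can be fixed (e.g. at the control
#' level) via `fix_floor`.
#'
#' @param inhibitor_doses inhibitor concentrations (uM), >= 4 distinct
#'   values including 0.
#' @param growth_responses growth readouts (index or percent of control).
#' @param fix_floor optional fixed floor value.
#' @return object of class `srb_inhibition` with `coefficients` (`Ki`, `G0`,
#'   `floor`), `standard_errors`, `converged`, and the underlying fit.
#' @export
fit_inhibition <- function(inhibitor_doses, growth_responses, fix_floor = NULL) {
  stopifnot(length(inhibitor_doses) == length(growth_responses))
  if (length(unique(inhibitor_doses)) < 4)
    stop("insufficient data: need >= 4 distinct inhibitor doses")
  if (min(inhibitor_doses) != 0)
    stop("insufficient data: need an uninhibited (dose 0) anchor")
  dmean <- tapply(growth_responses, inhibitor_doses, mean)
  dlev <- as.numeric(names(dmean))
  g0_start <- dmean[[which.min(dlev)]]
  floor_start <- min(dmean)
  half <- floor_start + (g0_start - floor_start) / 2
  ki_start <- dlev[dlev > 0][which.min(abs(dmean[dlev > 0] - half))]
  if (!is.finite(ki_start)) ki_start <- median(dlev[dlev > 0])
  df <- data.frame(I = inhibitor_doses, g = growth_responses)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15)
  # fitted with nls.lm directly: an exact (noiseless) fit makes the nls-object
  # construction in nlsLM fail on a singular gradient
  model_fun <- function(p, I) {
    fl <- if (is.null(fix_floor)) p[["floor"]] else fix_floor
    fl + (p[["G0"]] - fl) / (1 + I / p[["Ki"]])
  }
  start <- c(Ki = as.numeric(ki_start), G0 = g0_start)
  lower <- c(Ki = 1e-4, G0 = -Inf)
  upper <- c(Ki = 1e4, G0 = Inf)
  if (is.null(fix_floor)) {
    start <- c(start, floor = floor_start * 0.9)
    lower <- c(lower, floor = -Inf)
    upper <- c(upper, floor = Inf)
  }
  out <- minpack.lm::nls.lm(par = start,
                            fn = function(p) df$g - model_fun(p, df$I),
                            lower = lower, upper = upper, control = ctrl)
  cf <- out$par
  if (!is.null(fix_floor)) cf <- c(cf, floor = fix_floor)
  n_par <- length(out$par)
  sigma2 <- out$deviance / max(1, nrow(df) - n_par)
  se <- tryCatch(sqrt(diag(solve(out$hessian)) * sigma2),
                 error = function(e) setNames(rep(NA_real_, n_par),
                                              names(out$par)))
  converged <- out$info %in% 1:3
  if (!converged) warning("inhibition fit did not converge; best iterate returned")
  structure(list(coefficients = cf, standard_errors = se,
                 converged = converged, model = "one-site hyperbolic inhibition",
                 floor_fixed = !is.null(fix_floor), fit = out, data = df),
            class = "srb_inhibition")
}

#' @export
coef.srb_inhibition <- function(object, ...) object$coefficients

#' @export
predict.srb_inhibition <- function(object, newdata = NULL, ...) {
  I <- if (is.null(newdata)) object$data$I else
    if (is.data.frame(newdata)) newdata$I else newdata
  p <- object$coefficients
  p[["floor"]] + (p[["G0"]] - p[["floor"]]) / (1 + I / p[["Ki"]])
}

#' @export
print.srb_inhibition <- function(x, digits = 4, ...) {
  cat("One-site inhibition fit: growth = floor + (G0 - floor)/(1 + I/Ki)\n")
  print(round(x$coefficients, digits))
  cat("  Ki =", format(x$coefficients[["Ki"]], digits = digits), "uM",
      if (!x$converged) " [not converged]" else "", "\n")
  invisible(x)
}

#' Detect the onset of hypertrophic growth in a time course
#'
#' At each timepoint a two-sided t-test compares treated against control
#' replicates; p-values are Bonferroni-corrected across timepoints. The
#' onset is the earliest significant timepoint from which all later
#' timepoints are also significant, and the growth slope is the least-squares
#' slope of the treated values over timepoints at or after onset.
#'
#' @param timepoints numeric vector of timepoints (hours).
#' @param treated,control lists of numeric replicate vectors, one element
#'   per timepoint.
#' @param alpha significance level after correction.
#' @return object of class `srb_onset`: `onset_time` (`NA` if none),
#'   `slope` (index/hour, `NA` if no onset), `p_values`, `p_adjusted`,
#'   `significant`.
#' @export
detect_growth_onset <- function(timepoints, treated, control, alpha = 0.05) {
  stopifnot(length(timepoints) >= 3, length(treated) == length(timepoints),
            length(control) == length(timepoints))
  ord <- order(timepoints)
  timepoints <- timepoints[ord]
  treated <- treated[ord]
  control <- control[ord]
  p <- mapply(function(tr, ct) t.test(tr, ct)$p.value, treated, control)
  p_adj <- adjust_bonferroni(p)
  sig <- p_adj < alpha
  onset <- NA_real_
  # earliest timepoint significant with all later ones also significant
  run <- rev(cumprod(rev(sig))) == 1
  if (any(run)) onset <- timepoints[which(run)[1]]
  slope <- NA_real_
  if (!is.na(onset)) {
    keep <- timepoints >= onset
    tt <- rep(timepoints[keep], lengths(treated[keep]))
    vv <- unlist(treated[keep])
    if (length(unique(tt)) >= 2) slope <- unname(coef(lm(vv ~ tt))[2])
  }
  structure(list(onset_time = onset, slope = slope, p_values = p,
                 p_adjusted = p_adj, significant = sig,
                 timepoints = timepoints),
            class = "srb_onset")
}

#' @export
print.srb_onset <- function(x, ...) {
  if (is.na(x$onset_time)) {
    cat("No significant growth onset detected\n")
  } else {
    cat("Growth onset at", x$onset_time, "h; slope",
        format(x$slope, digits = 4), "per hour\n")
  }
  invisible(x)
}

#' Fit an exponential decay of growth index with cell density
#'
#' Fits `index = A * exp(-k * density)` by least squares with `k >= 0`
#' enforced; an increasing trend clamps `k` at 0 with a warning.
#'
#' @param densities particle counts per field, >= 4 distinct levels.
#' @param indices ratiometric indices.
#' @return object of class `srb_density`: coefficients `A`, `k`.
#' @export
fit_density_decay <- function(densities, indices) {
  stopifnot(length(densities) == length(indices))
  if (length(unique(densities)) < 4)
    stop("insufficient data: need >= 4 density levels")
  pos <- indices > 0
  k_start <- if (sum(pos) >= 2) {
    sl <- -coef(lm(log(indices[pos]) ~ densities[pos]))[2]
    max(unname(sl), 0)
  } else 0
  df <- data.frame(den = densities, idx = indices)
  fit <- minpack.lm::nlsLM(idx ~ A * exp(-k * den), data = df,
                           start = c(A = max(indices), k = max(k_start, 1e-6)),
                           lower = c(A = 0, k = 0),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 500, ftol = 1e-15, ptol = 1e-15))
  cf <- coef(fit)
  rho <- suppressWarnings(stats::cor(densities, indices))
  if (cf[["k"]] <= 1e-12 && is.finite(rho) && rho > 0.1)
    warning("increasing index-density trend: k clamped at 0")
  structure(list(coefficients = cf,
                 standard_errors = tryCatch(
                   summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) c(A = NA_real_, k = NA_real_)),
                 fit = fit, data = df),
            class = "srb_density")
}

#' @export
coef.srb_density <- function(object, ...) object$coefficients

#' @export
predict.srb_density <- function(object, newdata = NULL, ...) {
  den <- if (is.null(newdata)) object$data$den else
    if (is.data.frame(newdata)) newdata$den else newdata
  object$coefficients[["A"]] * exp(-object$coefficients[["k"]] * den)
}

#' @export
print.srb_density <- function(x, digits = 4, ...) {
  cat("Exponential density decay: index = A * exp(-k * density)\n")
  print(signif(x$coefficients, digits))
  invisible(x)
}
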