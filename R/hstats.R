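#' Bonferroni adjustment of p-values
#'
#' `p_adj = min(1, m * p)` with `m` the number of tests.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
adjust_bonferroni <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("invalid input: p-values must lie in [0, 1]")
  p.adjust(p_values, method = "bonferroni")
}

#' One-way random-effects variance components and intraclass correlation
#'
#' Estimates between-cluster (biological isolation) and within-cluster
#' (technical repeat) variance by expected mean squares from a one-way
#' random-effects layout; a negative between-cluster estimate is truncated
#' at zero. The intraclass correlation ICC =
#' sigma2_between / (sigma2_between + sigma2_within) measures how strongly
#' technical repeats cluster within isolations, and hence the
#' pseudo-replication risk of treating wells as independent.
#'
#' @param values numeric readouts (e.g. well indices).
#' @param cluster cluster (isolation) identifier per value.
#' @return list with `sigma2_between`, `sigma2_within`, `icc`.
#' @export
variance_components_icc <- function(values, cluster) {
  cluster <- factor(cluster)
  if (nlevels(cluster) < 2)
    stop("insufficient clusters: need >= 2 isolations")
  ni <- as.numeric(table(cluster))
  if (max(ni) < 2)
    stop("insufficient data: need >= 2 values in some cluster")
  N <- length(values)
  k <- nlevels(cluster)
  fit <- suppressWarnings(anova(lm(values ~ cluster)))
  msb <- fit[["Mean Sq"]][1]
  msw <- fit[["Mean Sq"]][2]
  if (!is.finite(msw)) msw <- 0
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  s2b <- max((msb - msw) / n0, 0)
  icc <- if (s2b + msw > 0) s2b / (s2b + msw) else 0
  list(sigma2_between = s2b, sigma2_within = msw, icc = icc)
}

#' Hierarchical (cluster-mean) one-way ANOVA
#'
#' Tests a condition effect on readouts with technical repeats nested in
#' biological isolations. Technical repeats are first averaged within each
#' cluster (unweighted: each isolation counts once), then a one-way ANOVA is
#' run across conditions on the cluster means. This two-stage analysis keeps
#' the type-I error at its nominal level when repeats cluster within
#' isolations, where a naive well-level ANOVA is anticonservative. Variance
#' components and ICC are reported from the condition-centered data.
#'
#' @param values numeric readouts per well.
#' @param cluster isolation identifier per value; each cluster must belong
#'   to a single condition.
#' @param condition condition label per value.
#' @return object of class `srb_hanova`: `F`, `p`, `df` (numerator,
#'   denominator), `sigma2_between`, `sigma2_within`, `icc`,
#'   `cluster_means`, `n_wells`, `n_isolations`.
#' @export
hierarchical_anova <- function(values, cluster, condition) {
  condition <- factor(condition)
  cluster <- factor(cluster)
  if (nlevels(condition) < 2)
    stop("invalid input: need >= 2 conditions")
  cc <- unique(data.frame(cluster = cluster, condition = condition))
  if (anyDuplicated(cc$cluster))
    stop("invalid input: each cluster must belong to exactly one condition")
  per_cond <- table(cc$condition)
  if (any(per_cond < 2))
    stop("insufficient clusters: every condition needs >= 2 isolations (",
         paste(names(per_cond)[per_cond < 2], collapse = ", "), ")")
  cm <- tapply(values, cluster, mean)
  cm_cond <- cc$condition[match(names(cm), cc$cluster)]
  fit <- suppressWarnings(anova(lm(cm ~ cm_cond)))
  # an exactly balanced layout can make both sums of squares vanish; report
  # F = 0, p = 1 rather than the 0/0 artifact
  if (fit[["Sum Sq"]][1] < 1e-18 * max(1, mean(cm)^2)) {
    fit[["F value"]][1] <- 0
    fit[["Pr(>F)"]][1] <- 1
  }
  # variance components on condition-centered well values
  centered <- values - tapply(values, condition, mean)[condition]
  vc <- variance_components_icc(centered, cluster)
  structure(list(F = fit[["F value"]][1], p = fit[["Pr(>F)"]][1],
                 df = c(fit[["Df"]][1], fit[["Df"]][2]),
                 sigma2_between = vc$sigma2_between,
                 sigma2_within = vc$sigma2_within, icc = vc$icc,
                 cluster_means = data.frame(cluster = names(cm),
                                            condition = as.character(cm_cond),
                                            mean = as.numeric(cm)),
                 n_wells = length(values), n_isolations = nlevels(cluster)),
            class = "srb_hanova")
}

#' @export
print.srb_hanova <- function(x, digits = 4, ...) {
  cat("Hierarchical (cluster-mean) one-way ANOVA\n")
  cat(sprintf("  F(%d, %d) = %s, p = %s\n", x$df[1], x$df[2],
              format(x$F, digits = digits), format.pval(x$p, digits = digits)))
  cat(sprintf("  ICC = %.3f (between %.4g, within %.4g); %d wells, %d isolations\n",
              x$icc, x$sigma2_between, x$sigma2_within, x$n_wells,
              x$n_isolations))
  invisible(x)
}

#' Naive well-level one-way ANOVA (for comparison)
#'
#' Treats every well as independent, ignoring isolation clustering. Exposed
#' so the pseudo-replication inflation of the type-I error can be
#' demonstrated against [hierarchical_anova()].
#'
#' @param values,condition as in [hierarchical_anova()].
#' @return list with `F`, `p`, `df`.
#' @export
naive_anova <- function(values, condition) {
  condition <- factor(condition)
  fit <- anova(lm(values ~ condition))
  list(F = fit[["F value"]][1], p = fit[["Pr(>F)"]][1],
       df = c(fit[["Df"]][1], fit[["Df"]][2]))
}

#' Design-effect-corrected well-level ANOVA
#'
#' Variant of the hierarchical analysis that keeps well-level resolution but
#' deflates the effective sample size by the design effect
#' `1 + (m_bar - 1) * ICC` (`m_bar` = mean wells per isolation): the F
#' denominator degrees of freedom and statistic are rescaled accordingly.
#' Provided as the flag-selectable alternative to the cluster-mean test.
#'
#' @param values,cluster,condition as in [hierarchical_anova()].
#' @return list with `F`, `p`, `df`, `design_effect`, `icc`.
#' @export
design_effect_anova <- function(values, cluster, condition) {
  condition <- factor(condition)
  cluster <- factor(cluster)
  centered <- values - tapply(values, condition, mean)[condition]
  vc <- variance_components_icc(centered, cluster)
  m_bar <- length(values) / nlevels(cluster)
  deff <- 1 + (m_bar - 1) * vc$icc
  fit <- anova(lm(values ~ condition))
  F_adj <- fit[["F value"]][1] / deff
  df2 <- max(1, floor(fit[["Df"]][2] / deff))
  list(F = F_adj, p = pf(F_adj, fit[["Df"]][1], df2, lower.tail = FALSE),
       df = c(fit[["Df"]][1], df2), design_effect = deff, icc = vc$icc)
}
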