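---
title: "Quantifying cardiomyocyte hypertrophy with the ratiometric SRB index"
author: "srbratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cardiomyocyte hypertrophy with the ratiometric SRB index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srbratio)
```

## The measurement problem

Hypertrophy — growth of a cell's protein mass without division — is the
cardinal in-vitro phenotype of stressed cardiac myocytes. Sulforhodamine B
(SRB) binds cellular protein stoichiometrically, so SRB fluorescence imaged
in situ is a linear proxy for biomass. The difficulty is that raw
fluorescence also scales with laser power, exposure, light path and cell
number, none of which is biology. This package implements a ratiometric
analysis of paired Hoechst (nuclear) and SRB (protein) images of neonatal
rat ventricular myocyte (NRVM) monolayers that cancels those factors:

$$
\mathrm{index} \;=\; \frac{\mathrm{eSRB}}
{\overline{\mathrm{nSRB}} \times N_\mathrm{cells}}
$$

where eSRB is the background-corrected SRB signal summed over all
*extra-nuclear* pixels of the field (cytoplasm plus background areas — no
cytoplasm segmentation is attempted), $\overline{\mathrm{nSRB}}$ is the
mean over nuclear particles of each particle's mean SRB, and
$N_\mathrm{cells}$ is the cell count derived from nuclear morphometry.
Because any multiplicative gain applied to the image scales numerator and
denominator equally, the index is invariant to acquisition settings; under
control conditions it sits around $0.3 \times 10^3$.

## Pipeline

1. **Segmentation.** The Hoechst image is background-corrected and
   thresholded with the Ridler–Calvard (isodata/intermeans) iteration
   $T_{k+1} = \tfrac12(\mu_{\le T_k} + \mu_{> T_k})$, started from the
   global mean (tolerance 0.5 intensity units, at most 100 iterations).
   Connected components are labelled with 8-connectivity and components
   below `min_area` (default 20 µm²) are discarded as debris. Touching
   nuclei are *deliberately not split*: a binucleate myocyte appears as one
   elongated particle, and that elongation is the classification signal.
   Border particles are retained by default (plate-reader fields are large;
   excluding them would bias density estimates).

2. **Morphometry and cell-type census.** Each particle's long and short
   axes are those of the ellipse with the same normalized second central
   moments (pixels treated as unit squares, so a 40×10 px rectangle gives a
   circularity ratio of exactly 4). Fibroblast nuclei are larger than
   myocyte nuclei, so a two-component Gaussian mixture on log(area) yields
   an area cutoff at the equal-posterior point; particles above the cutoff
   are split into fibroblasts (circularity ≈ 1) and binucleate myocytes
   (circularity ≫ 1) by a second two-component mixture on log(circularity).
   Each particle counts as one cell — a binucleate particle is a single
   myocyte. Fibroblasts are included in $N_\mathrm{cells}$ by default (no
   further correction factors); a flag restricts counting to myocytes.

3. **Ratiometry.** The SRB channel is background-corrected independently,
   partitioned by the nuclear mask, and the index computed per well.
   Treated wells are normalized to time-matched control wells *within each
   isolation*, then summarized across isolations.

4. **Pharmacology.** Percent-of-control responses feed a four-parameter
   Hill model $R_0 + R_\mathrm{hyp}\,d^{\,n}/(EC_{50}^{\,n} + d^{\,n})$
   (bounded Levenberg–Marquardt; zero-dose controls anchor $R_0$ at dose 0;
   inverse-variance weights per dose when ≥ 3 replicates), a one-site
   inhibition model $\mathrm{floor} + (G_0-\mathrm{floor})/(1 + I/K_i)$ for
   anti-hypertrophic screens, per-timepoint Bonferroni-corrected t-tests
   for growth-onset detection, and an exponential decay
   $A e^{-k\,\mathrm{density}}$ for the density dependence of growth.

5. **Hierarchical statistics.** Wells are technical repeats nested in
   biological isolations and cluster strongly within isolation (high
   intraclass correlation). Condition effects are therefore tested on
   isolation means (two-stage, cluster-mean ANOVA), which holds the type-I
   error at its nominal level where a naive well-level ANOVA is badly
   anticonservative; a design-effect-corrected well-level variant is
   available behind a flag. Variance components come from one-way
   random-effects expected mean squares with negative between-isolation
   estimates truncated at zero, giving
   $\mathrm{ICC} = \sigma^2_b/(\sigma^2_b + \sigma^2_w) \in [0, 1]$.

## Numerical choices worth knowing about

**Background estimation.** Cells are sparse relative to background, so the
background is the modal intensity of the image. The mode is located with
the *half-sample* method — recursively narrowing to the half of the sorted
intensities with the smallest range, breaking ties at the middle window —
rather than a fixed-bin histogram. The reason is exactness of the gain
invariance: a bin of fixed width is not equivariant under multiplicative
rescaling, and because eSRB sums over a few hundred thousand pixels, a
background error of one intensity unit moves eSRB by several percent. The
half-sample mode satisfies $\hat b(k\,x) = k\,\hat b(x)$ exactly, so the
index is bit-for-bit gain-invariant on noiseless rescalings and changes by
far less than 1% through the full simulated acquisition chain at 10× laser
power.

**Mixture fitting.** Both mixtures use a hand-written, fully deterministic
EM (median-split initialization, at most 500 iterations, tolerance $10^{-8}$
on the log-likelihood, component order fixed by mean). The log-likelihood
trace is stored; it is non-decreasing, and the tests assert this on every
fit. The area-cutoff fit is declared degenerate — triggering a fixed
fallback cutoff, by default twice the median particle area — when the
component means are closer than 0.5 pooled SD *or* when BIC prefers a
single Gaussian; the second trigger matters because EM happily splits a
unimodal sample into two overlapping components that pass the
mean-separation test. Classification ties at posterior 0.5 go to
fibroblast. Models are fitted per plate on pooled control wells and applied
plate-wide by default (per-well fitting via flag), which stabilizes the
cutoff in sparse wells.

**Curve fitting.** Hill bounds are $R_0 > 0$, $R_\mathrm{hyp} \ge 0$,
$n \in (0, 5]$, $EC_{50} \in [10^{-4}, 10^{3}]$ µM, with starts taken from
the data (minimum, span, dose nearest half-span, $n = 1$); noiseless
self-generated data are recovered to better than six significant digits. A
fit that ends on a bound is flagged. The inhibition model is fitted with
`nls.lm` directly because constructing a full `nls` object fails on
exactly-fitting (noiseless) data; the functional form of the inhibition
curve is not dictated by the assay, so the one-site hyperbola with an
optional floor is recorded in the fit object. Whether inhibition drives
growth fully back to control is left to the data: the floor is free by
default and can be fixed via `fix_floor`.

**Onset detection.** The onset is the earliest timepoint that is
significant *and* followed only by significant timepoints, which guards
against isolated false positives at early times; on flat null series the
onset rate stays at or below the Bonferroni-controlled level.

## The synthetic-data generator

No imaging data are deposited with the assay, so every pipeline stage is
validated against a generator with known ground truth
(`synthetic_spec()`, `generate_particle_table()`,
`generate_field_images()`, `generate_plate_dataset()`). Its defaults
emulate a control NRVM culture on a low-magnification plate reader:

* ~2500 nuclear particles per 2×2 mm field (1600² px at 1.25 µm/px), cell
  types at 77/16/7% (mononucleated myocytes / binucleated myocytes /
  fibroblasts);
* log-normal nuclear areas with medians 45 µm² (mononucleate) and 120 µm²
  (fibroblast), log-SD 0.12 — the particle-table generator uses median
  90 µm² for binucleate particles (two fused mononucleate nuclei), while
  the image renderer builds binucleates as two overlapping ellipses so the
  elongation emerges from the geometry;
* log-normal circularity ratios with medians 1.08 / 2.2 / 1.10, truncated
  at 1;
* size-independent nuclear SRB (200 intensity units) and per-cell
  cytoplasmic Gaussian halos (σ = 10 µm) whose integrated intensity equals
  the per-cell biomass (6×10⁴ intensity·px, log-SD 0.2), deposited on
  extra-nuclear pixels only so nuclear SRB is independent of biomass by
  construction; halos of neighbouring cells add;
* per-channel additive background (100 / 40), Gaussian noise (SD 5),
  then a multiplicative gain on both channels with saturation clipping at
  the bit-depth maximum — so invariance breakdown under saturation can be
  probed;
* per-cell biomass shrinking with seeding density at fixed growth area
  (`exp(-2.3e-4 × (n − 2500))`), reproducing the greater-than-2-fold index
  span between 1000 and 4500 particles per field;
* isolation-level log-normal random effects with variance set by a target
  ICC, and dose effects routed through a Hill model on the hypertrophy
  factor.

Channel intensities are kept continuous; quantization happens only when
fields are written as 16-bit TIFFs. The generator computes its own analytic
expected index from the noise-free render and true labels; the pipeline
reproduces it within 2% on clean renders (discretization only) and within
~10% under realistic background and noise, the residual bias coming from
halo tails entering the background estimate — the same effect out-of-focus
light has on real images.

What the generator does *not* emulate: optics (no PSF, no illumination
gradient), 3-D structure, fibroblast proliferation, cell motion, and
staining chemistry. Passing tests therefore demonstrate correctness of the
computation and its invariances, not robustness to every artifact of real
microscopy.

## Study-scale choices in the tests and acceptance script

Parameter-recovery simulations follow the published designs: dose-response
recovery uses 8 log-spaced doses (0.01–30 µM) plus a zero-dose control with
16 replicates per dose and 3% CV noise; the inhibition screen uses doses
0/1/3/10/30 µM with 25 wells per dose and 5% CV. The classifier-recovery
simulation pools 300 control wells (~600 particles each) with per-well
cell-type fractions drawn from a Dirichlet centred on 77/16/7%
(concentration 12, matching the reported ±12-point well-to-well SD of the
mononucleate fraction). Rendered-image tests use ~200-cell fields at 640²
px, with the density series at full scale (1000–4500 particles on 1600²
px). With the shallow 24-h cooperativity ($n = 0.5$) the EC50 estimator has
a median sampling error around 15% under the 16-replicate design, so the
test suite asserts the median recovery error across five independent
simulations rather than a single draw.

## Known limitations

* Closely adjacent but non-touching nuclei are not merged, so binucleate
  myocytes whose nuclei do not touch are counted as two mononucleated
  cells — a possible undercount the census inherits from connected-component
  labelling.
* eSRB underestimates biomass by the cytoplasm directly above and below
  nuclei (< 5%); no correction is applied.
* The area cutoff and circularity mixture assume bimodality; cultures with
  atypical fibroblast content may trigger the degenerate fallback.
* The hierarchical ANOVA is the two-stage cluster-mean estimator with
  unweighted cluster means; strongly unbalanced designs may prefer a mixed
  model, which is outside this package's scope.
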