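---
title: "Methods: drug sensitivity scoring and morphological profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drug sensitivity scoring and morphological profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsrtkit)
```

This vignette is the package's account of its science: the models it fits,
the conventions it adopts where the field leaves choices open, and what the
bundled simulators do and do not establish about real data.

## The screening model

A DSRT screen measures ATP-proxy luminescence in 384-well plates, one tumor
or healthy-control model per plate, each compound in an ascending
concentration series (five 10-fold dilutions by default), with DMSO wells as
the negative and a benzethonium-chloride-style kill control as the positive
anchor.

**Normalization.** Percent inhibition is anchored per plate to that plate's
own controls,

$$PI(w) = 100\,\frac{\mu_{neg} - S_w}{\mu_{neg} - \mu_{pos}},$$

so DMSO-level signal maps to 0 and the kill level to 100. Plates are the
batch unit: controls are never pooled across plates, which keeps the
normalization immune to plate-to-plate gain differences (and makes $PI$
invariant to rescaling all signals of a plate by any $k>0$). $PI$ is not
clamped; out-of-range values are handled by the fit constraints.
Replicates at a dose are averaged on the $PI$ scale, not on raw signal, so
each well is normalized against its own plate before pooling.

**Dose-response.** Each compound–model series is fit with a four-parameter
logistic on the $\log_{10}$ molar axis,

$$y(x) = d + \frac{a-d}{1+10^{\,b(c-x)}},$$

with bottom $d$ fixed at 0 (an inhibition scale starts at no effect; the
bottom is configurable for diagnostics), $0 \le a \le 100$,
$0 < b \le 10$, and $c$ restricted to the tested range widened by one log
unit per side. The least-squares problem is non-convex, so the fit is
multi-start: slopes $b_0 \in \{0.5, 1, 2, 5\}$ crossed with $c_0$ at the
midpoints of the dose grid, each refined by bounded Levenberg–Marquardt to
tight tolerances; the lowest residual sum of squares wins and exact ties go
to the smaller slope (the smoother curve). A series whose observed $PI$
range is below 10 percentage points is flagged *unidentifiable*: a flat
response constrains neither $b$ nor $c$, and the 10-point rule deliberately
equals the DSS activity threshold so that "no scoreable activity" and "no
trustworthy potency" coincide. If every start fails (not observed in
practice), the fallback is a flat curve at the mean response with
`converged = FALSE`.

**Potency.** The relative EC50 is $10^c$; the absolute IC50 solves
$y(x) = 50$, i.e. $10^{\,c - (1/b)\log_{10}(a/50-1)}$, and is reported as
not reached when $a \le 50$.

**DSS.** The drug sensitivity score integrates the fitted curve above an
activity threshold $t$ (default 10%) over the tested window
$[x_{min}, x_{max}]$. With $d=0$ the antiderivative of $y$ is
$\tfrac{a}{b}\log_{10}(1+10^{b(x-c)})$, giving the closed form

$$I = \frac{a}{b}\left[\log_{10}\!\big(1+10^{b(x_{max}-c)}\big) -
      \log_{10}\!\big(1+10^{b(x_1-c)}\big)\right] - t\,(x_{max}-x_1),$$

where $x_1$ is the larger of $x_{min}$ and the threshold crossing
$x_t = c - \tfrac1b\log_{10}(a/t-1)$; only the region with $y \ge t$
contributes. DSS1 normalizes $I$ by the maximal area
$(100-t)(x_{max}-x_{min})$ and scales to 0–100; DSS2 (the default) divides
DSS1 by $\log_{10} a$, which penalizes low-ceiling partial responses and
keeps scores on the ~0–50 scale on which the conventional DSS ≥ 10
effectiveness cutoff operates. Curves with $a \le t$ score 0, and under
DSS2 tops at or below 1.01 score 0 (the $\log_{10} a \le 0$ region is
meaningless and always below threshold anyway). A trapezoid-rule oracle
(`dss_numeric`) computes the same quantity by quadrature on
$\max(y-t,0)$; the two routes agree to $10^{-6}$ and the oracle exists
precisely so that the closed form never has to be trusted on faith.

**sDSS and hit calling.** The selective score is
$sDSS = DSS_{tumor} - DSS_{control}$, computed only between scores sharing
one configuration (window, threshold, variant); mixed-window subtraction is
an error rather than a silent harmonization. Thresholds are inclusive —
DSS ≥ 10 effective, sDSS ≥ 10 selective — and negative sDSS is preserved as
a signal of control-toxic compounds. Compounds strongly inhibiting the
healthy control already below the top concentration get a *low-dose
toxicity* flag (default: control $PI \ge 50\%$ at any tested dose strictly
below the top dose). The flag is reported, never used for silent removal,
since such compounds can still clear the sDSS cutoff; the numeric rule is a
declared operationalization of a qualitative exclusion practice, exposed as
configuration. Summaries give per-model counts, the union and intersection
of selective sets across models, and top-N rankings by sDSS with
lexicographic tie-breaks for determinism.

**Plate QC.** Z-prime per plate,
$Z' = 1 - 3(\sigma_{pos}+\sigma_{neg})/|\mu_{pos}-\mu_{neg}|$ with sample
SDs; $Z' > 0.5$ is the usual excellent-assay bar, and simulated plates at
the default 5% signal CV sit near 0.8.

## The screen simulator

The generator plants a true 4PL curve per compound and model and renders
raw luminescence from it. Its defaults define the study conditions the
tests exercise:

* library laid out columnwise, 5-dose series, 10-fold dilution from
  10 µM, 60 compounds per plate; 32 DMSO and 32 positive wells per plate in
  the fixed outer-adjacent columns (real layouts are vendor-specific and
  unpublished; this is a convention, not a reconstruction);
* 40% of compounds active ($a \sim U(30,100)$, $b \sim U(0.7,2.5)$, $c$
  uniform in the interior of the tested window), half of the actives
  inactive in the healthy-control model (selective);
* multiplicative lognormal noise with CV 5% — luminescence is positive and
  right-skewed, so a multiplicative model is the natural choice; an optional
  linear row/column drift exists to stress QC and is off by default;
* expected well signal interpolates the control anchors,
  $S = floor + (baseline - floor)\,(1 - PI_{true}/100)$, so the plate's own
  normalization recovers the planted inhibition exactly at zero noise — the
  property the round-trip tests rely on;
* one "combination" library entry is modeled as an ordinary compound with
  its own id;
* all randomness flows from one seed, and the caller's RNG state is
  restored afterwards.

`make_fixture_screen()` is the deterministic 24-compound, 2-tumor-model
fixture with hand-planted groups (8 selective in both tumors, 4 and 2
selective in one tumor each, 2 effective-but-unselective, 2 strongly active
with low-dose control toxicity, 6 inactive). Its documented hit sets are
derived from the planted curves via the closed-form scores at the standard
thresholds — not from the construction labels — because the
effective-but-unselective construction is itself necessarily low-dose-toxic
under the default rule (a control DSS ≥ 10 requires ≥ 50% control
inhibition below the top dose), and the truth-derived sets are what the
pipeline should recover.

## The imaging pipeline

**Thresholding.** Binarization uses the minimum-cross-entropy criterion
(Li's family),
$CE(T) = \sum_{g<T} g\,h(g)\log\frac{g}{\mu_b} + \sum_{g\ge T} g\,h(g)\log\frac{g}{\mu_f}$,
minimized by exhaustive search over the observed gray levels (vectorized
cumulative sums; ties to the smallest threshold). Exhaustive search, rather
than the usual fixed-point iteration, guarantees the global minimum and
makes the operator trivially checkable against a naive re-implementation.

**Nuclei.** MCE binary → Euclidean distance transform → local maxima as
watershed markers (plateau components, greedily accepted in decreasing peak
height with a minimum separation, default 20 px) → marker-based watershed
on the negated distance map restricted to the foreground (a priority-flood
implementation in C++ with FIFO tie-breaking for determinism) → masking
with the binary → discarding objects with equivalent circular diameter
$\sqrt{4A/\pi}$ outside 40–240 px. "Diameter" is not defined by the
upstream convention this mirrors, so the equivalent-diameter reading is
declared and configurable. Surviving labels are compacted.

**Cells.** Seeded propagation from the nuclei into the MCE-thresholded ER
channel (the propagate-style seeded region growing of the CellProfiler
family, via `EBImage::propagate`; regularization $\lambda = 0.05$ by
default). The propagation mask is the union of ER foreground and nuclei, so
every nucleus belongs to its own cell and a nucleus outside the ER
foreground degenerates to a cell equal to itself. On uniform-intensity
foreground the partition reduces to the geodesic equal-distance midline,
which is what the oracle test checks.

**Features.** 306 named features per cell over three compartments (nucleus,
cell, cytoplasm = cell ∖ nucleus) and four channels: 13 intensity
statistics (mean, SD, MAD, min, max, integrated, quantiles
5/10/25/50/75/90/95) per channel × compartment; gray-level co-occurrence
texture (contrast, correlation, energy, homogeneity, entropy) at offsets 1
and 5 px, direction-averaged over four orientations on 16 requantized
levels per compartment's own intensity range (requantization makes texture
deterministic and scale-free; constant regions score 0); 10 shape
descriptors per compartment (area, perimeter as 4-neighbor boundary edge
count, equivalent diameter, eccentricity and axis lengths from second
central moments with the 1/12 pixel-variance correction, solidity against
the discrete convex hull, extent, form factor $4\pi A/P^2$, connected
component count). An empty cytoplasm yields zeros plus a
`cytoplasm_empty` flag rather than missing values. The catalog is a
documented superset-style stand-in for the unpublished feature list of the
original tooling: the count and the intensity/texture/shape composition are
matched, the exact names are not reconstructable.

**Profiling.** Features are z-scored per plate against that plate's DMSO
cells only; features constant in the controls are zeroed and flagged.
Embedding is UMAP (via uwot) wrapped for determinism — single-threaded
optimization under a caller seed — because the embedding is a pluggable
visualization stage whose internals this package deliberately does not own.
Treatment-level profiles are group means of normalized features, clustered
with Euclidean distance and average linkage (the linkage is unstated in the
practice this mirrors; average linkage is the declared choice), with
lexicographic group order for reproducible dendrograms.

## The image simulator

Fields are 2-D (matching maximum-projection-style analysis planes; optical
stacks would be reduced by maximum-intensity projection before analysis),
with elliptical cells placed by rejection sampling so cell bodies never
touch, nucleus equivalent diameters drawn from 50–150 px by default, and a
bounded-retry placement error when the field is overfull. The fragmented
(mitotic-catastrophe-like) phenotype replaces the nucleus with 3–8
non-touching fragments inside the nuclear footprint. Channels render flat
nuclei, textured cell bodies, a bright AGP membrane rim, and punctate
mitochondria; degradation is Gaussian blur (PSF proxy, σ = 1.5 px), Poisson
shot noise and Gaussian read noise. Truth masks are pre-blur, pre-noise
labels with identical label sets for nuclei and cells.

What the simulator does *not* emulate: realistic optics, illumination
gradients, spheroid 3-D structure, debris, staining variability, or
cell-cell contact. Passing segmentation and profiling tests on these fields
therefore demonstrates algorithmic correctness against known truth, not
performance on real micrographs.

## Endpoint formulas

Tumor volume $TV = L\,W^2/2$ from caliper length/width (swapped with a
warning if given in the wrong order); treated/control ratio of group mean
volumes per timepoint; relative expression by $2^{-\Delta\Delta Ct}$ with
the reference taken as the arithmetic mean of the reference-gene Cts —
equivalent, on the log scale, to the geometric mean of their linear
quantities, which is the standard multi-reference normalization; two-sided
equal-variance Student's t-test by default (whether real analyses assume
equal variances is usually unstated; Welch is available behind a flag);
relative viability/caspase readouts as treated/control mean fractions with
the complementary percent decrease.

## Numerical choices and degenerate inputs

* Fit tolerances: Levenberg–Marquardt `ftol`/`ptol` $10^{-14}$, ≤ 200
  iterations per start; zero-noise 5-point series recover parameters to
  $10^{-4}$ or better.
* DSS closed form vs quadrature: agreement to $10^{-6}$ relative at a
  $10^5$-point grid.
* Degenerate plates (equal control means), constant images, series with
  fewer than two distinct doses, plates without DMSO cells, and empty
  foregrounds all have defined behavior (errors naming the offender, or
  documented empty results) rather than NaN propagation.
* Determinism: all simulator and embedding randomness flows from explicit
  seeds; watershed and ranking ties are broken by fixed rules (FIFO,
  lexicographic ids, smaller slope).

## Problem sizes used by the tests

The suite and the acceptance script run at desk scale: 1,000 random curves
for oracle equivalence, 200-compound single-model and 100-compound
three-model screens at 5% CV for recovery and hit-calling checks, a
900×900 px 20-nucleus field for segmentation, and four 650×650 px
6-cell fields for profiling. These sizes were chosen to exercise every code
path with comfortable statistical margins; the algorithms have no inherent
scale limits beyond memory.

## Known limitations

* The DSS variant used by any particular upstream analytics deployment is
  generally unpublished; the variant here is a config knob echoed in all
  outputs, and results should state it.
* The inhibition formula and clamping of upstream tools are likewise
  conventions; both are isolated in single operations to allow
  substitution.
* Feature values are not numerically interchangeable with CellProfiler's —
  the catalog matches in spirit and count, not in implementation detail.
* The 4PL fit is unweighted least squares; robust/weighted variants and
  Bayesian dose–response are out of scope.
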