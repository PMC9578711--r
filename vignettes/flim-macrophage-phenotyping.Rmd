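---
title: "Classifying macrophage polarisation from 2P-FLIM metabolic imaging"
author: "flimMacro authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying macrophage polarisation from 2P-FLIM metabolic imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimMacro)
```

## The scientific problem

Classically activated (IFN&gamma;-M1) and alternatively activated
(IL-4-M2) human macrophages run their metabolism differently: M1 cells
lean on glycolysis, M2 cells on oxidative phosphorylation. Because the
autofluorescent cofactor NAD(P)H has a long fluorescence lifetime when
enzyme-bound and a short one when free, and because the FAD+/NAD(P)H
intensity ratio (the optical redox ratio, ORR) tracks the cellular redox
state, two-photon fluorescence lifetime imaging (2P-FLIM) can read this
metabolic difference out non-invasively — no fixation, no staining. The
contrast between phenotypes sharpens when cells are challenged in real
time with a sequence of metabolic inhibitors (oligomycin, the uncoupler
FCCP, rotenone + antimycin A, 2-DG); the FCCP response separates the two
phenotypes most strongly.

flimMacro implements the full computational side of this assay: a seeded
simulator of TCSPC photon-decay image stacks with known ground truth,
lifetime fitting, phasor analysis, single-cell segmentation and feature
aggregation, extracellular-flux (ECAR/OCR) rate metrics, and a
random-forests classifier tuned by its out-of-bag (OOB) error.

## The decay model and derived quantities

Each pixel of a 2P-FLIM image holds a photon-arrival histogram over the
laser repetition window (12.5 ns at 80 MHz, split into 256 bins). The
package models NAD(P)H decays as bi-exponential,

$$I(t) = I_0\left[\alpha_1 e^{-t/\tau_1} + \alpha_2 e^{-t/\tau_2}\right] + C,$$

where $\tau_1$ is the long (protein-bound) and $\tau_2$ the short (free)
lifetime component, $\alpha_i$ the fractional amplitude of $\tau_i$
($\alpha_1+\alpha_2=1$) and $C$ a constant background. The
amplitude-weighted mean lifetime is

$$\tau_{avg} = \frac{\tau_1\alpha_1 + \tau_2\alpha_2}{\alpha_1+\alpha_2},$$

and the optical redox ratio is the intensity ratio
$\mathrm{ORR} = \mathrm{FAD}^{+}/\mathrm{NAD(P)H}$.

A note on labelling: published descriptions of this model sometimes
cross-pair the amplitude and lifetime subscripts inconsistently. This
package always pairs $\alpha_i$ with $\tau_i$ and orders components long
first ($\tau_1 \ge \tau_2$), enforcing the order by a post-fit swap.

### Fitting choices

`fitDecay()` performs a weighted nonlinear least-squares
(Levenberg–Marquardt) *tail fit* from the histogram peak to the end of
the window. No instrument response function is modelled, so bins before
the peak carry no shape information; they only feed the optional pinned
background estimate (`background = "prepeak"`). Specifics:

* **Weights**: Neyman weights $1/\max(y_i, 1)$ on binned counts, the
  standard TCSPC practice; a Poisson maximum-likelihood fit is available
  via `fitOptions(weighting = "poisson")`.
* **Start values and bounds**: $\tau_1 = 2.5$ ns, $\tau_2 = 0.4$ ns,
  $\alpha_1 = 0.5$, $I_0$ = peak count, $C$ = minimum count; lifetimes
  bounded to [0.05, 10] ns (the physiological NAD(P)H range), amplitudes
  to [0, 1], $C \ge 0$.
* **Goodness gate**: the reduced chi-square
  $\chi^2_\nu = \sum_i (y_i-\mu_i)^2/\max(\mu_i,1) / (n - 5)$ uses
  model-based variance with a floor of one count and 5 free parameters;
  fits with $\chi^2_\nu < 1.3$ are flagged good and only good fits enter
  classification.
* **Photon floor**: per-unit fits require 500 photons (configurable);
  full-field aggregates operate near the $10^6$-photon scale.
* **Units**: the default fitting units are the full-field aggregate decay
  and per-cell aggregate decays. Whether published per-field variables
  derive from one aggregate-ROI fit or from averaged per-pixel fits is
  generally not knowable from reports; the aggregate is this package's
  default because it is photon-efficient and deterministic, and per-cell
  fits use the same machinery.

## Phasor analysis

`phasorTransform()` maps a decay to
$g = \sum_k y_k \cos(\omega t_k)/\sum_k y_k$,
$s = \sum_k y_k \sin(\omega t_k)/\sum_k y_k$ with $t_k$ at bin centres
(second-order accurate) and $\omega = 2\pi f_{rep}$ at the first
harmonic. Mono-exponential decays lie on the universal semicircle
$(g-\tfrac12)^2 + s^2 = \tfrac14$. Because the first harmonic satisfies
$\omega T = 2\pi$ over the repetition window $T$, truncating the decay to
the window does not displace mono-exponential phasors from the
semicircle — only bin discretisation does, at the $10^{-5}$ scale for 256
bins. The harmonic is fixed at 1; no instrument phase/modulation
calibration is applied (the synthetic data need none), though a complex
calibration factor can be folded into real data upstream.

`chordFraction()` projects a phasor orthogonally onto the chord joining
the fixed reference lifetimes 0.4 ns and 3.4 ns (the free/bound NAD(P)H
anchors used in the phasor literature) and reports the normalised
position toward the long-lifetime end, clipped to [0, 1]. Phasors are
computed per cell by default; per-pixel use is possible by passing pixel
histograms directly.

## What the synthetic cohort emulates

`cohortConfig()` + `simulateField()` generate fields of disk-shaped
cells whose per-pixel NAD(P)H histograms follow the bi-exponential model
exactly: each signal photon picks component $i$ with probability
proportional to $\alpha_i\tau_i$ (the component's share of emitted
intensity) and draws an arrival time from the window-truncated
exponential via its inverse CDF; a Poisson background is added per bin.
Photons landing beyond the window are thereby re-drawn rather than
wrapped around, which keeps the forward model exactly invertible by the
IRF-free tail fit. The FAD+ image is realised as
target ORR &times; the cell's NAD(P)H photon count, Poisson-sampled per
pixel, so the intensity-ratio estimator is unbiased in expectation.

The default parameterisation encodes the polarisation physiology the
assay exploits, chosen once from physiological NAD(P)H ranges and the
reported direction and relative strength of effects:

* IL-4-M2 cells carry higher $\tau_1$, $\tau_2$, $\tau_{avg}$ and lower
  ORR than IFN&gamma;-M1 cells under every treatment, with the largest
  lifetime gap under FCCP (e.g. $\tau_1$: 3.10 vs 2.60 ns at FCCP);
* $\tau_{avg}$ rises along the inhibitor sequence and falls under 2-DG
  for both phenotypes;
* effect sizes relative to variability are strongest for the lifetime
  family, intermediate for $\alpha_2$ and weakest for ORR, consistent
  with the reported variable-importance ordering of this assay;
* donor-to-donor variability is an additive Gaussian random effect per
  variable (SDs: 0.08 ns, 0.03 ns, 0.015, 0.10 for
  $\tau_1, \tau_2, \alpha_2$, ORR), shared across a donor's phenotypes
  and treatments — the simplest structure that reproduces per-donor
  differences in single-cell separability;
* cell-to-cell SDs (0.25 ns, 0.08 ns, 0.04, 0.15) make single-cell
  classification noticeably harder than full-field classification, as
  observed in practice.

Geometry and photon budget: 24 cells per field (the stated minimum per
field of view), disk radius 6 px at the 128-px working scale with a
guaranteed 4-px gap (so cells never touch and segmentation needs no
watershed; at radius 8 the random placement of 24 disks would exceed the
jamming density of sequential placement), ~4.2&times;10^4 photons per
cell putting a field at the 10^6-photon scale, and cell positions held
fixed across the treatment sequence of a field, emulating a maintained
field of view. All of these are configurable; production-scale 512-px
images are supported but not the default.

What the simulator does **not** emulate: optical point-spread functions
and the instrument response, photobleaching, realistic cell morphology,
intra-cell spatial heterogeneity, or pile-up effects. Passing tests on
synthetic data therefore validate the *analysis chain* (fitting,
segmentation, aggregation, classification), not the microscope physics.

## Segmentation and tracking

`segmentCells()` re-implements the single-cell stage as Gaussian
smoothing (default $\sigma = 1$ px), Otsu thresholding on
log1p-transformed counts, connected-component labelling, and removal of
components below 20 px or touching the border (partial cells bias
lifetime aggregates). Touching-object splitting by distance-transform
watershed exists behind `watershed = TRUE` for real data.
`matchCellsAcrossTreatments()` tracks cells across the maintained field
of view by greedy nearest-centroid matching within a 10-px displacement
radius; cells without a partner are flagged rather than dropped.

## Extracellular flux metrics

`computeFluxRates()` summarises ECAR/OCR series over the five phases
delimited by the four injections: basal glycolysis = mean ECAR before
oligomycin − non-glycolytic ECAR; max glycolysis = mean ECAR between
oligomycin and FCCP; basal respiration = mean OCR before oligomycin −
non-mitochondrial OCR; max respiration = mean OCR between FCCP and
Rot+AA. Non-glycolytic ECAR and non-mitochondrial OCR are
operationalised as the post-2-DG and post-Rot+AA phase means
respectively, following the assay manufacturer's convention.
Measurements falling exactly on an injection time belong to the
preceding phase. Per-phase areas under the curve use the trapezoidal
rule; blank-well series can be subtracted timepoint-wise.

## Classification protocol

`buildFeatureTable()` assembles (per field or per cell) the predictors
$\tau_{avg}, \tau_1, \tau_2, \alpha_2$, ORR for one treatment (FCCP by
default). $\alpha_1$ is dropped because it is deterministically
$1-\alpha_2$; rows failing the $\chi^2_\nu$ gate are excluded.

`trainRFOOBGrid()` trains one random forest per (ntree, mtry) candidate
with the maximal number of terminal nodes per tree fixed at 8, and picks
the pair minimising the OOB error (ties resolve toward smaller ntree,
then smaller mtry; candidate grids default to
ntree &isin; {50, 100, 150, 200, 250, 300, 400, 500} and mtry 1..p,
since published analyses report chosen values but not their candidate
sets). For the 36-row full-field dataset no holdout exists, so ROC-AUC
and confusion counts are computed from the OOB class-probability votes —
the only honest score available at that size; resubstitution is
deliberately not reported. Donor-specific single-cell models use a
stratified 75/25 train/test split and are scored on the holdout.

Conventions decided here: the positive class is IFN&gamma;-M1; the
probability threshold is 0.5 with ties (score = threshold) counted
positive; z-score matrices use the population SD; no multiple-testing
control is applied to importance rankings. Variable importance reports
the raw OOB-permutation mean decrease in accuracy (with its per-tree
standard error) and the mean decrease in Gini impurity.
`umapEmbed()` provides the cosine-metric UMAP used for visualisation;
it is seeded and single-threaded for reproducibility.

## Determinism and numerical choices

Every stochastic operation takes a seed and is a pure function of
(configuration, seed); the pipeline derives independent sub-streams for
placement, donor effects, photon generation, forest training and splits
from a single configuration seed, so re-running an unchanged
configuration reproduces outputs byte-identically. Degenerate inputs are
governed by explicit contracts: empty histograms and all-equal images
raise typed errors; a field with no detectable cells yields an empty
label map (with a message), not an error; per-cell fit failures are
recorded as flagged rows and excluded downstream rather than aborting a
batch.

## Problem sizes

The default cohort used by the pipeline and the acceptance analyses is
6 donors &times; 2 phenotypes &times; 3 FCCP fields of 24 cells at
128&times;128 px — 36 full-field rows and ~860 single cells — which runs
end-to-end in about a minute on one core. Parameter-recovery analyses
use 100 simulated decays at 10^6 photons. Unit tests run on smaller
fields (48–96 px, 2–8 cells) chosen to exercise the same code paths at
interactive speed.

## Known limitations

* The bi-exponential model is assumed, not selected; no triple-exponential
  or lifetime-distribution alternatives are fitted, and FAD+ is used by
  intensity only.
* Without an IRF, very short lifetimes (approaching the bin width) are
  biased; the default bounds keep fits in the physiological range.
* The simulator's Gaussian donor effect cannot generate donors whose
  effect *direction* flips; observed donor-level failures of single-cell
  classification may have structure this misses.
* OOB-vote confusion counts at n = 36 are themselves noisy; seed-to-seed
  variation of one or two counts is expected.
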