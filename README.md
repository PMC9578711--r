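# flimMacro

Non-invasive classification of human macrophage polarisation from
two-photon fluorescence lifetime imaging (2P-FLIM) of NAD(P)H
autofluorescence and FAD⁺ intensity.

IFNγ-activated (M1) macrophages run on glycolysis; IL-4-activated (M2)
macrophages lean on oxidative phosphorylation. Enzyme-bound NAD(P)H has a
long fluorescence lifetime, free NAD(P)H a short one, so the per-pixel
TCSPC decay histograms of a 2P-FLIM image — together with the optical
redox ratio ORR = FAD⁺/NAD(P)H — encode the metabolic state, and with it
the phenotype. The contrast is strongest when cells are challenged in
real time with sequential metabolic inhibitors (oligomycin, FCCP,
rotenone + antimycin A, 2-DG); the FCCP response separates the
phenotypes best.

The package provides, as one tested pipeline:

* a **seeded simulator** of 2P-FLIM field stacks (per-pixel photon-arrival
  histograms, 256 bins over 12.5 ns at 80 MHz, plus a matched FAD⁺ image)
  with known per-cell ground truth, donor-level random effects, and the
  phenotype × treatment effect structure of the assay;
* **bi-exponential lifetime fitting** of
  `I(t) = I0[α₁ e^(−t/τ₁) + α₂ e^(−t/τ₂)] + C` (IRF-free tail fit,
  Neyman-weighted Levenberg–Marquardt or Poisson likelihood), deriving
  `τ_avg = (τ₁α₁ + τ₂α₂)/(α₁+α₂)` and gating fits at reduced
  χ²ν < 1.3;
* **phasor analysis**: `(g, s)` coordinates at the first harmonic and the
  projection onto the fixed 0.4 ns – 3.4 ns reference chord;
* **cell segmentation** (smooth → Otsu threshold → label → filter),
  per-cell feature aggregation and greedy centroid tracking across the
  treatment sequence;
* **extracellular-flux metrics**: phase means, basal/max glycolysis and
  respiration, per-phase trapezoidal AUCs for ECAR/OCR series;
* **random-forests classification** of M1 vs M2 with hyper-parameters
  (ntree, mtry; 8 terminal nodes max) tuned by out-of-bag error, reporting
  ROC-AUC, confusion counts and permutation/Gini variable importance —
  at full field-of-view level (OOB-scored) and per donor at single-cell
  level (75/25 stratified holdout) — plus cosine-metric UMAP embeddings.

## Worked example

Simulate a million-photon NAD(P)H decay with known parameters, fit it,
and place it on the phasor plot:

```r
library(flimMacro)
acq <- flimAcquisition()                      # 80 MHz, 256 bins, 12.5 ns
gt  <- groundTruth(alpha1 = 0.3, tau1 = 2.5, tau2 = 0.4, C = 0)
h   <- simulateDecayHistogram(gt, acq, nPhotons = 1e6, seed = 1)
fitDecay(h)
#> Bi-exponential tail fit
#>   tau1 = 2.490 ns (alpha1 = 0.314), tau2 = 0.398 ns (alpha2 = 0.686)
#>   tau_avg = 1.054 ns, C = 0.80, chi2_nu = 0.919 (good), n = 1000000 photons
```

The fit recovers the generating parameters (τ₁ = 2.5 ns, τ₂ = 0.4 ns,
α₁ = 0.3) to within a few percent, and the reduced χ²ν ≈ 0.92 passes the
1.3 goodness gate. The same histogram's phasor,

```r
p <- phasorTransform(h, acq)
chordFraction(p, acq)
#> g = 0.544, s = 0.408, chord fraction 0.622
```

sits inside the universal semicircle (as every multi-exponential decay
must) at 62% of the way along the 0.4–3.4 ns chord toward the
long-lifetime end.

Running the full synthetic study — 6 donors × 2 phenotypes × 3 FCCP
fields of 24 cells each — and training the OOB-tuned classifier:

```r
rep <- runPipeline(list(seed = 42, outDir = "out"))
rep$fullFovReport
#> Random-forests model report
#>   ntree = 50, mtry = 1 (8 terminal nodes max), split = oob
#>   OOB error = 0.00%, ROC-AUC = 1.000
#>   confusion (M1 positive): TP=16 FP=0 FN=0 TN=18
variableImportance(rep$fullFovReport)$predictor
#> "tau2_ns" "tau_avg_ns" "tau1_ns" "alpha2" "orr"
```

On the default cohort the full field-of-view classifier separates the
phenotypes essentially perfectly (36 rows; two M1 fields were excluded
by the χ²ν gate), and the lifetime family τ₁/τ₂/τ_avg occupies the top
importance ranks, with α₂ and ORR behind — the variable structure this
assay is known for. Per-donor single-cell models (`rep$donorReports`)
land at ROC-AUC ≈ 0.96–0.99, reflecting the extra cell-level noise.

A thin CLI over the same functions lives at `inst/scripts/flimmacro`
(subcommands `run`, `simulate`, `flux`, `validate`).

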