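acq <- flimAcquisition()

test_that("the decay model evaluates Eq-style closed forms", {
  expect_equal(biexpModel(0, groundTruth(I0 = 1000, alpha1 = 0.5, C = 10)),
               1010)
  # mono-exponential limit
  gt <- groundTruth(I0 = 500, alpha1 = 1, alpha2 = 0, tau1 = 2.0,
                    tau2 = 0.4, C = 3)
  expect_equal(biexpModel(1.2, gt), 500 * exp(-1.2 / 2.0) + 3)
  # value frozen from a 30-digit arbitrary-precision evaluation
  gt2 <- groundTruth(I0 = 1000, alpha1 = 0.6, alpha2 = 0.4, tau1 = 2.0,
                     tau2 = 0.4, C = 10)
  expect_equal(biexpModel(2.0, gt2), 233.422843502499579795968681466,
               tolerance = 1e-12)
  expect_error(biexpModel(-1, gt2), class = "flimDomainError")
})

test_that("tauAverage implements the amplitude-weighted mean", {
  expect_equal(tauAverage(3.0, 0.4, 0.5, 0.5), 1.7)
  expect_equal(tauAverage(2.5, 0.4, 1, 0), 2.5)
  expect_equal(tauAverage(2.8, 0.4, 0.25, 0.75), 1.0)
  expect_error(tauAverage(2.8, 0.4, 0, 0), class = "flimDomainError")
})

test_that("the optical redox ratio is a guarded intensity ratio", {
  expect_equal(opticalRedoxRatio(200, 400), 0.5)
  expect_equal(opticalRedoxRatio(123.4, 123.4), 1.0)
  expect_error(opticalRedoxRatio(10, 0), class = "flimDomainError")
})

test_that("bi-exponential parameters are recovered from a 1e6-photon decay", {
  gt <- groundTruth(alpha1 = 0.3, tau1 = 2.5, tau2 = 0.4, C = 0)
  h <- simulateDecayHistogram(gt, acq, 1e6, seed = 41)
  f <- fitDecay(h)
  expect_lt(abs(f@tau1 - 2.5) / 2.5, 0.05)
  expect_lt(abs(f@tau2 - 0.4) / 0.4, 0.05)
  expect_lt(abs(f@alpha1 - 0.3), 0.05)
  expect_true(goodFit(f))
})

test_that("tau_avg of a mono-exponential decay is identified regardless of the split", {
  gt <- groundTruth(alpha1 = 1, alpha2 = 0, tau1 = 2.0, tau2 = 0.4, C = 0)
  h <- simulateDecayHistogram(gt, acq, 1e6, seed = 42)
  f <- fitDecay(h)
  expect_lt(abs(tauAvg(f) - 2.0) / 2.0, 0.03)
})

test_that("histograms below the photon floor are rejected", {
  h <- decayHistogram(rep(0, 256), acqBinWidth(acq))
  expect_error(fitDecay(h), class = "flimInsufficientPhotonsError")
})

test_that("fitting is deterministic", {
  h <- simulateDecayHistogram(groundTruth(alpha1 = 0.3), acq, 5e4,
                              seed = 43)
  f1 <- fitDecay(h); f2 <- fitDecay(h)
  expect_identical(fitParams(f1), fitParams(f2))
  expect_identical(f1@chi2nu, f2@chi2nu)
})

test_that("fit invariants hold across random ground truths", {
  withr::with_seed(44, {
    for (k in 1:15) {
      gt <- groundTruth(alpha1 = runif(1, 0.15, 0.85),
                        tau1 = runif(1, 1.8, 3.4),
                        tau2 = runif(1, 0.25, 0.6), C = runif(1, 0, 2))
      h <- simulateDecayHistogram(gt, acq, 2e5, seed = 4400 + k)
      f <- fitDecay(h)
      expect_gte(f@tau1, f@tau2)
      expect_equal(f@alpha1 + f@alpha2, 1, tolerance = 1e-9)
      expect_gte(tauAvg(f), f@tau2 - 1e-9)
      expect_lte(tauAvg(f), f@tau1 + 1e-9)
      expect_identical(goodFit(f), f@chi2nu < 1.3)
    }
  })
})

test_that("reduced chi-square is zero for an exact model and ~1 for Poisson data", {
  # histogram manufactured from the model itself
  dt <- acqBinWidth(acq)
  tt <- (seq_len(256) - 1) * dt
  mu <- 800 * (0.35 * exp(-tt / 2.4) + 0.65 * exp(-tt / 0.45)) + 2
  fit <- new("BiExpFit", I0 = 800, alpha1 = 0.35, alpha2 = 0.65,
             tau1 = 2.4, tau2 = 0.45, bg = 2, chi2nu = 0,
             tauAvg = tauAverage(2.4, 0.45, 0.35, 0.65), good = TRUE,
             nPhotons = sum(mu), t0Bin = 1L)
  h <- decayHistogram(mu, dt)
  expect_equal(reducedChiSquare(h, fit), 0)
  # Poisson replicates around the same model
  chis <- withr::with_seed(45, {
    vapply(1:60, function(i) {
      reducedChiSquare(decayHistogram(rpois(256, mu), dt), fit)
    }, numeric(1))
  })
  expect_lt(abs(mean(chis) - 1), 0.12)
  expect_error(reducedChiSquare(decayHistogram(mu[1:4], dt), fit),
               class = "flimDomainError")
})

test_that("the chi-square gate rejects fits at or above 1.3", {
  h <- simulateDecayHistogram(groundTruth(alpha1 = 0.3), acq, 1e5,
                              seed = 46)
  f <- fitDecay(h, options = fitOptions(chi2Gate = 0))  # force-fail gate
  expect_false(goodFit(f))
  fDefault <- fitDecay(h)
  expect_identical(goodFit(fDefault), fDefault@chi2nu < 1.3)
})

test_that("the Poisson-likelihood option agrees with the weighted fit", {
  h <- simulateDecayHistogram(groundTruth(alpha1 = 0.3), acq, 5e5,
                              seed = 47)
  fN <- fitDecay(h)
  fP <- fitDecay(h, options = fitOptions(weighting = "poisson"))
  expect_lt(abs(fN@tau1 - fP@tau1) / fN@tau1, 0.05)
  expect_lt(abs(fN@alpha1 - fP@alpha1), 0.05)
})
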