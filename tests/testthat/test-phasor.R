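acq <- flimAcquisition()
omega <- 2 * pi * acq@repRate * 1e-9

test_that("a delta-like decay sits at the (1, 0) pole", {
  fine <- flimAcquisition(nBins = 4096L)
  h <- decayHistogram(c(1e6, rep(0, 4095)), acqBinWidth(fine))
  p <- phasorTransform(h, fine)
  expect_equal(p$g, 1, tolerance = 1e-3)
  expect_equal(p$s, 0, tolerance = 1e-2)
})

test_that("a mono-exponential with omega*tau = 1 lands at (0.5, 0.5)", {
  tau <- 1 / omega
  cts <- oracleExpectedHistogram(256L, acqWindow(acq), tau, 0.4, 1, 0,
                                 nPhotons = 1e6)
  p <- phasorTransform(decayHistogram(cts, acqBinWidth(acq)), acq)
  expect_equal(p$g, 0.5, tolerance = 1e-3)
  expect_equal(p$s, 0.5, tolerance = 1e-3)
})

test_that("simulated mono-exponentials live on the universal semicircle", {
  for (tau in c(0.4, 1, 2, 3.4)) {
    cts <- oracleExpectedHistogram(256L, acqWindow(acq), tau, 0.4, 1, 0,
                                   nPhotons = 1e6)
    p <- phasorTransform(decayHistogram(cts, acqBinWidth(acq)), acq)
    resid <- abs((p$g - 0.5)^2 + p$s^2 - 0.25)
    expect_lt(resid, 1e-2)
    expect_gte(p$s, 0)
    expect_lte(p$g^2 + p$s^2, 1 + 1e-9)
  }
})

test_that("bi-exponential phasors are convex combinations of components", {
  tau1 <- 2.8; tau2 <- 0.45; a1 <- 0.3; a2 <- 0.7
  cts <- oracleExpectedHistogram(256L, acqWindow(acq), tau1, tau2, a1, a2,
                                 nPhotons = 1e6)
  p <- phasorTransform(decayHistogram(cts, acqBinWidth(acq)), acq)
  ref <- oraclePhasor(tau1, tau2, a1, a2, omega, acqWindow(acq))
  expect_equal(p$g, unname(ref["g"]), tolerance = 1e-3)
  expect_equal(p$s, unname(ref["s"]), tolerance = 1e-3)
})

test_that("the transform is exactly linear in photon-wise mixtures", {
  h1 <- oracleExpectedHistogram(256L, 12.5, 3.0, 0.4, 1, 0, 4e5)
  h2 <- oracleExpectedHistogram(256L, 12.5, 0.5, 0.4, 1, 0, 6e5)
  dt <- 12.5 / 256
  pm <- phasorTransform(decayHistogram(h1 + h2, dt), acq)
  p1 <- phasorTransform(decayHistogram(h1, dt), acq)
  p2 <- phasorTransform(decayHistogram(h2, dt), acq)
  w1 <- sum(h1) / sum(h1 + h2)
  expect_equal(pm$g, w1 * p1$g + (1 - w1) * p2$g, tolerance = 1e-12)
  expect_equal(pm$s, w1 * p1$s + (1 - w1) * p2$s, tolerance = 1e-12)
})

test_that("chord fractions hit the reference endpoints and midpoint", {
  pL <- referencePhasor(3.4, acq); pS <- referencePhasor(0.4, acq)
  expect_equal(chordFraction(pL, acq), 1.0)
  expect_equal(chordFraction(pS, acq), 0.0)
  mid <- data.frame(g = (pL$g + pS$g) / 2, s = (pL$s + pS$s) / 2)
  expect_equal(chordFraction(mid, acq), 0.5)
  expect_error(chordFraction(mid, acq, tauLong = 1, tauShort = 1),
               class = "flimDomainError")
})

test_that("empty histograms and empty point lists are rejected", {
  expect_error(phasorTransform(decayHistogram(rep(0, 16), 0.05), acq),
               class = "flimDomainError")
  expect_error(phasorHistogram(data.frame(g = numeric(0), s = numeric(0)),
                               acq),
               class = "flimDomainError")
})

test_that("phasor histograms conserve counts", {
  one <- data.frame(g = 0.4, s = 0.3)
  hb <- phasorHistogram(one, acq)
  expect_equal(sum(hb$grid), 1)
  two <- data.frame(g = c(0.4, 0.4), s = c(0.3, 0.3))
  hb2 <- phasorHistogram(two, acq)
  expect_equal(sum(hb2$grid), 2)
  expect_equal(max(hb2$grid), 2)  # identical points share one 2-D bin
  expect_equal(sum(hb2$chord), 2)
})

test_that("M2 cells shift toward the long-lifetime chord end under FCCP", {
  ct <- defaultConditionTable()
  cf <- list()
  withr::with_seed(61, {
    for (ph in c("M1", "M2")) {
      mu <- ct[ct$phenotype == ph & ct$treatment == "FCCP", ]
      cf[[ph]] <- vapply(1:100, function(i) {
        gt <- groundTruth(alpha1 = 1 - mu$alpha2 + rnorm(1, 0, 0.04),
                          tau1 = mu$tau1 + rnorm(1, 0, 0.25),
                          tau2 = mu$tau2 + rnorm(1, 0, 0.08), C = 0)
        h <- simulateDecayHistogram(gt, acq, 2e4, seed = 6100 + i +
                                      1000 * (ph == "M2"))
        chordFraction(phasorTransform(h, acq), acq)
      }, numeric(1))
    }
  })
  wt <- stats::wilcox.test(cf$M2, cf$M1, alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})
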