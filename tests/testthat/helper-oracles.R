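# Independent oracles used across the suite; these deliberately avoid the
# package's own code paths.

# Closed-form mean of an exponential(tau) truncated to [0, window].
oracleTruncExpMean <- function(tau, window) {
  tau - window * exp(-window / tau) / (1 - exp(-window / tau))
}

# Brute-force pairwise ROC-AUC: fraction of positive/negative pairs where
# the positive outranks the negative, ties counted one half.
oracleAUC <- function(scores, labels, positive = "M1") {
  ps <- scores[labels == positive]
  ns <- scores[labels != positive]
  tot <- 0
  for (p in ps) for (n in ns)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(ps) * length(ns))
}

# Expected (noise-free) histogram of a window-truncated bi-exponential
# decay: per-bin masses by direct integration of the density.
oracleExpectedHistogram <- function(nBins, window, tau1, tau2, alpha1,
                                    alpha2, nPhotons = 1) {
  edges <- seq(0, window, length.out = nBins + 1L)
  massOne <- function(tau) {
    m <- exp(-edges[-(nBins + 1L)] / tau) - exp(-edges[-1L] / tau)
    m / (1 - exp(-window / tau))
  }
  w1 <- alpha1 * tau1 / (alpha1 * tau1 + alpha2 * tau2)
  nPhotons * (w1 * massOne(tau1) + (1 - w1) * massOne(tau2))
}

# Brute-force phasor of a decay by fine-grained numerical integration of
# the simulator's law: component i emits with probability proportional to
# alpha_i * tau_i, arrival times follow the window-truncated exponential.
oraclePhasor <- function(tau1, tau2, alpha1, alpha2, omega, window,
                         n = 200000L) {
  t <- seq(0, window, length.out = n)
  w1 <- alpha1 * tau1 / (alpha1 * tau1 + alpha2 * tau2)
  comp <- function(tau) exp(-t / tau) / (tau * (1 - exp(-window / tau)))
  dens <- w1 * comp(tau1) + (1 - w1) * comp(tau2)
  tot <- pracma::trapz(t, dens)
  c(g = pracma::trapz(t, dens * cos(omega * t)) / tot,
    s = pracma::trapz(t, dens * sin(omega * t)) / tot)
}

# Fine-grid integration oracle for the AUC of a sampled series: evaluate
# the piecewise-linear interpolant on a dense grid that includes the
# sample knots and integrate with the composite trapezoid rule.
oracleCurveAUC <- function(times, values) {
  grid <- sort(unique(c(times, seq(min(times), max(times),
                                   length.out = 5000L))))
  f <- stats::approxfun(times, values)
  pracma::trapz(grid, f(grid))
}

# Mean silhouette width over two groups, computed from scratch.
oracleSilhouette <- function(xy, labels) {
  d <- as.matrix(stats::dist(xy))
  sil <- vapply(seq_len(nrow(xy)), function(i) {
    same <- labels == labels[i]; same[i] <- FALSE
    a <- mean(d[i, same])
    b <- mean(d[i, !same & seq_len(nrow(xy)) != i])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}

# Small feature cohort of two Gaussian classes with configurable
# separation, for classifier tests.
makeGaussianFeatures <- function(n, p = 5, sep = 5, seed = 1) {
  withr::with_seed(seed, {
    y <- factor(rep(c("M1", "M2"), length.out = n), levels = c("M1", "M2"))
    x <- matrix(rnorm(n * p), n, p)
    x[y == "M2", 1] <- x[y == "M2", 1] + sep
    colnames(x) <- paste0("f", seq_len(p))
    list(x = as.data.frame(x), y = y)
  })
}

# Synthetic single-cell feature rows with a configurable M1/M2 shift.
mkRows <- function(n, seed = 1, phenos = c("M1", "M2"), donor = 1) {
  withr::with_seed(seed, {
    ph <- rep(phenos, length.out = n)
    shift <- ifelse(ph == "M2", 0.5, 0)
    data.frame(donor = donor, phenotype = ph, treatment = "FCCP",
               field_id = 1, cell_id = seq_len(n),
               tau1_ns = 2.6 + shift + rnorm(n, 0, 0.2),
               tau2_ns = 0.4 + 0.2 * shift + rnorm(n, 0, 0.05),
               alpha1 = 0.25, alpha2 = 0.75,
               tau_avg_ns = 0.95 + 0.3 * shift + rnorm(n, 0, 0.08),
               orr = 0.9 - 0.2 * shift + rnorm(n, 0, 0.1),
               chi2_nu = 1.0, n_photons = 5e4, good = TRUE, failed = FALSE)
  })
}

tinyCohort <- function(seed = 101, nDonors = 2L, cellsPerField = 6L,
                       imageSize = 64L, photonsPerCell = 8000,
                       treatments = "FCCP", fieldsPerCondition = 1L,
                       cellRadius = 5L, ...) {
  cohortConfig(seed = seed, nDonors = nDonors, cellsPerField = cellsPerField,
               imageSize = imageSize, photonsPerCell = photonsPerCell,
               treatments = treatments,
               fieldsPerCondition = fieldsPerCondition,
               cellRadius = cellRadius, ...)
}
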