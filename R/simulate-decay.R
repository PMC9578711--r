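#' Simulate a TCSPC photon-arrival histogram
#'
#' Forward simulation of the bi-exponential decay model the fitter inverts.
#' Each signal photon is assigned to lifetime component i with probability
#' proportional to alpha_i * tau_i (the component's share of the total
#' emitted intensity), and its arrival time is drawn from the exponential
#' law with mean tau_i truncated to the measurement window (photons arriving
#' beyond the window are rejected and redrawn; implemented by inverse-CDF
#' sampling of the truncated law). A Poisson background with per-bin mean
#' `C` is added on top.
#'
#' @param params a [GroundTruth-class] parameter set; `C` is the per-bin
#'   Poisson background mean
#' @param acq a [FlimAcquisition-class] object
#' @param nPhotons number of signal photons to draw (>= 0)
#' @param seed integer seed; the result is a pure function of
#'   (params, acq, nPhotons, seed)
#'
#' @return a [DecayHistogram-class]; `metadata` records `nComponent`, the
#'   realised per-component photon counts, and `nBackground`
#' @examples
#' h <- simulateDecayHistogram(groundTruth(alpha1 = 0.3), flimAcquisition(),
#'                             nPhotons = 1e4, seed = 1)
#' totalPhotons(h)
#' @export
simulateDecayHistogram <- function(params, acq, nPhotons, seed) {
  validObject(params); validObject(acq)
  if (length(nPhotons) != 1L || is.na(nPhotons) || nPhotons < 0)
    stopDomain("nPhotons must be a single non-negative count")
  nPhotons <- as.integer(round(nPhotons))
  window <- acqWindow(acq)
  dt <- acqBinWidth(acq)
  nb <- acq@nBins
  withr::with_seed(as.integer(seed), {
    p1 <- params@alpha1 * params@tau1 /
      (params@alpha1 * params@tau1 + params@alpha2 * params@tau2)
    n1 <- if (nPhotons > 0) stats::rbinom(1L, nPhotons, p1) else 0L
    n2 <- nPhotons - n1
    arrivals <- c(rtruncexp(n1, params@tau1, window),
                  rtruncexp(n2, params@tau2, window))
    bins <- pmin.int(floor(arrivals / dt) + 1L, nb)
    counts <- tabulate(bins, nbins = nb)
    bg <- if (params@bg > 0) stats::rpois(nb, params@bg) else integer(nb)
    decayHistogram(counts + bg, dt,
                   metadata = list(nComponent = c(n1, n2),
                                   nBackground = sum(bg)))
  })
}

# Inverse-CDF draw from an exponential(tau) truncated to [0, window].
rtruncexp <- function(n, tau, window) {
  if (n <= 0L) return(numeric(0))
  u <- stats::runif(n)
  -tau * log(1 - u * (1 - exp(-window / tau)))
}
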