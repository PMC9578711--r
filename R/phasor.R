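#' Phasor transform of a decay histogram
#'
#' Model-free Fourier representation of a decay at a given harmonic of the
#' repetition frequency: `g = sum(c * cos(w t)) / sum(c)` and
#' `s = sum(c * sin(w t)) / sum(c)` with `t` at bin centres and
#' `w = 2 pi * harmonic * repRate`. Mono-exponential decays lie on the
#' universal semicircle `(g - 1/2)^2 + s^2 = 1/4`.
#'
#' @param hist a [DecayHistogram-class] with at least one photon
#' @param acq a [FlimAcquisition-class]
#' @param harmonic positive integer harmonic (default 1)
#' @return one-row data.frame with columns g, s, harmonic, omega
#'   (rad/ns)
#' @export
phasorTransform <- function(hist, acq, harmonic = 1L) {
  validObject(hist)
  total <- sum(hist@counts)
  if (total <= 0) stopDomain("empty histogram has no phasor")
  omega <- 2 * pi * harmonic * acq@repRate * 1e-9   # rad/ns
  t <- (seq_along(hist@counts) - 0.5) * hist@binWidth
  data.frame(g = sum(hist@counts * cos(omega * t)) / total,
             s = sum(hist@counts * sin(omega * t)) / total,
             harmonic = as.integer(harmonic), omega = omega)
}

#' Phasor of an ideal mono-exponential decay
#'
#' Closed form `g = 1 / (1 + (w tau)^2)`, `s = w tau / (1 + (w tau)^2)`;
#' the reference points used for the fixed-lifetime chord.
#'
#' @param tau lifetime in ns
#' @param acq a [FlimAcquisition-class]
#' @param harmonic positive integer harmonic
#' @return one-row data.frame with columns g, s, harmonic, omega
#' @export
referencePhasor <- function(tau, acq, harmonic = 1L) {
  if (any(tau <= 0)) stopDomain("tau must be > 0")
  omega <- 2 * pi * harmonic * acq@repRate * 1e-9
  wt <- omega * tau
  data.frame(g = 1 / (1 + wt^2), s = wt / (1 + wt^2),
             harmonic = as.integer(harmonic), omega = omega)
}

#' Position of a phasor along the fixed-lifetime chord
#'
#' Orthogonal projection of a phasor point onto the segment joining the
#' mono-exponential reference phasors of the short and long lifetime
#' (defaults 0.4 ns and 3.4 ns), normalised so that 0 is the short end and
#' 1 the long end, clipped to [0, 1].
#'
#' @param p one-row data.frame (or list) with `g` and `s`
#' @param acq a [FlimAcquisition-class]
#' @param tauLong,tauShort reference lifetimes in ns
#' @param harmonic positive integer harmonic
#' @return fraction in [0, 1] toward the long-lifetime end
#' @export
chordFraction <- function(p, acq, tauLong = 3.4, tauShort = 0.4,
                          harmonic = 1L) {
  if (tauLong <= 0 || tauShort <= 0 || tauLong == tauShort)
    stopDomain("reference lifetimes must be distinct and positive")
  a <- referencePhasor(tauShort, acq, harmonic)
  b <- referencePhasor(tauLong, acq, harmonic)
  ab <- c(b$g - a$g, b$s - a$s)
  len2 <- sum(ab^2)
  if (len2 < 1e-18) stopDomain("reference phasors coincide")
  tpar <- ((p$g - a$g) * ab[1] + (p$s - a$s) * ab[2]) / len2
  pmin(pmax(tpar, 0), 1)
}

#' Phasor density grid and chord-fraction histogram
#'
#' Bins a set of phasor points into a 2-D density over the unit phasor
#' square and a 1-D histogram of their chord fractions over [0, 1].
#'
#' @param points data.frame with columns g and s (one row per unit)
#' @param acq a [FlimAcquisition-class]
#' @param nBins2d side length of the 2-D grid (default 64)
#' @param nBinsChord bins of the chord-fraction histogram (default 20)
#' @param tauLong,tauShort reference lifetimes for the chord
#' @return list with `grid` (nBins2d x nBins2d counts over g, s in
#'   [0, 1]), `chord` (counts over [0, 1]), `chordFraction` (per-point
#'   values) and `breaks` for both axes
#' @export
phasorHistogram <- function(points, acq, nBins2d = 64L, nBinsChord = 20L,
                            tauLong = 3.4, tauShort = 0.4) {
  if (is.null(points) || nrow(points) == 0L)
    stopDomain("point list must be non-empty")
  gb <- seq(0, 1, length.out = nBins2d + 1L)
  gi <- pmin(pmax(findInterval(points$g, gb, rightmost.closed = TRUE), 1L),
             nBins2d)
  si <- pmin(pmax(findInterval(points$s, gb, rightmost.closed = TRUE), 1L),
             nBins2d)
  grid <- matrix(0L, nBins2d, nBins2d)
  for (k in seq_along(gi))
    grid[gi[k], si[k]] <- grid[gi[k], si[k]] + 1L
  cf <- chordFraction(points, acq, tauLong = tauLong, tauShort = tauShort)
  cb <- seq(0, 1, length.out = nBinsChord + 1L)
  ci <- pmin(pmax(findInterval(cf, cb, rightmost.closed = TRUE), 1L),
             nBinsChord)
  list(grid = grid, chord = tabulate(ci, nBinsChord),
       chordFraction = cf, gridBreaks = gb, chordBreaks = cb)
}
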