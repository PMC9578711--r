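#' Create an acquisition description
#'
#' @param repRate pulse repetition frequency in Hz (default 80 MHz)
#' @param nBins time bins per pixel (default 256)
#' @param imageSize image side length in pixels (default 512; tests and the
#'   default synthetic pipeline use 128)
#'
#' @details The measurement window is `1e9 / repRate` ns and the bin width
#'   `window / nBins` ns; both are available through [acqWindow()] and
#'   [acqBinWidth()].
#'
#' @return a [FlimAcquisition-class] object
#' @examples
#' acq <- flimAcquisition(imageSize = 128)
#' acqWindow(acq)   # 12.5 ns at 80 MHz
#' @export
flimAcquisition <- function(repRate = 8e7, nBins = 256L, imageSize = 512L) {
  new("FlimAcquisition", repRate = as.numeric(repRate),
      nBins = as.integer(nBins), imageSize = as.integer(imageSize))
}

#' @rdname flimAcquisition
#' @param acq a [FlimAcquisition-class] object
#' @export
acqWindow <- function(acq) 1e9 / acq@repRate

#' @rdname flimAcquisition
#' @export
acqBinWidth <- function(acq) acqWindow(acq) / acq@nBins

#' Create a ground-truth decay parameter set
#'
#' @param I0 amplitude scale (photons); must be positive
#' @param alpha1 fractional amplitude of the long component; `alpha2` is
#'   `1 - alpha1` unless given explicitly
#' @param alpha2 fractional amplitude of the short component
#' @param tau1 long lifetime (ns)
#' @param tau2 short lifetime (ns)
#' @param C constant background (photons per bin)
#' @return a [GroundTruth-class] object
#' @examples
#' groundTruth(alpha1 = 0.3, tau1 = 2.5, tau2 = 0.4)
#' @export
groundTruth <- function(I0 = 1000, alpha1 = 0.5, alpha2 = 1 - alpha1,
                        tau1 = 2.5, tau2 = 0.4, C = 0) {
  new("GroundTruth", I0 = as.numeric(I0), alpha1 = as.numeric(alpha1),
      alpha2 = as.numeric(alpha2), tau1 = as.numeric(tau1),
      tau2 = as.numeric(tau2), bg = as.numeric(C))
}

#' Create a decay histogram
#'
#' @param counts photon counts per time bin
#' @param binWidth bin width in ns
#' @param metadata optional list of provenance information
#' @return a [DecayHistogram-class] object
#' @export
decayHistogram <- function(counts, binWidth, metadata = list()) {
  new("DecayHistogram", counts = as.numeric(counts),
      binWidth = as.numeric(binWidth), metadata = metadata)
}

#' Create an extracellular-flux series
#'
#' @param times measurement times (minutes), strictly increasing
#' @param ecar,ocr per-timepoint ECAR / OCR values
#' @param schedule four increasing injection times (minutes) for
#'   oligomycin, FCCP, rotenone + antimycin A and 2-DG
#' @param replicate replicate identifier
#' @param group group label
#' @return a [FluxSeries-class] object
#' @export
fluxSeries <- function(times, ecar, ocr, schedule,
                       replicate = "r1", group = "group") {
  schedule <- as.numeric(schedule)
  if (is.null(names(schedule)) || !all(nzchar(names(schedule))))
    names(schedule) <- c("oligomycin", "FCCP", "RotAA", "2DG")
  new("FluxSeries", times = as.numeric(times), ecar = as.numeric(ecar),
      ocr = as.numeric(ocr), schedule = schedule,
      replicate = as.character(replicate), group = as.character(group))
}
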