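#' @import methods
NULL

#' Acquisition geometry of a TCSPC FLIM measurement
#'
#' Describes the timing geometry of a time-correlated single-photon counting
#' (TCSPC) acquisition: laser repetition rate, number of time bins per pixel
#' and image side length.  The measurement window is tied to the repetition
#' rate (window = 1e9 / repRate nanoseconds), so an 80 MHz source gives the
#' canonical 12.5 ns window split into 256 bins.
#'
#' @slot repRate pulse repetition frequency in Hz
#' @slot nBins number of time bins per pixel
#' @slot imageSize image side length in pixels
#'
#' @seealso [flimAcquisition()]
#' @exportClass FlimAcquisition
setClass("FlimAcquisition",
  representation(repRate = "numeric", nBins = "integer", imageSize = "integer"),
  prototype(repRate = 8e7, nBins = 256L, imageSize = 512L))

setValidity("FlimAcquisition", function(object) {
  msg <- NULL
  if (length(object@repRate) != 1L || !is.finite(object@repRate) ||
      object@repRate <= 0)
    msg <- c(msg, "repRate must be a single positive number")
  if (length(object@nBins) != 1L || object@nBins < 2L)
    msg <- c(msg, "nBins must be >= 2")
  if (length(object@imageSize) != 1L || object@imageSize < 1L)
    msg <- c(msg, "imageSize must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' Ground-truth parameters of a bi-exponential fluorescence decay
#'
#' Parameter bundle for the two-component decay model
#' I(t) = I0 * (alpha1 * exp(-t/tau1) + alpha2 * exp(-t/tau2)) + C.
#' alpha_i is the fractional amplitude of lifetime tau_i; tau1 is the long
#' (protein-bound NAD(P)H) and tau2 the short (free NAD(P)H) component.
#'
#' @slot I0 amplitude scale (photons per bin at t = 0, before background)
#' @slot alpha1,alpha2 fractional amplitudes, summing to 1
#' @slot tau1,tau2 lifetimes in ns, tau1 > tau2 > 0
#' @slot C constant background (photons per bin)
#'
#' @seealso [groundTruth()]
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(I0 = "numeric", alpha1 = "numeric", alpha2 = "numeric",
                 tau1 = "numeric", tau2 = "numeric", bg = "numeric"))

setValidity("GroundTruth", function(object) {
  msg <- NULL
  sc <- function(x) length(x) == 1L && is.finite(x)
  if (!all(vapply(list(object@I0, object@alpha1, object@alpha2,
                       object@tau1, object@tau2, object@bg), sc, logical(1))))
    return("all parameters must be finite scalars")
  if (abs(object@alpha1 + object@alpha2 - 1) > 1e-9)
    msg <- c(msg, "alpha1 + alpha2 must equal 1")
  if (object@alpha1 < 0 || object@alpha2 < 0)
    msg <- c(msg, "amplitude fractions must be non-negative")
  if (!(object@tau1 >= object@tau2 && object@tau2 > 0))
    msg <- c(msg, "lifetimes must satisfy tau1 >= tau2 > 0")
  if (object@bg < 0) msg <- c(msg, "background C must be >= 0")
  if (object@I0 <= 0) msg <- c(msg, "I0 must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' Photon-arrival histogram of one pixel, cell or region of interest
#'
#' The raw TCSPC object every lifetime quantity derives from: photon counts
#' per time bin over the measurement window.
#'
#' @slot counts non-negative photon counts per time bin
#' @slot binWidth time-bin width in ns
#' @slot metadata free-form list (e.g. per-component photon counts recorded
#'   by the simulator)
#'
#' @seealso [decayHistogram()], [fitDecay()], [phasorTransform()]
#' @exportClass DecayHistogram
setClass("DecayHistogram",
  representation(counts = "numeric", binWidth = "numeric", metadata = "list"),
  prototype(metadata = list()))

setValidity("DecayHistogram", function(object) {
  msg <- NULL
  if (length(object@counts) < 2L)
    msg <- c(msg, "at least two time bins are required")
  if (any(!is.finite(object@counts)) || any(object@counts < 0))
    msg <- c(msg, "counts must be finite and non-negative")
  if (length(object@binWidth) != 1L || !is.finite(object@binWidth) ||
      object@binWidth <= 0)
    msg <- c(msg, "binWidth must be a single positive number")
  if (is.null(msg)) TRUE else msg
})

#' Result of a bi-exponential tail fit to a decay histogram
#'
#' Fitted parameters of the two-component decay model plus the derived
#' amplitude-weighted mean lifetime, the reduced chi-square of the fit and
#' the goodness gate (chi2nu < 1.3).  Component labels are ordered so that
#' tau1 >= tau2 (long/bound first).
#'
#' @slot I0 fitted amplitude (photons per bin)
#' @slot alpha1,alpha2 fractional amplitudes (sum to 1)
#' @slot tau1,tau2 fitted lifetimes in ns (tau1 >= tau2)
#' @slot C fitted constant background (photons per bin)
#' @slot chi2nu reduced chi-square of the fit
#' @slot tauAvg amplitude-weighted mean lifetime in ns
#' @slot good logical, TRUE when chi2nu < gate (default 1.3)
#' @slot nPhotons total photons in the fitted histogram
#' @slot t0Bin index of the histogram peak the tail fit starts from
#'
#' @seealso [fitDecay()]
#' @exportClass BiExpFit
setClass("BiExpFit",
  representation(I0 = "numeric", alpha1 = "numeric", alpha2 = "numeric",
                 tau1 = "numeric", tau2 = "numeric", bg = "numeric",
                 chi2nu = "numeric", tauAvg = "numeric", good = "logical",
                 nPhotons = "numeric", t0Bin = "integer"))

setValidity("BiExpFit", function(object) {
  msg <- NULL
  if (object@tau1 < object@tau2)
    msg <- c(msg, "tau1 must be >= tau2 (long component first)")
  if (abs(object@alpha1 + object@alpha2 - 1) > 1e-9)
    msg <- c(msg, "alpha1 + alpha2 must equal 1")
  if (object@tauAvg < object@tau2 - 1e-9 || object@tauAvg > object@tau1 + 1e-9)
    msg <- c(msg, "tauAvg must lie between tau2 and tau1")
  if (is.null(msg)) TRUE else msg
})

#' One simulated imaging field under one treatment condition
#'
#' Holds the per-pixel NAD(P)H photon-arrival histograms, the matched FAD+
#' intensity image, the ground-truth cell label map and per-cell parameters,
#' and the (donor, phenotype, treatment, field) condition.
#'
#' @slot nadh numeric array (y, x, time bin) of photon counts
#' @slot fad numeric matrix (y, x) of FAD+ photon counts
#' @slot labels integer matrix of ground-truth cell ids (0 = background)
#' @slot truth data.frame of per-cell ground-truth parameters
#' @slot condition list with elements donor, phenotype, treatment, field
#' @slot binWidth time-bin width in ns
#'
#' @seealso [simulateField()], [fitField()]
#' @exportClass FieldStack
setClass("FieldStack",
  representation(nadh = "array", fad = "matrix", labels = "matrix",
                 truth = "data.frame", condition = "list",
                 binWidth = "numeric"))

setValidity("FieldStack", function(object) {
  msg <- NULL
  if (length(dim(object@nadh)) != 3L)
    msg <- c(msg, "nadh must be a (y, x, bin) array")
  if (any(object@nadh < 0) || any(object@fad < 0))
    msg <- c(msg, "photon counts must be non-negative")
  if (!identical(dim(object@nadh)[1:2], dim(object@fad)) ||
      !identical(dim(object@fad), dim(object@labels)))
    msg <- c(msg, "nadh, fad and labels must share spatial dimensions")
  need <- c("donor", "phenotype", "treatment", "field")
  if (!all(need %in% names(object@condition)))
    msg <- c(msg, "condition must carry donor, phenotype, treatment, field")
  if (is.null(msg)) TRUE else msg
})

#' Cell label map from segmentation
#'
#' @slot labels integer matrix, 0 for background, 1..nCells for cells
#' @slot nCells number of cells
#' @slot centroids nCells x 2 matrix of (y, x) centroids
#' @slot areas per-cell pixel counts
#'
#' @seealso [segmentCells()]
#' @exportClass LabelMap
setClass("LabelMap",
  representation(labels = "matrix", nCells = "integer",
                 centroids = "matrix", areas = "integer"))

setValidity("LabelMap", function(object) {
  msg <- NULL
  lab <- sort(unique(as.vector(object@labels)))
  lab <- lab[lab != 0]
  if (length(lab) != object@nCells ||
      (object@nCells > 0L && !identical(as.integer(lab), seq_len(object@nCells))))
    msg <- c(msg, "labels must be consecutive 1..nCells")
  if (nrow(object@centroids) != object@nCells ||
      length(object@areas) != object@nCells)
    msg <- c(msg, "centroids and areas must have one entry per cell")
  if (is.null(msg)) TRUE else msg
})

#' Extracellular-flux time series for one well
#'
#' ECAR/OCR measurements over time with the four-injection schedule
#' (oligomycin, FCCP, rotenone + antimycin A, 2-DG) that partitions the
#' series into five phases.
#'
#' @slot times measurement times in minutes, strictly increasing
#' @slot ecar extracellular acidification rate per timepoint
#' @slot ocr oxygen consumption rate per timepoint
#' @slot schedule named numeric of the four injection times (minutes)
#' @slot replicate replicate identifier
#' @slot group group label (e.g. M1, M2, UT)
#'
#' @seealso [fluxSeries()], [computeFluxRates()]
#' @exportClass FluxSeries
setClass("FluxSeries",
  representation(times = "numeric", ecar = "numeric", ocr = "numeric",
                 schedule = "numeric", replicate = "character",
                 group = "character"))

setValidity("FluxSeries", function(object) {
  msg <- NULL
  n <- length(object@times)
  if (length(object@ecar) != n || length(object@ocr) != n)
    msg <- c(msg, "times, ecar and ocr must have equal length")
  if (n >= 2L && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(object@schedule) != 4L || any(diff(object@schedule) <= 0))
    msg <- c(msg, "schedule must hold 4 strictly increasing injection times")
  if (n > 0L && (min(object@schedule) < min(object@times) ||
                 max(object@schedule) > max(object@times)))
    msg <- c(msg, "injection times must lie within the measured time range")
  if (any(!is.finite(object@ecar)) || any(!is.finite(object@ocr)))
    msg <- c(msg, "ecar/ocr must be finite")
  if (is.null(msg)) TRUE else msg
})

#' Report of one tuned random-forests classification model
#'
#' Records the grid-search outcome (ntree, mtry at fixed 8 terminal nodes),
#' the out-of-bag error of the selected model, ROC-AUC, confusion counts
#' with IFNg-M1 as the positive class, and per-predictor importance.
#'
#' @slot ntree,mtry selected hyper-parameters
#' @slot oobError out-of-bag error in percent
#' @slot rocAuc area under the ROC curve
#' @slot confusion named integer (TP, FP, FN, TN)
#' @slot importance data.frame with mean decrease accuracy (raw and SD) and
#'   mean decrease Gini per predictor
#' @slot split description of the evaluation split ("oob" or "holdout")
#' @slot seed integer seed the training was derived from
#' @slot model the fitted randomForest object
#'
#' @seealso [trainRFOOBGrid()], [runDonorModels()]
#' @exportClass RFModelReport
setClass("RFModelReport",
  representation(ntree = "integer", mtry = "integer", oobError = "numeric",
                 rocAuc = "numeric", confusion = "integer",
                 importance = "data.frame", split = "character",
                 seed = "integer", model = "ANY"))

setValidity("RFModelReport", function(object) {
  msg <- NULL
  if (!all(c("TP", "FP", "FN", "TN") %in% names(object@confusion)))
    msg <- c(msg, "confusion must carry TP, FP, FN, TN")
  if (object@rocAuc < 0 || object@rocAuc > 1)
    msg <- c(msg, "rocAuc must lie in [0, 1]")
  if (object@oobError < 0 || object@oobError > 100)
    msg <- c(msg, "oobError is a percentage in [0, 100]")
  if (is.null(msg)) TRUE else msg
})
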