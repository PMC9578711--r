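#' Photon-count mask for background removal
#'
#' Pixels whose total photon count falls below a threshold are removed from
#' analysis, improving the signal-to-noise ratio of aggregate decays. The
#' threshold is either absolute or chosen automatically by Otsu's method on
#' log1p-transformed counts.
#'
#' @param intensityImage non-negative matrix of per-pixel total photons
#' @param method "otsu" (default) or "absolute"
#' @param threshold absolute photon threshold (required when
#'   `method = "absolute"`)
#' @return logical matrix, TRUE where the pixel is kept
#' @export
photonMask <- function(intensityImage, method = c("otsu", "absolute"),
                       threshold = NULL) {
  method <- match.arg(method)
  if (any(intensityImage < 0))
    stopDomain("intensity image must be non-negative")
  if (method == "absolute") {
    if (is.null(threshold)) stopDomain("absolute method requires a threshold")
    return(intensityImage >= threshold)
  }
  x <- log1p(intensityImage)
  rng <- range(x)
  if (diff(rng) == 0)
    stop(errorCondition(
      "all pixels are equal; automatic threshold is degenerate",
      class = c("flimDegenerateThresholdError", "error")))
  xn <- (x - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(xn), range = c(0, 1))
  xn >= th
}

# Per-pixel histograms as a (pixels x bins) matrix; built once per field.
histogramMatrix <- function(stack) {
  d <- dim(stack@nadh)
  matrix(stack@nadh, d[1] * d[2], d[3])
}

#' Sum per-pixel histograms over a pixel mask into one aggregate decay
#'
#' @param stack a [FieldStack-class]
#' @param mask logical matrix (or vector) selecting pixels
#' @param m optional precomputed [histogramMatrix] (internal use)
#' @return a [DecayHistogram-class]
#' @export
aggregateHistogram <- function(stack, mask, m = NULL) {
  if (is.null(m)) m <- histogramMatrix(stack)
  counts <- colSums(m[as.vector(mask), , drop = FALSE])
  decayHistogram(counts, stack@binWidth)
}

#' Fit the decays of one imaging field
#'
#' In `full_fov` mode all masked-pixel histograms are summed into one
#' aggregate decay which is fitted once; in `per_cell` mode histograms are
#' summed within each cell label and fitted per cell. Per-unit failures
#' (insufficient photons, non-convergence) are recorded in the returned
#' table rather than aborting the batch.
#'
#' @param stack a [FieldStack-class]
#' @param mode "full_fov" or "per_cell"
#' @param labels optional integer label matrix; defaults to the stack's
#'   ground-truth labels (use [segmentCells()] output for real data)
#' @param mask optional logical mask for `full_fov`; defaults to
#'   `labels > 0` when labels exist, else an automatic [photonMask()]
#' @param options a [fitOptions()] list
#' @return data.frame with columns unit_id, tau1_ns, tau2_ns, alpha1,
#'   alpha2, tau_avg_ns, orr, chi2_nu, n_photons, good, failed, reason
#' @export
fitField <- function(stack, mode = c("full_fov", "per_cell"),
                     labels = NULL, mask = NULL, options = fitOptions()) {
  mode <- match.arg(mode)
  validObject(stack)
  if (is.null(labels)) labels <- stack@labels
  m <- histogramMatrix(stack)
  nadhTotal <- matrix(rowSums(m), nrow(stack@fad), ncol(stack@fad))

  fitUnit <- function(unitId, pixSel) {
    h <- aggregateHistogram(stack, pixSel, m = m)
    nadhSum <- sum(nadhTotal[pixSel]); fadSum <- sum(stack@fad[pixSel])
    res <- tryCatch(list(fit = fitDecay(h, options = options), err = NULL),
                    error = function(e) list(fit = NULL,
                                             err = conditionMessage(e)))
    if (is.null(res$fit)) {
      data.frame(unit_id = unitId, tau1_ns = NA_real_, tau2_ns = NA_real_,
                 alpha1 = NA_real_, alpha2 = NA_real_, tau_avg_ns = NA_real_,
                 orr = NA_real_, chi2_nu = NA_real_,
                 n_photons = sum(h@counts), good = FALSE, failed = TRUE,
                 reason = res$err)
    } else {
      f <- res$fit
      data.frame(unit_id = unitId, tau1_ns = f@tau1, tau2_ns = f@tau2,
                 alpha1 = f@alpha1, alpha2 = f@alpha2, tau_avg_ns = f@tauAvg,
                 orr = if (nadhSum > 0) fadSum / nadhSum else NA_real_,
                 chi2_nu = f@chi2nu, n_photons = f@nPhotons, good = f@good,
                 failed = FALSE, reason = "")
    }
  }

  if (mode == "full_fov") {
    if (is.null(mask)) {
      mask <- if (any(labels > 0)) labels > 0 else photonMask(nadhTotal)
    }
    fitUnit("full_fov", mask)
  } else {
    ids <- sort(unique(as.vector(labels)))
    ids <- ids[ids != 0]
    if (length(ids) == 0L)
      return(data.frame(unit_id = character(0), tau1_ns = numeric(0),
                        tau2_ns = numeric(0), alpha1 = numeric(0),
                        alpha2 = numeric(0), tau_avg_ns = numeric(0),
                        orr = numeric(0), chi2_nu = numeric(0),
                        n_photons = numeric(0), good = logical(0),
                        failed = logical(0), reason = character(0)))
    do.call(rbind, lapply(ids, function(i) fitUnit(i, labels == i)))
  }
}
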