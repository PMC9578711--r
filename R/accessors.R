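#' @rdname DecayHistogram-class
#' @aliases photonCounts,DecayHistogram-method
setMethod("photonCounts", "DecayHistogram", function(object) object@counts)

#' @rdname DecayHistogram-class
setMethod("binWidth", "DecayHistogram", function(object) object@binWidth)

#' @rdname DecayHistogram-class
setMethod("totalPhotons", "DecayHistogram",
          function(object) sum(object@counts))

#' @rdname DecayHistogram-class
setMethod("t0Bin", "DecayHistogram",
          function(object) which.max(object@counts))

setMethod("show", "DecayHistogram", function(object) {
  cat(sprintf("DecayHistogram: %d bins x %.4g ns, %d photons (peak bin %d)\n",
              length(object@counts), object@binWidth,
              round(sum(object@counts)), t0Bin(object)))
})

#' @rdname BiExpFit-class
setMethod("tauAvg", "BiExpFit", function(object) object@tauAvg)

#' @rdname BiExpFit-class
setMethod("goodFit", "BiExpFit", function(object) object@good)

#' @rdname BiExpFit-class
setMethod("fitParams", "BiExpFit", function(object) {
  c(I0 = object@I0, alpha1 = object@alpha1, alpha2 = object@alpha2,
    tau1 = object@tau1, tau2 = object@tau2, C = object@bg)
})

setMethod("show", "BiExpFit", function(object) {
  cat("Bi-exponential tail fit\n")
  cat(sprintf("  tau1 = %.3f ns (alpha1 = %.3f), tau2 = %.3f ns (alpha2 = %.3f)\n",
              object@tau1, object@alpha1, object@tau2, object@alpha2))
  cat(sprintf("  tau_avg = %.3f ns, C = %.2f, chi2_nu = %.3f (%s), n = %d photons\n",
              object@tauAvg, object@bg, object@chi2nu,
              if (object@good) "good" else "rejected",
              round(object@nPhotons)))
})

setMethod("show", "FieldStack", function(object) {
  d <- dim(object@nadh)
  cc <- object@condition
  cat(sprintf("FieldStack %dx%d px, %d time bins | donor %s, %s, %s (field %s)\n",
              d[1], d[2], d[3], cc$donor, cc$phenotype, cc$treatment, cc$field))
  cat(sprintf("  %d cells, %.3g NAD(P)H photons\n",
              nrow(object@truth), sum(object@nadh)))
})

#' @rdname LabelMap-class
setMethod("nCells", "LabelMap", function(object) object@nCells)

#' @rdname LabelMap-class
setMethod("centroids", "LabelMap", function(object) object@centroids)

#' @rdname LabelMap-class
setMethod("cellAreas", "LabelMap", function(object) object@areas)

setMethod("show", "LabelMap", function(object) {
  cat(sprintf("LabelMap: %d cells over %dx%d px\n", object@nCells,
              nrow(object@labels), ncol(object@labels)))
})

setMethod("show", "FluxSeries", function(object) {
  cat(sprintf("FluxSeries [%s / %s]: %d timepoints over %.0f-%.0f min, 4 injections\n",
              object@group, object@replicate, length(object@times),
              min(object@times), max(object@times)))
})

#' @rdname RFModelReport-class
setMethod("oobError", "RFModelReport", function(object) object@oobError)

#' @rdname RFModelReport-class
setMethod("rocAuc", "RFModelReport", function(object) object@rocAuc)

#' @rdname RFModelReport-class
setMethod("confusion", "RFModelReport", function(object) object@confusion)

#' @rdname RFModelReport-class
setMethod("rfImportance", "RFModelReport", function(object) object@importance)

setMethod("show", "RFModelReport", function(object) {
  cat("Random-forests model report\n")
  cat(sprintf("  ntree = %d, mtry = %d (8 terminal nodes max), split = %s\n",
              object@ntree, object@mtry, object@split))
  cat(sprintf("  OOB error = %.2f%%, ROC-AUC = %.3f\n",
              object@oobError, object@rocAuc))
  cm <- object@confusion
  cat(sprintf("  confusion (M1 positive): TP=%d FP=%d FN=%d TN=%d\n",
              cm["TP"], cm["FP"], cm["FN"], cm["TN"]))
})
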