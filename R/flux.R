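#' Per-phase means of an extracellular-flux series
#'
#' Arithmetic mean of the ECAR and OCR measurements within each of the five
#' phases delimited by the four injections. A measurement taken exactly at
#' an injection time belongs to the preceding phase.
#'
#' @param series a [FluxSeries-class]
#' @return data.frame with columns phase (basal, post_oligomycin,
#'   post_FCCP, post_RotAA, post_2DG), n, ecar, ocr
#' @export
phaseMeans <- function(series) {
  validObject(series)
  ph <- fluxPhase(series)
  labs <- fluxPhaseLabels()
  if (!all(seq_len(5L) %in% ph))
    stop(errorCondition(
      sprintf("phase(s) without measurements: %s",
              paste(labs[setdiff(seq_len(5L), unique(ph))], collapse = ", ")),
      class = c("flimPhaseCoverageError", "error")))
  data.frame(
    phase = factor(labs, levels = labs),
    n = as.integer(tabulate(ph, 5L)),
    ecar = as.numeric(tapply(series@ecar, factor(ph, levels = 1:5), mean)),
    ocr = as.numeric(tapply(series@ocr, factor(ph, levels = 1:5), mean)),
    row.names = NULL)
}

fluxPhase <- function(series)
  findInterval(series@times, series@schedule, left.open = TRUE) + 1L

fluxPhaseLabels <- function()
  c("basal", "post_oligomycin", "post_FCCP", "post_RotAA", "post_2DG")

#' Glycolysis and respiration rates from a flux series
#'
#' Computes the four summary rates of the sequential-inhibition assay:
#' basal glycolysis (mean ECAR before oligomycin minus non-glycolytic ECAR),
#' max glycolysis (mean ECAR between oligomycin and FCCP), basal
#' respiration (mean OCR before oligomycin minus non-mitochondrial OCR) and
#' max respiration (mean OCR between FCCP and rotenone + antimycin A).
#' Non-glycolytic ECAR is taken as the post-2-DG phase mean and
#' non-mitochondrial OCR as the post-Rot+AA phase mean, following the
#' manufacturer convention for the assay. Per-phase trapezoidal AUCs are
#' attached for both signals.
#'
#' @param series a [FluxSeries-class]
#' @param blank optional paired blank-well [FluxSeries-class] subtracted
#'   timepoint-wise before computing rates
#' @return one-row data.frame: replicate, group, basal_glycolysis,
#'   max_glycolysis, basal_respiration, max_respiration, and per-phase AUC
#'   columns `auc_ecar_*` / `auc_ocr_*`
#' @export
computeFluxRates <- function(series, blank = NULL) {
  if (!is.null(blank)) {
    if (!identical(blank@times, series@times))
      stopDomain("blank series must share the measurement times")
    series <- fluxSeries(series@times, series@ecar - blank@ecar,
                         series@ocr - blank@ocr, series@schedule,
                         series@replicate, series@group)
  }
  pm <- phaseMeans(series)
  out <- data.frame(
    replicate = series@replicate, group = series@group,
    basal_glycolysis = pm$ecar[1] - pm$ecar[5],
    max_glycolysis = pm$ecar[2],
    basal_respiration = pm$ocr[1] - pm$ocr[4],
    max_respiration = pm$ocr[3])
  for (p in seq_len(5L)) {
    lab <- fluxPhaseLabels()[p]
    out[[paste0("auc_ecar_", lab)]] <-
      tryCatch(aucBetweenTreatments(series, p, "ecar"), error = function(e) NA_real_)
    out[[paste0("auc_ocr_", lab)]] <-
      tryCatch(aucBetweenTreatments(series, p, "ocr"), error = function(e) NA_real_)
  }
  out
}

#' Area under the curve within one assay phase
#'
#' Trapezoidal integral of ECAR or OCR over the measurements falling in the
#' given phase (1 = basal, 2 = post-oligomycin, ..., 5 = post-2-DG).
#'
#' @param series a [FluxSeries-class]
#' @param phase phase index 1..5 or a phase label
#' @param signal "ecar" or "ocr"
#' @return AUC in assay units x minutes
#' @export
aucBetweenTreatments <- function(series, phase, signal = c("ecar", "ocr")) {
  signal <- match.arg(signal)
  if (is.character(phase)) phase <- match(phase, fluxPhaseLabels())
  if (is.na(phase) || phase < 1L || phase > 5L)
    stopDomain("phase must index one of the five assay phases")
  idx <- fluxPhase(series) == phase
  if (sum(idx) < 2L)
    stopDomain("phase has fewer than 2 timepoints; AUC undefined")
  y <- slot(series, signal)[idx]
  pracma::trapz(series@times[idx], y)
}
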