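#' Simulate extracellular-flux (ECAR/OCR) time series
#'
#' Piecewise-constant phase means (basal plus one level after each of the
#' four sequential injections) with additive Gaussian measurement noise,
#' one series per replicate.
#'
#' @param phaseMeans 5 x 2 matrix (or data.frame) of per-phase (ecar, ocr)
#'   levels, rows ordered basal, post-oligomycin, post-FCCP, post-Rot+AA,
#'   post-2-DG
#' @param schedule four strictly increasing injection times (minutes)
#' @param times measurement times; defaults to three measurements per phase
#'   on a 6-minute cadence
#' @param noiseSd Gaussian noise SD (assay units)
#' @param nReplicates number of replicate series
#' @param seed integer seed
#' @param group group label attached to every replicate
#' @return list of [FluxSeries-class], one per replicate
#' @examples
#' pm <- cbind(ecar = c(20, 35, 30, 28, 5), ocr = c(50, 20, 90, 10, 10))
#' simulateFluxSeries(pm, schedule = c(18, 36, 54, 72), noiseSd = 0,
#'                    nReplicates = 1, seed = 1)
#' @export
simulateFluxSeries <- function(phaseMeans, schedule = c(18, 36, 54, 72),
                               times = NULL, noiseSd = 1, nReplicates = 3L,
                               seed, group = "group") {
  phaseMeans <- as.matrix(phaseMeans)
  if (nrow(phaseMeans) != 5L || ncol(phaseMeans) != 2L)
    stopDomain("phaseMeans must be 5 phases x (ecar, ocr)")
  if (length(schedule) != 4L || any(diff(schedule) <= 0))
    stop(errorCondition("schedule must hold 4 strictly increasing times",
                        class = c("flimScheduleError", "error")))
  if (is.null(times)) {
    step <- diff(c(0, schedule))[1] / 3
    times <- seq(step / 2, schedule[4] + 3 * step, by = step)
  }
  phase <- findInterval(times, schedule, left.open = TRUE) + 1L
  if (!all(seq_len(5L) %in% phase))
    stopDomain("every phase needs at least one measurement time")
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(nReplicates), function(r) {
      ecar <- phaseMeans[phase, 1] + stats::rnorm(length(times), 0, noiseSd)
      ocr <- phaseMeans[phase, 2] + stats::rnorm(length(times), 0, noiseSd)
      fluxSeries(times, ecar, ocr, schedule,
                 replicate = paste0("r", r), group = group)
    })
  })
}
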