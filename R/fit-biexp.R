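#' Bi-exponential decay model
#'
#' Expected fluorescence intensity
#' `I0 * (alpha1 * exp(-t / tau1) + alpha2 * exp(-t / tau2)) + C`
#' at time `t` (ns) after excitation.
#'
#' @param t time(s) in ns, `t >= 0`
#' @param params a [GroundTruth-class] parameter set
#' @return expected intensity (photons per bin), same length as `t`
#' @examples
#' biexpModel(0, groundTruth(I0 = 1000, alpha1 = 0.5, C = 10))  # 1010
#' @export
biexpModel <- function(t, params) {
  validObject(params)
  if (any(t < 0)) stopDomain("t must be >= 0")
  params@I0 * (params@alpha1 * exp(-t / params@tau1) +
               params@alpha2 * exp(-t / params@tau2)) + params@bg
}

#' Options for the bi-exponential tail fit
#'
#' @param minPhotons minimum total photons required (default 500, the
#'   per-cell floor; full-field aggregates are expected near the 1e6 scale)
#' @param weighting "neyman" (weights 1/max(counts, 1); default) or
#'   "poisson" (maximum-likelihood fit)
#' @param background "free" fits C as a non-negative parameter (default);
#'   "prepeak" pins it to the mean of the bins before the histogram peak
#'   (falling back to "free" when there are none)
#' @param chi2Gate reduced chi-square threshold below which a fit is
#'   flagged good (default 1.3)
#' @param start named start values (tau1, tau2, alpha1)
#' @param tauBounds lifetime search range in ns
#' @return list of class `FitOptions`
#' @export
fitOptions <- function(minPhotons = 500,
                       weighting = c("neyman", "poisson"),
                       background = c("free", "prepeak"),
                       chi2Gate = 1.3,
                       start = c(tau1 = 2.5, tau2 = 0.4, alpha1 = 0.5),
                       tauBounds = c(0.05, 10)) {
  structure(list(minPhotons = minPhotons, weighting = match.arg(weighting),
                 background = match.arg(background), chi2Gate = chi2Gate,
                 start = start, tauBounds = tauBounds),
            class = "FitOptions")
}

#' Fit a decay histogram with the bi-exponential model
#'
#' Weighted nonlinear least-squares (Levenberg-Marquardt) tail fit over the
#' bins from the histogram peak to the end of the window; no instrument
#' response function is used, so pre-peak bins only inform the optional
#' pinned background estimate. Component labels are swapped after fitting
#' if needed so that tau1 >= tau2, amplitude fractions are normalised to
#' sum to 1, and the fit is gated by reduced chi-square < `chi2Gate`.
#' The result is deterministic given (hist, options).
#'
#' @param hist a [DecayHistogram-class]
#' @param acq optional [FlimAcquisition-class] (only its bin width is used,
#'   and the histogram carries its own; kept for interface symmetry)
#' @param options a [fitOptions()] list
#' @return a [BiExpFit-class]
#' @examples
#' h <- simulateDecayHistogram(groundTruth(alpha1 = 0.3, I0 = 1),
#'                             flimAcquisition(), 1e5, seed = 7)
#' fitDecay(h)
#' @export
fitDecay <- function(hist, acq = NULL, options = fitOptions()) {
  validObject(hist)
  counts <- hist@counts
  n <- sum(counts)
  if (n < options$minPhotons)
    stop(errorCondition(
      sprintf("histogram holds %d photons, below the minimum of %d",
              round(n), round(options$minPhotons)),
      class = c("flimInsufficientPhotonsError", "error")))
  dt <- hist@binWidth
  t0 <- which.max(counts)
  idx <- t0:length(counts)
  y <- counts[idx]
  tt <- (idx - t0) * dt           # time relative to the peak-bin centre
  w <- 1 / pmax(y, 1)

  pinC <- options$background == "prepeak" && t0 > 1L
  Cpin <- if (pinC) mean(counts[seq_len(t0 - 1L)]) else NA_real_

  st <- list(I0 = max(y), a1 = unname(options$start["alpha1"]),
             tau1 = unname(options$start["tau1"]),
             tau2 = unname(options$start["tau2"]))
  if (!pinC) st$C <- min(y)
  lowB <- c(I0 = 1e-6, a1 = 0, tau1 = options$tauBounds[1],
            tau2 = options$tauBounds[1], C = 0)
  uppB <- c(I0 = Inf, a1 = 1, tau1 = options$tauBounds[2],
            tau2 = options$tauBounds[2], C = Inf)
  if (pinC) { lowB <- lowB[1:4]; uppB <- uppB[1:4] }

  model <- function(p) {
    C <- if (pinC) Cpin else p["C"]
    p["I0"] * (p["a1"] * exp(-tt / p["tau1"]) +
               (1 - p["a1"]) * exp(-tt / p["tau2"])) + C
  }

  if (options$weighting == "poisson") {
    nll <- function(pv) {
      p <- stats::setNames(pv, names(lowB))
      mu <- pmax(model(p), 1e-12)
      sum(mu - y * log(mu))
    }
    opt <- stats::optim(unlist(st), nll, method = "L-BFGS-B",
                        lower = lowB, upper = uppB,
                        control = list(maxit = 500))
    if (opt$convergence != 0)
      stop(errorCondition(
        sprintf("Poisson fit did not converge (code %d)", opt$convergence),
        class = c("flimConvergenceError", "error")))
    est <- stats::setNames(opt$par, names(lowB))
  } else {
    df <- data.frame(y = y, tt = tt)
    fml <- if (pinC)
      y ~ I0 * (a1 * exp(-tt / tau1) + (1 - a1) * exp(-tt / tau2)) + 0 * tt + Cpin
    else
      y ~ I0 * (a1 * exp(-tt / tau1) + (1 - a1) * exp(-tt / tau2)) + C
    fit <- tryCatch(
      minpack.lm::nlsLM(fml, data = df, start = st, weights = w,
                        lower = unname(lowB), upper = unname(uppB),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e)
        stop(errorCondition(
          sprintf("optimiser failed: %s", conditionMessage(e)),
          class = c("flimConvergenceError", "error"))))
    est <- stats::coef(fit)
  }

  I0 <- unname(est["I0"]); a1 <- unname(est["a1"])
  tau1 <- unname(est["tau1"]); tau2 <- unname(est["tau2"])
  C <- if (pinC) Cpin else unname(est["C"])
  a2 <- 1 - a1
  if (tau1 < tau2) {            # enforce long-component-first labelling
    tmp <- tau1; tau1 <- tau2; tau2 <- tmp
    tmp <- a1; a1 <- a2; a2 <- tmp
  }
  s <- a1 + a2                  # always 1 by construction; keep the guard
  a1 <- a1 / s; a2 <- a2 / s
  tav <- tauAverage(tau1, tau2, a1, a2)

  out <- new("BiExpFit", I0 = I0, alpha1 = a1, alpha2 = a2,
             tau1 = tau1, tau2 = tau2, bg = C, chi2nu = 0,
             tauAvg = tav, good = TRUE, nPhotons = n, t0Bin = as.integer(t0))
  chi2 <- reducedChiSquare(hist, out)
  out@chi2nu <- chi2
  out@good <- chi2 < options$chi2Gate
  out
}

#' Reduced chi-square of a fitted decay
#'
#' Sum over the fitted (tail) bins of (observed - model)^2 / max(model, 1),
#' divided by the degrees of freedom (fitted bins minus the number of free
#' parameters, 5 by default).
#'
#' @param hist the fitted [DecayHistogram-class]
#' @param fit the [BiExpFit-class] whose model is evaluated
#' @param nParams number of free parameters (default 5)
#' @return reduced chi-square (unitless)
#' @export
reducedChiSquare <- function(hist, fit, nParams = 5L) {
  counts <- hist@counts
  t0 <- fit@t0Bin
  idx <- t0:length(counts)
  dof <- length(idx) - nParams
  if (dof <= 0L) stopDomain("degrees of freedom must be positive")
  tt <- (idx - t0) * hist@binWidth
  mu <- fit@I0 * (fit@alpha1 * exp(-tt / fit@tau1) +
                  fit@alpha2 * exp(-tt / fit@tau2)) + fit@bg
  sum((counts[idx] - mu)^2 / pmax(mu, 1)) / dof
}

#' Amplitude-weighted mean lifetime
#'
#' `(tau1 * alpha1 + tau2 * alpha2) / (alpha1 + alpha2)`.
#'
#' @param tau1,tau2 lifetimes in ns
#' @param alpha1,alpha2 amplitude fractions, `alpha1 + alpha2 > 0`
#' @return mean lifetime in ns
#' @examples
#' tauAverage(3.0, 0.4, 0.5, 0.5)  # 1.7
#' @export
tauAverage <- function(tau1, tau2, alpha1, alpha2) {
  s <- alpha1 + alpha2
  if (any(s <= 0)) stopDomain("alpha1 + alpha2 must be > 0")
  (tau1 * alpha1 + tau2 * alpha2) / s
}

#' Optical redox ratio
#'
#' FAD+ intensity divided by NAD(P)H intensity.
#'
#' @param fadIntensity FAD+ photons (or mean intensity)
#' @param nadphIntensity NAD(P)H photons (or mean intensity), must be > 0
#' @return unitless ratio
#' @export
opticalRedoxRatio <- function(fadIntensity, nadphIntensity) {
  if (any(nadphIntensity <= 0))
    stopDomain("NAD(P)H intensity must be > 0")
  fadIntensity / nadphIntensity
}
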