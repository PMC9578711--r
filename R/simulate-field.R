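#' Default condition means for the synthetic macrophage cohort
#'
#' Per (phenotype, treatment) means of the generative parameters
#' (tau1, tau2, alpha2, ORR).  Values sit in the physiological NAD(P)H range
#' (bound lifetime ~2.4-3.1 ns, free lifetime ~0.34-0.5 ns) and encode the
#' observed direction of polarisation effects: IL-4-M2 macrophages carry
#' higher tau1, tau2 and tau_avg and lower ORR than IFNg-M1 macrophages,
#' with the largest gap under FCCP uncoupling; tau_avg rises along the
#' inhibitor sequence and drops under 2-DG for both phenotypes.
#'
#' @return data.frame with columns phenotype, treatment, tau1, tau2,
#'   alpha2, orr
#' @export
defaultConditionTable <- function() {
  tr <- c("baseline", "oligomycin", "FCCP", "RotAA", "2DG")
  m1 <- data.frame(
    phenotype = "M1", treatment = tr,
    tau1   = c(2.50, 2.55, 2.60, 2.60, 2.40),
    tau2   = c(0.36, 0.37, 0.38, 0.38, 0.34),
    alpha2 = c(0.80, 0.79, 0.78, 0.79, 0.82),
    orr    = c(0.90, 0.88, 0.91, 0.89, 0.95))
  m2 <- data.frame(
    phenotype = "M2", treatment = tr,
    tau1   = c(2.80, 2.90, 3.10, 2.95, 2.70),
    tau2   = c(0.42, 0.45, 0.50, 0.46, 0.40),
    alpha2 = c(0.78, 0.77, 0.755, 0.765, 0.80),
    orr    = c(0.82, 0.78, 0.79, 0.79, 0.86))
  rbind(m1, m2)
}

#' Configure a synthetic imaging cohort
#'
#' Defines the study conditions the generator emulates: donors, phenotypes
#' (IFNg-M1, IL-4-M2), the sequential inhibitor treatments, per-condition
#' parameter means, cell-to-cell and donor-level variability, and the
#' imaging geometry.
#'
#' @param nDonors number of donors (default 6)
#' @param phenotypes phenotype labels
#' @param treatments ordered treatment labels
#' @param conditionTable per-condition means, see [defaultConditionTable()]
#' @param cellSd named cell-to-cell SDs for tau1, tau2, alpha2, orr
#' @param donorEffectSd named SDs of the additive Gaussian donor-level
#'   random effect per variable
#' @param cellsPerField cells per field of view (default 24)
#' @param fieldsPerCondition imaging fields per donor x phenotype x
#'   treatment (default 3)
#' @param imageSize image side in pixels (default 128)
#' @param cellRadius cell disk radius in pixels (default 6; cells keep a
#'   gap of at least 4 px so that smoothing during segmentation cannot
#'   bridge neighbouring cells)
#' @param photonsPerCell mean NAD(P)H signal photons per cell; the default
#'   puts the full-field photon budget at the 1e6 scale
#' @param background per-pixel per-bin Poisson background mean
#' @param seed mandatory integer seed
#'
#' @return a validated list of class `CohortConfig`
#' @examples
#' cfg <- cohortConfig(seed = 1, nDonors = 2, treatments = "FCCP",
#'                     imageSize = 64, cellsPerField = 5)
#' @export
cohortConfig <- function(nDonors = 6L,
                         phenotypes = c("M1", "M2"),
                         treatments = c("baseline", "oligomycin", "FCCP",
                                        "RotAA", "2DG"),
                         conditionTable = defaultConditionTable(),
                         cellSd = c(tau1 = 0.25, tau2 = 0.08,
                                    alpha2 = 0.04, orr = 0.15),
                         donorEffectSd = c(tau1 = 0.08, tau2 = 0.03,
                                           alpha2 = 0.015, orr = 0.10),
                         cellsPerField = 24L,
                         fieldsPerCondition = 3L,
                         imageSize = 128L,
                         cellRadius = 6L,
                         photonsPerCell = 42000,
                         background = 0.02,
                         seed) {
  if (missing(seed) || length(seed) != 1L || is.na(seed))
    stopValidation("cohortConfig requires a single integer seed")
  cfg <- structure(list(
    nDonors = as.integer(nDonors), phenotypes = phenotypes,
    treatments = treatments, conditionTable = conditionTable,
    cellSd = cellSd, donorEffectSd = donorEffectSd,
    cellsPerField = as.integer(cellsPerField),
    fieldsPerCondition = as.integer(fieldsPerCondition),
    imageSize = as.integer(imageSize), cellRadius = as.integer(cellRadius),
    photonsPerCell = as.numeric(photonsPerCell),
    background = as.numeric(background),
    seed = as.integer(seed)), class = "CohortConfig")
  validateCohortConfig(cfg)
  cfg
}

validateCohortConfig <- function(cfg) {
  vars <- c("tau1", "tau2", "alpha2", "orr")
  if (cfg$nDonors < 1L) stopValidation("nDonors must be >= 1")
  if (cfg$cellsPerField < 1L) stopValidation("cellsPerField must be >= 1")
  if (cfg$fieldsPerCondition < 1L)
    stopValidation("fieldsPerCondition must be >= 1")
  if (!all(vars %in% names(cfg$cellSd)) || any(cfg$cellSd < 0))
    stopValidation("cellSd must name tau1, tau2, alpha2, orr with SDs >= 0")
  if (!all(vars %in% names(cfg$donorEffectSd)) || any(cfg$donorEffectSd < 0))
    stopValidation("donorEffectSd must name tau1, tau2, alpha2, orr with SDs >= 0")
  ct <- cfg$conditionTable
  need <- c("phenotype", "treatment", vars)
  if (!all(need %in% names(ct)))
    stopValidation("conditionTable must carry columns %s",
                   paste(need, collapse = ", "))
  combos <- expand.grid(phenotype = cfg$phenotypes,
                        treatment = cfg$treatments,
                        stringsAsFactors = FALSE)
  if (!all(paste(combos$phenotype, combos$treatment) %in%
           paste(ct$phenotype, ct$treatment)))
    stopValidation("conditionTable is missing phenotype x treatment rows")
  # Polarisation effect directions under FCCP must be encoded in the means.
  if ("FCCP" %in% cfg$treatments && all(c("M1", "M2") %in% cfg$phenotypes)) {
    f <- ct[ct$treatment == "FCCP", ]
    m1 <- f[f$phenotype == "M1", ]; m2 <- f[f$phenotype == "M2", ]
    tavg <- function(r) r$tau1 * (1 - r$alpha2) + r$tau2 * r$alpha2
    if (!(m2$tau1 > m1$tau1 && m2$tau2 > m1$tau2 &&
          tavg(m2) > tavg(m1) && m2$orr < m1$orr))
      stopValidation(paste("FCCP means must order M2 > M1 in tau1, tau2,",
                           "tau_avg and M2 < M1 in ORR"))
  }
  if (2 * (cfg$cellRadius + 7) >= cfg$imageSize)
    stopValidation("imageSize too small for the configured cellRadius")
  invisible(cfg)
}

conditionRow <- function(cfg, phenotype, treatment) {
  ct <- cfg$conditionTable
  r <- ct[ct$phenotype == phenotype & ct$treatment == treatment, ]
  if (nrow(r) != 1L)
    stopValidation("no condition row for phenotype %s, treatment %s",
                   phenotype, treatment)
  r
}

# Additive donor-level random effect, one draw per donor shared across the
# donor's phenotypes and treatments.
donorEffect <- function(cfg, donor) {
  withr::with_seed(deriveSeed(cfg$seed, donor, "donor_effect"), {
    stats::rnorm(4) * cfg$donorEffectSd[c("tau1", "tau2", "alpha2", "orr")]
  })
}

# Non-overlapping disk centres; positions depend on (donor, phenotype,
# field) but not on treatment, emulating a maintained field of view across
# the inhibitor sequence.
placeCells <- function(cfg, donor, phenotype, field) {
  r <- cfg$cellRadius
  # margin keeps cells clear of the border even after segmentation blur
  lo <- r + 7; hi <- cfg$imageSize - r - 6
  withr::with_seed(deriveSeed(cfg$seed, donor, phenotype, field, "placement"), {
    centres <- matrix(NA_real_, cfg$cellsPerField, 2)
    for (i in seq_len(cfg$cellsPerField)) {
      ok <- FALSE
      for (try in seq_len(500L)) {
        cand <- stats::runif(2, lo, hi)
        if (i == 1L || all((centres[seq_len(i - 1L), 1] - cand[1])^2 +
                           (centres[seq_len(i - 1L), 2] - cand[2])^2 >
                           (2 * r + 4)^2)) {
          centres[i, ] <- cand; ok <- TRUE; break
        }
      }
      if (!ok)
        stop(errorCondition(
          sprintf("could not place %d non-overlapping cells after bounded retries",
                  cfg$cellsPerField),
          class = c("flimPlacementError", "error")))
    }
    centres
  })
}

#' Simulate one imaging field
#'
#' Generates a [FieldStack-class] for one (donor, phenotype, treatment,
#' field) condition: non-overlapping disk-shaped cells at positions that are
#' identical across the treatment sequence of a field, per-cell decay
#' parameters drawn from the condition's distributions plus the donor's
#' random effect, per-pixel NAD(P)H photon-arrival histograms, and a FAD+
#' intensity image realised so each cell's expected ORR equals its drawn
#' target (FAD+ photons = target ORR x the cell's NAD(P)H photons,
#' Poisson-sampled per pixel).
#'
#' @param cfg a [cohortConfig()] object
#' @param donor donor index (1..nDonors)
#' @param phenotype one of `cfg$phenotypes`
#' @param treatment one of `cfg$treatments`
#' @param field field index (1..fieldsPerCondition)
#' @param acq optional [FlimAcquisition-class]; defaults to 80 MHz / 256
#'   bins at `cfg$imageSize`
#' @return a [FieldStack-class]
#' @export
simulateField <- function(cfg, donor, phenotype, treatment, field = 1L,
                          acq = NULL) {
  validateCohortConfig(cfg)
  if (!phenotype %in% cfg$phenotypes || !treatment %in% cfg$treatments)
    stopDomain("condition (%s, %s) outside the cohort's label sets",
               phenotype, treatment)
  if (is.null(acq))
    acq <- flimAcquisition(imageSize = cfg$imageSize)
  nb <- acq@nBins; dt <- acqBinWidth(acq); window <- acqWindow(acq)
  size <- cfg$imageSize
  centres <- placeCells(cfg, donor, phenotype, field)
  de <- donorEffect(cfg, donor)
  mu <- conditionRow(cfg, phenotype, treatment)

  labels <- matrix(0L, size, size)
  yy <- matrix(seq_len(size), size, size)
  xx <- matrix(seq_len(size), size, size, byrow = TRUE)
  for (i in seq_len(nrow(centres))) {
    inside <- (yy - centres[i, 1])^2 + (xx - centres[i, 2])^2 <=
      cfg$cellRadius^2
    labels[inside] <- i
  }

  withr::with_seed(deriveSeed(cfg$seed, donor, phenotype, field, treatment,
                              "photons"), {
    nCell <- nrow(centres)
    tau2 <- pmax(stats::rnorm(nCell, mu$tau2 + de["tau2"],
                              cfg$cellSd["tau2"]), 0.1)
    tau1 <- pmax(stats::rnorm(nCell, mu$tau1 + de["tau1"],
                              cfg$cellSd["tau1"]), tau2 + 0.2)
    alpha2 <- pmin(pmax(stats::rnorm(nCell, mu$alpha2 + de["alpha2"],
                                     cfg$cellSd["alpha2"]), 0.05), 0.95)
    orr <- pmax(stats::rnorm(nCell, mu$orr + de["orr"],
                             cfg$cellSd["orr"]), 0.05)
    alpha1 <- 1 - alpha2

    nadh <- numeric(size * size * nb)
    fad <- matrix(0, size, size)
    nPhotCell <- integer(nCell)
    for (i in seq_len(nCell)) {
      pix <- which(labels == i)   # linear (y, x) indices
      n <- stats::rpois(1L, cfg$photonsPerCell)
      nPhotCell[i] <- n
      if (n > 0L) {
        p1 <- alpha1[i] * tau1[i] /
          (alpha1[i] * tau1[i] + alpha2[i] * tau2[i])
        n1 <- stats::rbinom(1L, n, p1)
        arrivals <- c(rtruncexp(n1, tau1[i], window),
                      rtruncexp(n - n1, tau2[i], window))
        bins <- pmin.int(floor(arrivals / dt) + 1L, nb)
        where <- pix[sample.int(length(pix), n, replace = TRUE)]
        idx <- where + (bins - 1L) * (size * size)
        add <- tabulate(idx, nbins = size * size * nb)
        nadh <- nadh + add
      }
      fad[pix] <- stats::rpois(length(pix),
                               orr[i] * n / length(pix))
    }
    if (cfg$background > 0)
      nadh <- nadh + stats::rpois(size * size * nb, cfg$background)
    dim(nadh) <- c(size, size, nb)

    truth <- data.frame(
      cell = seq_len(nCell), y = centres[, 1], x = centres[, 2],
      radius = cfg$cellRadius, tau1 = tau1, tau2 = tau2,
      alpha1 = alpha1, alpha2 = alpha2,
      tau_avg = tau1 * alpha1 + tau2 * alpha2, orr = orr,
      n_photons = nPhotCell)

    new("FieldStack", nadh = nadh, fad = fad, labels = labels,
        truth = truth,
        condition = list(donor = donor, phenotype = phenotype,
                         treatment = treatment, field = field),
        binWidth = dt)
  })
}

#' Simulate a full cohort of imaging fields
#'
#' Generates every (donor, phenotype, treatment, field) combination of the
#' configuration and the matching ground-truth cell table. For large
#' configurations prefer [runPipeline()], which streams fields instead of
#' holding the whole cohort in memory.
#'
#' @param cfg a [cohortConfig()] object
#' @return list with `fields` (list of [FieldStack-class]) and `truth`
#'   (data.frame of per-cell ground truth with condition identifiers)
#' @export
simulateCohort <- function(cfg) {
  validateCohortConfig(cfg)
  fields <- list(); truth <- list(); k <- 0L
  for (donor in seq_len(cfg$nDonors))
    for (phenotype in cfg$phenotypes)
      for (treatment in cfg$treatments)
        for (field in seq_len(cfg$fieldsPerCondition)) {
          k <- k + 1L
          fs <- simulateField(cfg, donor, phenotype, treatment, field)
          fields[[k]] <- fs
          tt <- fs@truth
          tt$donor <- donor; tt$phenotype <- phenotype
          tt$treatment <- treatment; tt$field <- field
          truth[[k]] <- tt
        }
  list(fields = fields, truth = do.call(rbind, truth))
}
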