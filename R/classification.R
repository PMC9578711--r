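#' Assemble the classification feature table
#'
#' Filters feature rows to one treatment condition (FCCP by default, where
#' phenotype separation is strongest), drops rows failing the reduced
#' chi-square gate, and builds the predictor matrix. The alpha1 amplitude
#' is removed by default because of its deterministic negative relationship
#' with alpha2, leaving predictors (tau_avg, tau1, tau2, alpha2, ORR).
#'
#' @param rows feature data.frame (schema of [aggregateCellFeatures()] /
#'   the full-FoV fit table with identifier columns)
#' @param level "full_fov" or "single_cell" (provenance only; both use the
#'   same predictor set)
#' @param treatment treatment condition to keep (default "FCCP")
#' @param dropCollinear drop alpha1 (default TRUE)
#' @param predictors optional explicit predictor subset (e.g.
#'   `c("tau1_ns", "tau2_ns", "tau_avg_ns")`)
#' @return list with `x` (numeric predictor data.frame), `y` (factor with
#'   levels M1, M2) and `meta` (provenance columns)
#' @export
buildFeatureTable <- function(rows, level = c("full_fov", "single_cell"),
                              treatment = "FCCP", dropCollinear = TRUE,
                              predictors = NULL) {
  level <- match.arg(level)
  keep <- rows$treatment == treatment & !is.na(rows$tau1_ns)
  if ("good" %in% names(rows)) keep <- keep & rows$good
  if ("failed" %in% names(rows)) keep <- keep & !rows$failed
  rows <- rows[keep, , drop = FALSE]
  if (is.null(predictors)) {
    predictors <- c("tau_avg_ns", "tau1_ns", "tau2_ns", "alpha2", "orr")
    if (!dropCollinear) predictors <- c(predictors, "alpha1")
  }
  if (length(unique(rows$phenotype)) < 2L)
    stop(errorCondition("fewer than 2 phenotype classes present",
                        class = c("flimClassCoverageError", "error")))
  x <- rows[, predictors, drop = FALSE]
  if (anyNA(x)) stopDomain("predictor columns contain missing values")
  metaCols <- intersect(c("donor", "phenotype", "treatment", "field_id",
                          "cell_id"), names(rows))
  list(x = x, y = factor(rows$phenotype, levels = c("M1", "M2")),
       meta = rows[, metaCols, drop = FALSE])
}

#' Column-wise z-scores
#'
#' Standardises each column to mean 0 and SD 1 using the population SD
#' (divide by n). Zero-variance columns map to all-zeros with a warning.
#'
#' @param x numeric matrix or data.frame with at least 2 rows
#' @return numeric matrix of z-scores
#' @export
zscoreMatrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stopDomain("z-scores need at least 2 rows")
  mu <- colMeans(x)
  sdev <- sqrt(colMeans(sweep(x, 2, mu)^2))
  out <- sweep(x, 2, mu)
  degen <- sdev == 0
  if (any(degen)) {
    warning("zero-variance column(s) mapped to zeros: ",
            paste(colnames(x)[degen], collapse = ", "))
    sdev[degen] <- 1
  }
  out <- sweep(out, 2, sdev, "/")
  out[, degen] <- 0
  out
}

#' UMAP embedding with cosine distance
#'
#' Two-dimensional embedding of the feature rows using a cosine distance
#' function; deterministic given the seed.
#'
#' @param x numeric matrix or data.frame of features
#' @param seed integer seed
#' @param nNeighbors neighbourhood size (capped at n - 1)
#' @param metric distance metric (default "cosine")
#' @return n x 2 matrix of embedding coordinates
#' @export
umapEmbed <- function(x, seed, nNeighbors = 15L, metric = "cosine") {
  x <- as.matrix(x)
  if (nrow(x) < 4L) stopDomain("too few rows to embed")
  nn <- min(nNeighbors, nrow(x) - 1L)
  withr::with_seed(as.integer(seed), {
    uwot::umap(x, n_neighbors = nn, metric = metric, n_threads = 1,
               n_sgd_threads = 0, batch = FALSE)
  })
}

#' ROC-AUC by the rank (Mann-Whitney) formulation
#'
#' Probability that a randomly chosen positive outranks a randomly chosen
#' negative, ties counted one half; equivalent to trapezoidal integration
#' of the ROC curve.
#'
#' @param scores numeric class-probability (or any monotone score) per row
#' @param labels factor/character labels
#' @param positive positive class (default "M1")
#' @return AUC in [0, 1]
#' @examples
#' rocAUC(c(0.9, 0.4, 0.8, 0.2), c("M1", "M1", "M2", "M2"))  # 0.75
#' @export
rocAUC <- function(scores, labels, positive = "M1") {
  pos <- labels == positive
  nPos <- sum(pos); nNeg <- sum(!pos)
  if (nPos == 0L || nNeg == 0L)
    stopDomain("both classes must be present to compute ROC-AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Confusion counts at a probability threshold
#'
#' Rows with score >= threshold are predicted positive (IFNg-M1 by
#' convention), ties therefore resolve toward the positive class.
#'
#' @param scores numeric positive-class probability per row
#' @param labels factor/character labels
#' @param threshold decision threshold (default 0.5)
#' @param positive positive class (default "M1")
#' @return named integer vector (TP, FP, FN, TN)
#' @export
confusionCounts <- function(scores, labels, threshold = 0.5,
                            positive = "M1") {
  pos <- labels == positive
  predPos <- scores >= threshold
  c(TP = sum(predPos & pos), FP = sum(predPos & !pos),
    FN = sum(!predPos & pos), TN = sum(!predPos & !pos))
}

#' Candidate grid for the OOB hyper-parameter search
#'
#' @param ntree candidate numbers of trees
#' @param mtry candidate numbers of predictors per split; defaults to
#'   1..p at training time when NULL
#' @param maxnodes maximum terminal nodes per tree (fixed at 8)
#' @return list of class `RFSearchGrid`
#' @export
rfSearchGrid <- function(ntree = c(50L, 100L, 150L, 200L, 250L, 300L,
                                   400L, 500L),
                         mtry = NULL, maxnodes = 8L) {
  if (any(ntree < 1L) || (!is.null(mtry) && any(mtry < 1L)))
    stopDomain("grid candidates must be >= 1")
  structure(list(ntree = sort(unique(as.integer(ntree))),
                 mtry = if (is.null(mtry)) NULL else
                   sort(unique(as.integer(mtry))),
                 maxnodes = as.integer(maxnodes)),
            class = "RFSearchGrid")
}

# Train one forest deterministically for a (ntree, mtry) pair.
trainOneRF <- function(x, y, ntree, mtry, maxnodes, seed) {
  withr::with_seed(deriveSeed(seed, ntree, mtry, "rf"), {
    withCallingHandlers(
      randomForest::randomForest(x = x, y = y, ntree = ntree, mtry = mtry,
                                 maxnodes = maxnodes, importance = TRUE,
                                 keep.forest = TRUE),
      # small bootstrap samples cannot always realise 8 terminal nodes;
      # the cap still binds where it matters
      warning = function(w) {
        if (grepl("maxnodes", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  })
}

#' Grid-search a random forest by out-of-bag error
#'
#' Trains one forest per (ntree, mtry) candidate with the maximum number of
#' terminal nodes per tree fixed at 8, and selects the pair minimising the
#' out-of-bag error estimate (ties broken toward smaller ntree, then
#' smaller mtry). No validation split is consumed: evaluation of the
#' selected model uses its OOB class-probability votes for ROC-AUC and
#' confusion counts.
#'
#' @param x predictor data.frame/matrix
#' @param y factor labels (levels M1, M2)
#' @param grid an [rfSearchGrid()]
#' @param seed integer seed
#' @return an [RFModelReport-class] (split = "oob")
#' @export
trainRFOOBGrid <- function(x, y, grid = rfSearchGrid(), seed) {
  x <- as.data.frame(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L)
    stop(errorCondition("need both classes to train",
                        class = c("flimClassCoverageError", "error")))
  mtryCand <- if (is.null(grid$mtry)) seq_len(ncol(x)) else grid$mtry
  if (any(mtryCand > ncol(x)))
    stopDomain("mtry candidates cannot exceed the number of predictors")
  best <- NULL
  for (nt in grid$ntree) for (mt in mtryCand) {
    fit <- trainOneRF(x, y, nt, mt, grid$maxnodes, seed)
    oob <- unname(fit$err.rate[nt, "OOB"])
    if (is.null(best) || oob < best$oob - 1e-12) {
      best <- list(ntree = nt, mtry = mt, oob = oob, fit = fit)
    }
  }
  rfReport(best$fit, best$ntree, best$mtry, seed, split = "oob")
}

# Build an RFModelReport from a fitted forest, scoring either OOB votes or
# a holdout set.
rfReport <- function(fit, ntree, mtry, seed, split,
                     xTest = NULL, yTest = NULL) {
  imp <- randomForest::importance(fit, scale = FALSE)
  impDf <- data.frame(predictor = rownames(imp),
                      mean_decrease_accuracy = imp[, "MeanDecreaseAccuracy"],
                      mda_sd = fit$importanceSD[, "MeanDecreaseAccuracy"],
                      mean_decrease_gini = imp[, "MeanDecreaseGini"],
                      row.names = NULL)
  if (split == "oob") {
    scores <- fit$votes[, "M1"]
    labs <- fit$y
  } else {
    scores <- stats::predict(fit, xTest, type = "prob")[, "M1"]
    labs <- yTest
  }
  auc <- rocAUC(scores, labs)
  cm <- confusionCounts(scores, labs)
  new("RFModelReport", ntree = as.integer(ntree), mtry = as.integer(mtry),
      oobError = 100 * unname(fit$err.rate[fit$ntree, "OOB"]),
      rocAuc = auc, confusion = as.integer(cm) |>
        stats::setNames(names(cm)),
      importance = impDf, split = split, seed = as.integer(seed),
      model = fit)
}

#' Permutation and impurity variable importance
#'
#' Per-predictor mean decrease in accuracy (out-of-bag permutation, raw
#' scale, with its standard error over trees) and mean decrease in Gini
#' impurity for a trained model report.
#'
#' @param report an [RFModelReport-class]
#' @return data.frame ordered by decreasing mean decrease accuracy
#' @export
variableImportance <- function(report) {
  imp <- rfImportance(report)
  imp[order(-imp$mean_decrease_accuracy), , drop = FALSE]
}

#' Stratified train/test split
#'
#' Disjoint, exhaustive split preserving class proportions (within one row
#' per class), reproducible given the seed.
#'
#' @param labels factor/character class label per row
#' @param trainFraction fraction assigned to training (default 0.75)
#' @param seed integer seed
#' @return list with integer index vectors `train` and `test`
#' @export
splitTrainTest <- function(labels, trainFraction = 0.75, seed) {
  labels <- as.factor(labels)
  if (any(table(labels) < 2L))
    stop(errorCondition("every class needs >= 2 rows to stratify",
                        class = c("flimStratificationError", "error")))
  # largest-remainder allocation: the overall train count is
  # round(n * fraction) and each class is within one row of its share
  target <- round(length(labels) * trainFraction)
  sizes <- table(labels)
  shares <- as.numeric(sizes) * trainFraction
  nTrain <- pmax(1L, pmin(as.integer(sizes) - 1L, floor(shares)))
  extra <- target - sum(nTrain)
  if (extra > 0) {
    ord <- order(shares - floor(shares), decreasing = TRUE)
    for (j in ord) {
      if (extra == 0) break
      if (nTrain[j] < sizes[j] - 1L) { nTrain[j] <- nTrain[j] + 1L
                                       extra <- extra - 1L }
    }
  }
  withr::with_seed(as.integer(seed), {
    train <- integer(0)
    for (k in seq_along(levels(labels))) {
      idx <- which(labels == levels(labels)[k])
      train <- c(train, sample(idx, nTrain[k]))
    }
    list(train = sort(train),
         test = setdiff(seq_along(labels), train))
  })
}

#' Donor-specific single-cell classification models
#'
#' For each donor carrying both phenotypes: stratified 75/25 split of the
#' donor's single-cell rows, OOB grid search on the training part, and
#' ROC-AUC plus confusion counts on the held-out part. Donors missing a
#' class are skipped with a message.
#'
#' @param rows single-cell feature data.frame
#' @param grid an [rfSearchGrid()]
#' @param seed integer seed
#' @param treatment treatment condition (default "FCCP")
#' @param trainFraction training fraction (default 0.75)
#' @return named list of [RFModelReport-class], keyed by donor
#' @export
runDonorModels <- function(rows, grid = rfSearchGrid(), seed,
                           treatment = "FCCP", trainFraction = 0.75) {
  donors <- sort(unique(rows$donor))
  if (length(donors) < 2L) stopDomain("need >= 2 donors")
  reports <- list()
  for (d in donors) {
    sub <- rows[rows$donor == d, , drop = FALSE]
    tab <- tryCatch(buildFeatureTable(sub, "single_cell",
                                      treatment = treatment),
                    error = function(e) e)
    if (inherits(tab, "error")) {
      message("donor ", d, " skipped: ", conditionMessage(tab))
      next
    }
    dSeed <- deriveSeed(seed, d, "donor_model")
    sp <- splitTrainTest(tab$y, trainFraction, dSeed)
    xTr <- tab$x[sp$train, , drop = FALSE]
    yTr <- tab$y[sp$train]
    mtryCand <- if (is.null(grid$mtry)) seq_len(ncol(xTr)) else grid$mtry
    best <- NULL
    for (nt in grid$ntree) for (mt in mtryCand) {
      fit <- trainOneRF(xTr, yTr, nt, mt, grid$maxnodes, dSeed)
      oob <- unname(fit$err.rate[nt, "OOB"])
      if (is.null(best) || oob < best$oob - 1e-12)
        best <- list(ntree = nt, mtry = mt, oob = oob, fit = fit)
    }
    reports[[as.character(d)]] <-
      rfReport(best$fit, best$ntree, best$mtry, dSeed, split = "holdout",
               xTest = tab$x[sp$test, , drop = FALSE],
               yTest = tab$y[sp$test])
  }
  reports
}

#' Train a forest with fixed hyper-parameters on an external feature CSV
#'
#' Fits a random forest with given (ntree, mtry) and 8 terminal nodes to a
#' feature table in the package's CSV schema (or any table with the
#' predictor columns plus a phenotype column), reporting OOB error,
#' OOB-vote ROC-AUC and confusion counts. Intended for re-analysis of
#' published per-replicate feature tables.
#'
#' @param table data.frame or path to a CSV file
#' @param predictors predictor column names
#' @param ntree,mtry fixed hyper-parameters (defaults 100 and 2)
#' @param maxnodes maximum terminal nodes (default 8)
#' @param seed integer seed
#' @return an [RFModelReport-class]
#' @export
reproduceSourceData <- function(table,
                                predictors = c("tau_avg_ns", "tau1_ns",
                                               "tau2_ns", "alpha2", "orr"),
                                ntree = 100L, mtry = 2L, maxnodes = 8L,
                                seed = 1L) {
  if (is.character(table)) table <- utils::read.csv(table)
  miss <- setdiff(c(predictors, "phenotype"), names(table))
  if (length(miss))
    stopDomain("table lacks column(s): %s", paste(miss, collapse = ", "))
  x <- table[, predictors, drop = FALSE]
  y <- factor(table$phenotype, levels = c("M1", "M2"))
  fit <- trainOneRF(x, y, as.integer(ntree), as.integer(mtry),
                    as.integer(maxnodes), as.integer(seed))
  rfReport(fit, ntree, mtry, seed, split = "oob")
}
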