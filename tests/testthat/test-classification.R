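test_that("the feature table drops alpha1 and enforces class coverage", {
  rows <- mkRows(36, seed = 81)
  tab <- buildFeatureTable(rows, "full_fov")
  expect_false("alpha1" %in% colnames(tab$x))
  expect_setequal(colnames(tab$x),
                  c("tau_avg_ns", "tau1_ns", "tau2_ns", "alpha2", "orr"))
  expect_equal(nrow(tab$x), 36L)
  tabAll <- buildFeatureTable(rows, "full_fov", dropCollinear = FALSE)
  expect_true("alpha1" %in% colnames(tabAll$x))
  only1 <- rows[rows$phenotype == "M1", ]
  expect_error(buildFeatureTable(only1, "full_fov"),
               class = "flimClassCoverageError")
  # gated rows are excluded
  rows$good[1:4] <- FALSE
  expect_equal(nrow(buildFeatureTable(rows, "full_fov")$x), 32L)
})

test_that("z-scores use the population SD and guard degeneracies", {
  x <- cbind(a = c(1, 3), b = c(2, 2))
  expect_warning(z <- zscoreMatrix(x), "zero-variance")
  expect_equal(unname(z[, "a"]), c(-1, 1))
  expect_equal(unname(z[, "b"]), c(0, 0))
  withr::with_seed(82, {
    m <- matrix(rnorm(200), 40, 5)
    z2 <- zscoreMatrix(m)
    expect_equal(unname(colMeans(z2)), rep(0, 5), tolerance = 1e-12)
    popSd <- sqrt(colMeans(sweep(z2, 2, colMeans(z2))^2))
    expect_equal(unname(popSd), rep(1, 5), tolerance = 1e-12)
  })
  expect_error(zscoreMatrix(matrix(1, 1, 3)), class = "flimDomainError")
})

test_that("rocAUC reproduces closed cases and the brute-force oracle", {
  expect_equal(rocAUC(c(0.9, 0.8, 0.2, 0.1), c("M1", "M1", "M2", "M2")), 1)
  expect_equal(rocAUC(c(0.1, 0.2, 0.8, 0.9), c("M1", "M1", "M2", "M2")), 0)
  expect_equal(rocAUC(c(0.9, 0.4, 0.8, 0.2), c("M1", "M1", "M2", "M2")),
               0.75)
  withr::with_seed(83, {
    for (k in 1:25) {
      n <- sample(4:50, 1)
      labels <- c("M1", "M2", sample(c("M1", "M2"), n - 2, replace = TRUE))
      scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
      expect_identical(rocAUC(scores, labels),
                       oracleAUC(scores, labels))
    }
  })
  expect_error(rocAUC(c(0.5, 0.6), c("M1", "M1")),
               class = "flimDomainError")
})

test_that("rocAUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(84, {
    labels <- sample(c("M1", "M2"), 60, replace = TRUE, prob = c(0.4, 0.6))
    scores <- rnorm(60) + (labels == "M1")
    ref <- as.numeric(suppressMessages(
      pROC::auc(pROC::roc(labels, scores, levels = c("M2", "M1"),
                          direction = "<"))))
    expect_equal(rocAUC(scores, labels), ref, tolerance = 1e-12)
  })
})

test_that("confusion counts conserve rows and resolve ties upward", {
  labels <- c("M1", "M1", "M2", "M2")
  cm <- confusionCounts(c(0.9, 0.8, 0.2, 0.1), labels)
  expect_equal(unname(cm), c(2L, 0L, 0L, 2L))
  tied <- confusionCounts(rep(0.5, 4), labels)
  expect_equal(unname(tied["TP"]), 2L)  # >= threshold counts positive
  expect_equal(unname(tied["FP"]), 2L)
  withr::with_seed(85, {
    sc <- runif(40); lb <- sample(c("M1", "M2"), 40, replace = TRUE)
    cm2 <- confusionCounts(sc, lb, threshold = 0.35)
    brute <- c(TP = sum(sc >= 0.35 & lb == "M1"),
               FP = sum(sc >= 0.35 & lb == "M2"),
               FN = sum(sc < 0.35 & lb == "M1"),
               TN = sum(sc < 0.35 & lb == "M2"))
    expect_equal(cm2, brute)
    expect_equal(sum(cm2), 40L)
  })
})

test_that("stratified splits are disjoint, exhaustive and reproducible", {
  labels <- rep(c("M1", "M2"), each = 50)
  sp <- splitTrainTest(labels, seed = 86)
  expect_length(sp$train, 75L)
  expect_length(sp$test, 25L)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_lte(abs(sum(labels[sp$train] == "M1") -
                 sum(labels[sp$train] == "M2")), 1)
  sp2 <- splitTrainTest(labels, seed = 86)
  expect_identical(sp, sp2)
  expect_error(splitTrainTest(c("M1", "M2", "M2"), seed = 1),
               class = "flimStratificationError")
})

test_that("the OOB grid search separates constructed Gaussian classes", {
  sep <- makeGaussianFeatures(36, sep = 5, seed = 87)
  rep1 <- trainRFOOBGrid(sep$x, sep$y, rfSearchGrid(ntree = c(50L, 100L)),
                         seed = 87)
  expect_lte(oobError(rep1), 5)
  expect_true(rep1@ntree %in% c(50L, 100L))
  expect_true(rep1@mtry %in% seq_len(ncol(sep$x)))
  expect_equal(sum(confusion(rep1)), 36L)
  expect_error(trainRFOOBGrid(sep$x, factor(rep("M1", 36),
                                            levels = c("M1", "M2"))[1:36],
                              seed = 1),
               class = "flimClassCoverageError")
})

test_that("permuted labels give chance-level OOB error", {
  withr::with_seed(88, {
    x <- as.data.frame(matrix(rnorm(200 * 5), 200, 5))
    y <- factor(sample(rep(c("M1", "M2"), 100)), levels = c("M1", "M2"))
  })
  repNull <- trainRFOOBGrid(x, y, rfSearchGrid(ntree = 100L, mtry = 2L),
                            seed = 88)
  expect_lt(abs(oobError(repNull) - 50), 15)
})

test_that("grid search is deterministic given the seed", {
  d <- makeGaussianFeatures(40, sep = 2, seed = 89)
  r1 <- trainRFOOBGrid(d$x, d$y, rfSearchGrid(ntree = c(50L, 100L)),
                       seed = 90)
  r2 <- trainRFOOBGrid(d$x, d$y, rfSearchGrid(ntree = c(50L, 100L)),
                       seed = 90)
  expect_identical(oobError(r1), oobError(r2))
  expect_identical(rocAuc(r1), rocAuc(r2))
  expect_identical(c(r1@ntree, r1@mtry), c(r2@ntree, r2@mtry))
})

test_that("variable importance isolates an informative predictor", {
  withr::with_seed(91, {
    n <- 150
    y <- factor(rep(c("M1", "M2"), length.out = n), levels = c("M1", "M2"))
    x <- data.frame(signal = rnorm(n) + 3 * (y == "M2"),
                    noise1 = rnorm(n), noise2 = rnorm(n),
                    noise3 = rnorm(n))
  })
  rep1 <- trainRFOOBGrid(x, y, rfSearchGrid(ntree = 200L, mtry = 2L),
                         seed = 91)
  vi <- variableImportance(rep1)
  expect_equal(vi$predictor[1], "signal")
  gini <- vi[order(-vi$mean_decrease_gini), "predictor"]
  expect_equal(gini[1], "signal")
  # pure-noise predictors have permutation importance near zero
  noiseRows <- vi[vi$predictor != "signal", ]
  expect_true(all(abs(noiseRows$mean_decrease_accuracy) <
                  3 * pmax(noiseRows$mda_sd, 1e-6)))
  expect_setequal(vi$predictor, colnames(x))
})

test_that("UMAP embeddings are seeded, cluster-preserving and local", {
  d <- makeGaussianFeatures(60, sep = 8, seed = 92)
  e1 <- umapEmbed(d$x, seed = 92, nNeighbors = 10)
  e2 <- umapEmbed(d$x, seed = 92, nNeighbors = 10)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(60L, 2L))
  expect_gt(oracleSilhouette(e1, d$y), 0.5)
  # a duplicated row embeds next to its twin
  xdup <- rbind(d$x, d$x[1, ])
  ed <- umapEmbed(xdup, seed = 93, nNeighbors = 10)
  dupDist <- sqrt(sum((ed[61, ] - ed[1, ])^2))
  spread <- stats::median(as.matrix(stats::dist(ed))[upper.tri(diag(61))])
  expect_lt(dupDist, 0.2 * spread)
  expect_error(umapEmbed(d$x[1:3, ], seed = 1), class = "flimDomainError")
})

test_that("donor-specific models report complete schemas and effect ordering", {
  rows <- rbind(mkRows(120, seed = 94, donor = 1),
                mkRows(120, seed = 95, donor = 2))
  # donor 2 overlaps: shrink its separation by shuffling phenotype labels
  withr::with_seed(96, {
    flip <- sample(which(rows$donor == 2), 60)
    rows$phenotype[flip] <- sample(rows$phenotype[flip])
  })
  reps <- runDonorModels(rows, rfSearchGrid(ntree = c(50L, 100L)),
                         seed = 97)
  expect_length(reps, 2L)
  for (r in reps) {
    expect_s4_class(r, "RFModelReport")
    expect_true(r@ntree %in% c(50L, 100L))
    expect_gte(rocAuc(r), 0)
    expect_equal(r@split, "holdout")
    expect_equal(nrow(rfImportance(r)), 5L)
  }
  expect_gte(rocAuc(reps[["1"]]), 0.9)
  expect_gt(rocAuc(reps[["1"]]), rocAuc(reps[["2"]]))
  # a donor missing a class is skipped with a message
  rows3 <- rbind(rows, transform(mkRows(20, seed = 98, donor = 3),
                                 phenotype = "M1"))
  expect_message(reps3 <- runDonorModels(rows3,
                                         rfSearchGrid(ntree = 50L),
                                         seed = 99),
                 "skipped")
  expect_length(reps3, 2L)
})
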