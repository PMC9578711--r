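test_that("photon masks behave on uniform, empty and bimodal images", {
  uni <- matrix(50, 16, 16)
  expect_true(all(photonMask(uni, "absolute", threshold = 10)))
  expect_false(any(photonMask(matrix(0, 16, 16), "absolute", threshold = 1)))
  expect_error(photonMask(uni), class = "flimDegenerateThresholdError")
  expect_error(photonMask(matrix(-1, 4, 4)), class = "flimDomainError")

  # bimodal synthetic field: automatic mask recovers cell pixels
  cfg <- tinyCohort(seed = 71, cellsPerField = 5L)
  st <- simulateField(cfg, 1, "M1", "FCCP", 1)
  total <- apply(st@nadh, c(1, 2), sum)
  mask <- photonMask(total)
  truthPix <- st@labels > 0
  expect_gte(sum(mask & truthPix) / sum(truthPix), 0.99)
})

test_that("well-separated disks are segmented with accurate centroids", {
  cfg <- tinyCohort(seed = 72, cellsPerField = 5L)
  st <- simulateField(cfg, 1, "M1", "FCCP", 1)
  lm <- segmentCells(apply(st@nadh, c(1, 2), sum))
  expect_equal(nCells(lm), 5L)
  cen <- centroids(lm)
  for (i in seq_len(nrow(st@truth))) {
    d <- sqrt((cen[, 1] - st@truth$y[i])^2 + (cen[, 2] - st@truth$x[i])^2)
    expect_lte(min(d), 1)
  }
})

test_that("blank images and sub-minimum components give empty maps", {
  expect_message(lm <- segmentCells(matrix(0, 64, 64), method = "absolute",
                                    threshold = 1),
                 "no cells")
  expect_equal(nCells(lm), 0L)
  img <- matrix(0, 64, 64); img[30:31, 30:31] <- 100  # 4 px < minArea
  lm2 <- suppressMessages(segmentCells(img, sigma = 0, method = "absolute",
                                       threshold = 50, minArea = 20L))
  expect_equal(nCells(lm2), 0L)
})

test_that("segmentation on default synthetic fields is near-exhaustive", {
  cfg <- cohortConfig(seed = 73, nDonors = 1L, treatments = "FCCP",
                      fieldsPerCondition = 1L, photonsPerCell = 4000)
  tp <- 0; found <- 0; truthN <- 0
  for (ph in c("M1", "M2")) {
    st <- simulateField(cfg, 1, ph, "FCCP", 1)
    lm <- segmentCells(apply(st@nadh, c(1, 2), sum))
    truthN <- truthN + nrow(st@truth)
    found <- found + nCells(lm)
    cen <- centroids(lm)
    for (i in seq_len(nCells(lm))) {
      d <- sqrt((st@truth$y - cen[i, 1])^2 + (st@truth$x - cen[i, 2])^2)
      if (min(d) <= 2) tp <- tp + 1
    }
  }
  expect_gte(tp / truthN, 0.95)  # recall
  expect_gte(tp / found, 0.95)   # precision
})

test_that("pixel partition and mask-mean aggregation are consistent", {
  cfg <- tinyCohort(seed = 74, cellsPerField = 4L)
  st <- simulateField(cfg, 1, "M2", "FCCP", 1)
  lm <- segmentCells(apply(st@nadh, c(1, 2), sum))
  expect_lte(sum(cellAreas(lm)), length(lm@labels))
  expect_equal(sort(unique(as.vector(lm@labels[lm@labels > 0]))),
               seq_len(nCells(lm)))
  # brute-force mask mean equals the aggregation the features use
  total <- apply(st@nadh, c(1, 2), sum)
  i <- 1L
  sel <- lm@labels == i
  expect_equal(mean(total[sel]),
               sum(total * sel) / sum(sel), tolerance = 1e-12)
})

test_that("per-cell features carry truth values and identifiers", {
  cfg <- tinyCohort(seed = 75, cellsPerField = 3L, photonsPerCell = 40000)
  st <- simulateField(cfg, 2, "M2", "FCCP", 1)
  lm <- segmentCells(apply(st@nadh, c(1, 2), sum))
  feats <- aggregateCellFeatures(lm, st)
  expect_equal(nrow(feats), 3L)
  expect_equal(length(unique(feats$cell_id)), 3L)
  expect_true(all(feats$donor == 2 & feats$phenotype == "M2"))
  # match each feature row to the nearest truth cell and compare
  cen <- centroids(lm)
  for (r in seq_len(nrow(feats))) {
    i <- which.min((st@truth$y - cen[r, 1])^2 + (st@truth$x - cen[r, 2])^2)
    expect_lt(abs(feats$tau1_ns[r] - st@truth$tau1[i]) / st@truth$tau1[i],
              0.10)
    expect_lt(abs(feats$orr[r] - st@truth$orr[i]), 0.15)
  }
})

test_that("ORR is 1 when FAD+ equals NAD(P)H everywhere", {
  cfg <- tinyCohort(seed = 76, cellsPerField = 2L)
  st <- simulateField(cfg, 1, "M1", "FCCP", 1)
  total <- apply(st@nadh, c(1, 2), sum)
  st@fad <- total                       # force identical intensities
  fits <- fitField(st, "per_cell")
  expect_true(all(abs(fits$orr - 1) < 1e-12))
})

test_that("greedy centroid matching tracks cells across treatments", {
  mkMap <- function(shift = 0, drop = NULL) {
    lab <- matrix(0L, 64, 64)
    cen <- rbind(c(15, 15), c(15, 45), c(45, 30))
    keep <- setdiff(1:3, drop)
    k <- 0L
    for (i in keep) {
      k <- k + 1L
      yy <- row(lab); xx <- col(lab)
      lab[(yy - cen[i, 1] - shift)^2 + (xx - cen[i, 2] - shift)^2 <= 16] <- k
    }
    segmentCells(1000 * (lab > 0), sigma = 0, method = "absolute",
                 threshold = 1, minArea = 5L, clearBorder = FALSE)
  }
  ident <- matchCellsAcrossTreatments(list(mkMap(), mkMap()))
  expect_true(all(ident$status == "complete"))
  expect_equal(ident$map1, ident$map2)

  shifted <- matchCellsAcrossTreatments(list(mkMap(), mkMap(shift = 1)))
  expect_true(all(shifted$status == "complete"))

  lost <- matchCellsAcrossTreatments(list(mkMap(), mkMap(drop = 3)))
  expect_equal(sum(lost$status == "partial"), 1L)
  expect_equal(sum(lost$status == "complete"), 2L)
  expect_error(matchCellsAcrossTreatments(list()), class = "flimDomainError")
})
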