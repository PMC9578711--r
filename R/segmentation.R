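#' Segment cells from a total-intensity image
#'
#' Gaussian smoothing, automatic (Otsu on log1p counts) or absolute
#' thresholding, connected-component labelling, then removal of components
#' below the minimum area and, optionally, components touching the image
#' border (partial cells bias lifetime aggregates). Labels are relabelled
#' consecutively 1..nCells. Finding no cells is not an error: an empty
#' [LabelMap-class] is returned with a message.
#'
#' @param intensityImage non-negative matrix (e.g. summed NAD(P)H counts)
#' @param sigma Gaussian smoothing SD in pixels (default 1; 0 disables)
#' @param method "otsu" or "absolute" thresholding (see [photonMask()])
#' @param threshold absolute threshold when `method = "absolute"`
#' @param minArea minimum component area in pixels (default 20)
#' @param clearBorder drop components touching the border (default TRUE)
#' @param watershed split touching objects by distance-transform watershed
#'   (default FALSE; synthetic cells do not touch)
#' @return a [LabelMap-class]
#' @export
segmentCells <- function(intensityImage, sigma = 1, method = c("otsu", "absolute"),
                         threshold = NULL, minArea = 20L,
                         clearBorder = TRUE, watershed = FALSE) {
  method <- match.arg(method)
  if (any(intensityImage < 0))
    stopDomain("intensity image must be non-negative")
  img <- intensityImage
  if (sigma > 0)
    img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = sigma))
  mask <- photonMask(img, method = method, threshold = threshold)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  if (watershed)
    lab <- EBImage::watershed(EBImage::distmap(EBImage::Image(mask * 1)))
  lab <- as.matrix(lab)

  keep <- seq_len(max(lab))
  if (length(keep)) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(areas >= minArea)
    if (clearBorder) {
      border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
      keep <- setdiff(keep, border)
    }
  }
  relab <- integer(max(lab, 1L))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  out[nz] <- relab[lab[nz]]

  n <- length(keep)
  if (n == 0L) {
    message("segmentCells: no cells found")
    return(new("LabelMap", labels = out, nCells = 0L,
               centroids = matrix(numeric(0), 0, 2), areas = integer(0)))
  }
  areas <- tabulate(out[out > 0], nbins = n)
  yy <- row(out); xx <- col(out)
  cy <- as.numeric(tapply(yy[out > 0], out[out > 0], mean))
  cx <- as.numeric(tapply(xx[out > 0], out[out > 0], mean))
  new("LabelMap", labels = out, nCells = as.integer(n),
      centroids = cbind(y = cy, x = cx), areas = as.integer(areas))
}

#' Aggregate per-cell FLIM and redox features
#'
#' One row per segmented cell carrying the cell's aggregate-decay fit
#' (tau1, tau2, alpha1, alpha2, tau_avg), the per-cell optical redox ratio
#' (mean FAD+ intensity over the mask divided by mean NAD(P)H intensity),
#' and the (donor, phenotype, treatment, field, cell) identifiers. Cells
#' whose fit fails are emitted with `failed = TRUE` and excluded
#' downstream.
#'
#' @param labelMap a [LabelMap-class] from [segmentCells()]
#' @param field the corresponding [FieldStack-class]
#' @param fits optional per-cell fit table from
#'   `fitField(field, "per_cell", labels = labelMap@labels)`; computed when
#'   missing
#' @param options a [fitOptions()] list used when `fits` is missing
#' @return data.frame with identifier and feature columns (schema of the
#'   feature-table CSV)
#' @export
aggregateCellFeatures <- function(labelMap, field, fits = NULL,
                                  options = fitOptions()) {
  if (is.null(fits))
    fits <- fitField(field, "per_cell", labels = labelMap@labels,
                     options = options)
  if (nrow(fits) > 0 &&
      !all(fits$unit_id %in% seq_len(labelMap@nCells)))
    stopDomain("fit table labels are inconsistent with the label map")
  cc <- field@condition
  cbind(data.frame(donor = cc$donor, phenotype = cc$phenotype,
                   treatment = cc$treatment, field_id = cc$field,
                   cell_id = fits$unit_id),
        fits[, setdiff(names(fits), "unit_id"), drop = FALSE],
        row.names = NULL)
}

#' Match cells across an ordered treatment sequence
#'
#' Greedy nearest-centroid matching (ascending distance) between
#' consecutive label maps of the same maintained field of view, with a
#' maximum displacement radius. Cells without a partner are flagged as
#' lost/appearing.
#'
#' @param maps ordered list of [LabelMap-class] objects, one per treatment
#' @param maxDisplacement maximum centroid displacement in pixels
#'   (default 10)
#' @return data.frame with one row per track: track_id, one `map<k>`
#'   label column per input map (NA where unmatched), and `status`
#'   ("complete" or "partial")
#' @export
matchCellsAcrossTreatments <- function(maps, maxDisplacement = 10) {
  if (length(maps) == 0L) stopDomain("empty map list")
  tracks <- data.frame(track_id = seq_len(nCells(maps[[1]])))
  tracks$map1 <- tracks$track_id
  cent <- centroids(maps[[1]])
  for (k in seq_along(maps)[-1]) {
    cur <- centroids(maps[[k]])
    prevLab <- tracks[[paste0("map", k - 1L)]]
    matched <- rep(NA_integer_, nrow(tracks))
    if (nrow(cur) > 0 && any(!is.na(prevLab))) {
      live <- which(!is.na(prevLab))
      d <- outer(seq_along(live), seq_len(nrow(cur)),
                 Vectorize(function(i, j)
                   sqrt(sum((cent[live[i], ] - cur[j, ])^2))))
      usedT <- logical(length(live)); usedC <- logical(nrow(cur))
      ord <- order(d)
      for (o in ord) {
        if (d[o] > maxDisplacement) break
        i <- (o - 1L) %% length(live) + 1L
        j <- (o - 1L) %/% length(live) + 1L
        if (!usedT[i] && !usedC[j]) {
          matched[live[i]] <- j
          usedT[i] <- TRUE; usedC[j] <- TRUE
          cent[live[i], ] <- cur[j, ]
        }
      }
      newcells <- which(!usedC)
    } else newcells <- seq_len(nrow(cur))
    tracks[[paste0("map", k)]] <- matched
    if (length(newcells)) {
      add <- data.frame(track_id = max(tracks$track_id, 0L) + seq_along(newcells))
      for (kk in seq_len(k - 1L)) add[[paste0("map", kk)]] <- NA_integer_
      add[[paste0("map", k)]] <- newcells
      cent <- rbind(cent, cur[newcells, , drop = FALSE])
      tracks <- rbind(tracks, add)
    }
  }
  mapCols <- grep("^map", names(tracks))
  tracks$status <- ifelse(rowSums(is.na(tracks[, mapCols, drop = FALSE])) == 0,
                          "complete", "partial")
  tracks
}
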