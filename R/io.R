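#' Write a field stack to disk
#'
#' Serialises one [FieldStack-class] as a multi-page 16-bit TIFF (one page
#' per time bin) for the NAD(P)H histograms, a single-page 16-bit TIFF for
#' the FAD+ image, a 16-bit TIFF for the ground-truth label map, and a
#' JSON sidecar carrying the condition, bin width and per-cell truth.
#'
#' @param stack a [FieldStack-class]
#' @param prefix output path prefix; files `<prefix>_nadh.tif`,
#'   `<prefix>_fad.tif`, `<prefix>_labels.tif`, `<prefix>.json` are written
#' @return invisibly, the vector of written paths
#' @export
writeFieldStack <- function(stack, prefix) {
  validObject(stack)
  d <- dim(stack@nadh)
  scale <- 65535
  if (max(stack@nadh) > scale || max(stack@fad) > scale)
    stopDomain("counts exceed the 16-bit TIFF range")
  pages <- lapply(seq_len(d[3]), function(b) stack@nadh[, , b] / scale)
  paths <- paste0(prefix, c("_nadh.tif", "_fad.tif", "_labels.tif", ".json"))
  tiff::writeTIFF(pages, paths[1], bits.per.sample = 16L)
  tiff::writeTIFF(stack@fad / scale, paths[2], bits.per.sample = 16L)
  tiff::writeTIFF(stack@labels / scale, paths[3], bits.per.sample = 16L)
  jsonlite::write_json(
    list(condition = stack@condition, binWidth = stack@binWidth,
         truth = stack@truth),
    paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a field stack written by [writeFieldStack()]
#'
#' @param prefix the path prefix used at write time
#' @return a [FieldStack-class]
#' @export
readFieldStack <- function(prefix) {
  scale <- 65535
  pages <- tiff::readTIFF(paste0(prefix, "_nadh.tif"), all = TRUE)
  nadh <- array(0, c(dim(pages[[1]]), length(pages)))
  for (b in seq_along(pages)) nadh[, , b] <- round(pages[[b]] * scale)
  fad <- round(tiff::readTIFF(paste0(prefix, "_fad.tif")) * scale)
  labels <- round(tiff::readTIFF(paste0(prefix, "_labels.tif")) * scale)
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  new("FieldStack", nadh = nadh, fad = fad,
      labels = matrix(as.integer(labels), nrow(labels), ncol(labels)),
      truth = as.data.frame(side$truth), condition = as.list(side$condition),
      binWidth = side$binWidth)
}

#' Write / read the feature-table CSV
#'
#' Plain CSV in the schema (donor, phenotype, treatment, field_id,
#' cell_id, tau1_ns, tau2_ns, alpha1, alpha2, tau_avg_ns, orr, chi2_nu,
#' n_photons, good, failed, reason).
#'
#' @param rows feature data.frame
#' @param path output path
#' @return `writeFeatureTable` invisibly returns the path;
#'   `readFeatureTable` returns the data.frame
#' @export
writeFeatureTable <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
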