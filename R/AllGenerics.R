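#' @rdname DecayHistogram-class
#' @param object a package object
#' @export
setGeneric("photonCounts", function(object) standardGeneric("photonCounts"))

#' @rdname DecayHistogram-class
#' @export
setGeneric("binWidth", function(object) standardGeneric("binWidth"))

#' @rdname DecayHistogram-class
#' @export
setGeneric("totalPhotons", function(object) standardGeneric("totalPhotons"))

#' @rdname DecayHistogram-class
#' @export
setGeneric("t0Bin", function(object) standardGeneric("t0Bin"))

#' @rdname BiExpFit-class
#' @export
setGeneric("tauAvg", function(object) standardGeneric("tauAvg"))

#' @rdname BiExpFit-class
#' @export
setGeneric("goodFit", function(object) standardGeneric("goodFit"))

#' @rdname BiExpFit-class
#' @export
setGeneric("fitParams", function(object) standardGeneric("fitParams"))

#' @rdname RFModelReport-class
#' @export
setGeneric("oobError", function(object) standardGeneric("oobError"))

#' @rdname RFModelReport-class
#' @export
setGeneric("rocAuc", function(object) standardGeneric("rocAuc"))

#' @rdname RFModelReport-class
#' @export
setGeneric("confusion", function(object) standardGeneric("confusion"))

#' @rdname RFModelReport-class
#' @export
setGeneric("rfImportance", function(object) standardGeneric("rfImportance"))

#' @rdname LabelMap-class
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))

#' @rdname LabelMap-class
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))

#' @rdname LabelMap-class
#' @export
setGeneric("cellAreas", function(object) standardGeneric("cellAreas"))
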