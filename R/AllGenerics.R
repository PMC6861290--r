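#' @importFrom SummarizedExperiment assay rowData colData assayNames
#' @importFrom S4Vectors metadata DataFrame
NULL

#' Access the count matrix
#'
#' @param x a \linkS4class{MicrobiomeExperiment}.
#' @return numeric matrix of counts, features x samples.
#' @export
setGeneric("countMatrix", function(x) standardGeneric("countMatrix"))

#' @rdname countMatrix
#' @export
setMethod("countMatrix", "MicrobiomeExperiment", function(x)
    SummarizedExperiment::assay(x, "counts"))

#' Access the taxonomy table
#'
#' @param x a \linkS4class{MicrobiomeExperiment}.
#' @return data.frame of rank assignments (only the rank columns present in
#'   \code{rowData}), or NULL when none are stored.
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))

#' @rdname taxonomy
#' @export
setMethod("taxonomy", "MicrobiomeExperiment", function(x) {
    rd <- as.data.frame(SummarizedExperiment::rowData(x))
    keep <- intersect(TAXONOMY_RANKS, colnames(rd))
    if (!length(keep)) return(NULL)
    rd[, keep, drop = FALSE]
})

#' Resolution of the feature axis
#'
#' @param x a \linkS4class{MicrobiomeExperiment}.
#' @return character scalar, e.g. "SV" or "Genus".
#' @export
setGeneric("axisRank", function(x) standardGeneric("axisRank"))

#' @rdname axisRank
#' @export
setMethod("axisRank", "MicrobiomeExperiment", function(x)
    S4Vectors::metadata(x)$axis_rank)

#' Kingdom assignment of each feature
#'
#' @param x a \linkS4class{MicrobiomeExperiment} or
#'   \linkS4class{CooccurrenceResult}.
#' @return named character vector of kingdoms, or NULL when absent.
#' @export
setGeneric("kingdomMap", function(x) standardGeneric("kingdomMap"))

#' @rdname kingdomMap
#' @export
setMethod("kingdomMap", "MicrobiomeExperiment", function(x) {
    k <- SummarizedExperiment::rowData(x)$kingdom
    if (is.null(k)) return(NULL)
    setNames(as.character(k), rownames(x))
})

#' @rdname kingdomMap
#' @export
setMethod("kingdomMap", "CooccurrenceResult", function(x) x@kingdom)

#' Filter / processing report attached to an object
#'
#' Stages that drop features or samples (filtering, rarefaction) attach a
#' small report describing what was removed; this accessor retrieves it.
#'
#' @param x a \linkS4class{MicrobiomeExperiment}.
#' @return a data.frame (or list) report, or NULL.
#' @export
setGeneric("processingReport", function(x) standardGeneric("processingReport"))

#' @rdname processingReport
#' @export
setMethod("processingReport", "MicrobiomeExperiment", function(x)
    S4Vectors::metadata(x)$report)
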