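#' Read / write feature count tables as TSV
#'
#' Count tables are stored features-as-rows, samples-as-columns, with the
#' first column holding the feature id.
#'
#' @param x a \linkS4class{MicrobiomeExperiment} or count matrix.
#' @param path file path.
#' @return \code{readCountTable} returns a numeric matrix (wrap with
#'   \code{\link{MicrobiomeExperiment}} to attach taxonomy/metadata).
#' @export
writeCountTable <- function(x, path) {
    m <- if (methods::is(x, "MicrobiomeExperiment")) countMatrix(x) else
        as.matrix(x)
    df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeCountTable
#' @export
readCountTable <- function(path) {
    df <- read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
}

#' Read / write taxonomy tables as 7-column TSV
#'
#' @param tax a taxonomy data.frame (rownames = feature ids) or a
#'   \linkS4class{MicrobiomeExperiment}.
#' @param path file path.
#' @return \code{readTaxonomyTable} returns a data.frame with rank
#'   columns.
#' @export
writeTaxonomyTable <- function(tax, path) {
    if (methods::is(tax, "MicrobiomeExperiment")) tax <- taxonomy(tax)
    df <- data.frame(feature_id = rownames(tax), tax, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "")
    invisible(path)
}

#' @rdname writeCountTable
#' @export
readTaxonomyTable <- function(path) {
    df <- read.delim(path, check.names = FALSE,
                     colClasses = "character")
    rownames(df) <- df[[1]]
    df[, -1, drop = FALSE]
}

#' Write sample metadata as TSV
#'
#' Columns: sample_id, variety, cropping, group, sample_type.
#'
#' @param meta metadata data.frame.
#' @param path file path.
#' @export
writeSampleMetadata <- function(meta, path) {
    write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeSampleMetadata
#' @export
readSampleMetadata <- function(path) read.delim(path)
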