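#' @import methods
#' @importFrom stats cor dist pt rnorm rpois runif rhyper rgamma rmultinom
#'   cmdscale sd setNames aggregate quantile
#' @importFrom utils read.delim write.table combn head
NULL

TAXONOMY_RANKS <- c("Kingdom", "Phylum", "Class", "Order", "Family",
                    "Genus", "Species")

#' MicrobiomeExperiment: a feature-by-sample count container
#'
#' A thin \linkS4class{SummarizedExperiment} subclass holding a non-negative
#' integer count matrix (assay \code{"counts"}) of amplicon features
#' (sequence variants, genera, ...) by samples, with per-feature taxonomy
#' and attributes in \code{rowData} and sample metadata in \code{colData}.
#' The taxonomic resolution of the feature axis is recorded in
#' \code{metadata(x)$axis_rank}.
#'
#' @slot ... see \linkS4class{SummarizedExperiment}.
#' @aliases MicrobiomeExperiment-class
#' @exportClass MicrobiomeExperiment
setClass("MicrobiomeExperiment", contains = "SummarizedExperiment")

setValidity("MicrobiomeExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- SummarizedExperiment::assay(object, "counts")
        if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
        if (any(m != round(m))) msg <- c(msg, "counts must be integers")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate feature ids")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample ids")
    if (length(msg)) msg else TRUE
})

#' Construct a MicrobiomeExperiment
#'
#' @param counts non-negative integer matrix, features x samples, with
#'   dimnames.
#' @param taxonomy optional data.frame of rank assignments (columns from
#'   Kingdom to Species), one row per feature. Missing assignments are
#'   \code{NA}.
#' @param metadata optional data.frame of sample metadata, one row per
#'   sample (columns such as \code{variety}, \code{cropping}, \code{group},
#'   \code{sample_type}).
#' @param attributes optional data.frame of per-feature attributes
#'   (\code{length} in bp, logical \code{control}).
#' @param rank label for the feature axis resolution, e.g. \code{"SV"} or
#'   \code{"Genus"}.
#' @param kingdom optional single kingdom label, or per-feature vector,
#'   stored in \code{rowData(x)$kingdom}.
#' @return a \linkS4class{MicrobiomeExperiment}.
#' @examples
#' m <- matrix(rpois(12, 5), 3, 4,
#'             dimnames = list(paste0("sv", 1:3), paste0("s", 1:4)))
#' me <- MicrobiomeExperiment(m, rank = "SV")
#' axisRank(me)
#' @export
MicrobiomeExperiment <- function(counts, taxonomy = NULL, metadata = NULL,
                                 attributes = NULL, rank = "SV",
                                 kingdom = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("f", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("s", seq_len(ncol(counts)))
    rd <- S4Vectors::DataFrame(row.names = rownames(counts))
    if (!is.null(taxonomy)) {
        taxonomy <- as.data.frame(taxonomy)
        stopifnot(nrow(taxonomy) == nrow(counts))
        for (cn in colnames(taxonomy)) rd[[cn]] <- as.character(taxonomy[[cn]])
    }
    if (!is.null(attributes)) {
        attributes <- as.data.frame(attributes)
        stopifnot(nrow(attributes) == nrow(counts))
        for (cn in colnames(attributes)) rd[[cn]] <- attributes[[cn]]
    }
    if (!is.null(kingdom))
        rd$kingdom <- rep_len(as.character(kingdom), nrow(counts))
    cd <- S4Vectors::DataFrame(row.names = colnames(counts))
    if (!is.null(metadata)) {
        metadata <- as.data.frame(metadata)
        if (!is.null(metadata$sample_id))
            rownames(metadata) <- metadata$sample_id
        metadata <- metadata[colnames(counts), , drop = FALSE]
        for (cn in setdiff(colnames(metadata), "sample_id"))
            cd[[cn]] <- metadata[[cn]]
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), rowData = rd, colData = cd,
        metadata = list(axis_rank = rank))
    methods::new("MicrobiomeExperiment", se)
}

#' SyntheticScenario: parameterization of the synthetic experiment
#'
#' Full description of the generative model for a paired bacterial/fungal
#' mixed-cropping experiment: group sizes, per-kingdom genus counts,
#' baseline log-abundance distribution, variety effects, mixing
#' coefficients, planted correlation blocks, sequencing depth ranges, and
#' SV-level expansion parameters. See \code{\link{defaultScenario}} for the
#' default study design.
#'
#' @slot nSamples named integer vector of samples per treatment group
#'   (names \code{mono_A}, \code{mixed_A}, \code{mixed_W}, \code{mono_W}).
#' @slot nSoil number of start-of-experiment soil samples.
#' @slot nGenera named integer vector \code{c(bacteria=, fungi=)}.
#' @slot baseLog numeric \code{c(mean=, sd=)} of genus baseline
#'   log-abundances.
#' @slot varietyEffectSd sd of per-genus variety offsets.
#' @slot noiseSd sd of per-sample latent noise.
#' @slot mixing list \code{bacteria}/\code{fungi}, each \code{c(A=, W=)}:
#'   the fraction of the other variety's centroid blended in under
#'   mixed-cropping.
#' @slot plantedBlocks list of blocks, each
#'   \code{list(members=, r=, groups=)}.
#' @slot depthRange list \code{bacteria}/\code{fungi}, each
#'   \code{c(min, max)} reads per sample.
#' @slot svExpansion list of SV-expansion parameters (\code{meanSV},
#'   \code{lengthMode}, \code{lengthSd}, \code{outlierFrac},
#'   \code{outlierRange}, \code{contaminants}, \code{rareFrac}).
#' @slot seed integer master seed.
#' @aliases SyntheticScenario-class
#' @exportClass SyntheticScenario
setClass("SyntheticScenario",
    representation(nSamples = "integer", nSoil = "integer",
                   nGenera = "integer", baseLog = "numeric",
                   varietyEffectSd = "numeric", noiseSd = "numeric",
                   mixing = "list", plantedBlocks = "list",
                   depthRange = "list", svExpansion = "list",
                   seed = "integer"))

setValidity("SyntheticScenario", function(object) {
    msg <- character()
    grp <- c("mono_A", "mixed_A", "mixed_W", "mono_W")
    if (!all(grp %in% names(object@nSamples)))
        msg <- c(msg, "nSamples must name all four treatment groups")
    else if (any(object@nSamples[grp] < 3L))
        msg <- c(msg, "each treatment group needs >= 3 samples")
    if (!all(c("bacteria", "fungi") %in% names(object@nGenera)))
        msg <- c(msg, "nGenera must name bacteria and fungi")
    lam <- unlist(object@mixing)
    if (any(lam < 0 | lam > 1))
        msg <- c(msg, "mixing coefficients must lie in [0, 1]")
    for (k in names(object@depthRange)) {
        dr <- object@depthRange[[k]]
        if (dr[1] < 1 || dr[2] < dr[1])
            msg <- c(msg, sprintf("depthRange$%s must satisfy 1 <= min <= max", k))
    }
    ids <- featureIds(object)
    for (i in seq_along(object@plantedBlocks)) {
        b <- object@plantedBlocks[[i]]
        if (!all(b$members %in% ids))
            msg <- c(msg, sprintf("planted block %d references unknown features: %s",
                                  i, paste(setdiff(b$members, ids), collapse = ", ")))
        if (abs(b$r) >= 1)
            msg <- c(msg, sprintf("planted block %d: |r| must be < 1", i))
    }
    if (length(msg)) msg else TRUE
})

#' Feature identifiers implied by a scenario
#'
#' Bacterial genera are named \code{B001, B002, ...} and fungal genera
#' \code{F001, ...}; planted blocks refer to these ids.
#'
#' @param scenario a \linkS4class{SyntheticScenario}.
#' @return character vector of feature ids, bacteria first.
#' @export
featureIds <- function(scenario) {
    nb <- scenario@nGenera[["bacteria"]]
    nf <- scenario@nGenera[["fungi"]]
    c(sprintf("B%03d", seq_len(nb)), sprintf("F%03d", seq_len(nf)))
}

#' CooccurrenceResult: pairwise Spearman matrices for one treatment group
#'
#' Symmetric rank-correlation (\code{rho}) and two-sided p-value matrices
#' over the defined (non-constant) features of one treatment group, with
#' kingdom labels for cross-kingdom bookkeeping.
#'
#' @slot rho symmetric numeric matrix in [-1, 1].
#' @slot p symmetric numeric matrix in (0, 1]; diagonal NA.
#' @slot kingdom named character vector, one entry per retained feature.
#' @slot nSamples number of samples the correlations were computed over.
#' @slot group treatment-group label.
#' @slot excluded character vector of zero-variance features excluded from
#'   pair enumeration.
#' @aliases CooccurrenceResult-class
#' @exportClass CooccurrenceResult
setClass("CooccurrenceResult",
    representation(rho = "matrix", p = "matrix", kingdom = "character",
                   nSamples = "integer", group = "character",
                   excluded = "character"))

setValidity("CooccurrenceResult", function(object) {
    msg <- character()
    if (!isTRUE(all.equal(object@rho, t(object@rho), tolerance = 1e-12)))
        msg <- c(msg, "rho must be symmetric")
    off <- object@rho[upper.tri(object@rho)]
    if (any(abs(off[!is.na(off)]) > 1 + 1e-12))
        msg <- c(msg, "defined rho entries must lie in [-1, 1]")
    poff <- object@p[upper.tri(object@p)]
    poff <- poff[!is.na(poff)]
    if (any(poff <= 0 | poff > 1))
        msg <- c(msg, "p-values must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticScenario", function(object) {
    cat("SyntheticScenario\n")
    cat("  groups: ", paste(sprintf("%s=%d", names(object@nSamples),
                                    object@nSamples), collapse = ", "),
        " (+", object@nSoil, " soil)\n", sep = "")
    cat("  genera: bacteria=", object@nGenera[["bacteria"]],
        ", fungi=", object@nGenera[["fungi"]], "\n", sep = "")
    cat("  mixing lambda: bacteria A=", object@mixing$bacteria[["A"]],
        " W=", object@mixing$bacteria[["W"]],
        "; fungi A=", object@mixing$fungi[["A"]],
        " W=", object@mixing$fungi[["W"]], "\n", sep = "")
    cat("  planted blocks: ", length(object@plantedBlocks),
        "; seed: ", object@seed, "\n", sep = "")
})

setMethod("show", "CooccurrenceResult", function(object) {
    cat("CooccurrenceResult for group '", object@group, "'\n", sep = "")
    cat("  features: ", nrow(object@rho), " (",
        sum(object@kingdom == "bacteria"), " bacteria, ",
        sum(object@kingdom == "fungi"), " fungi); excluded: ",
        length(object@excluded), "\n", sep = "")
    cat("  samples: ", object@nSamples, "\n", sep = "")
})
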