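#' Quality-filter sequence variants
#'
#' Applies the SV-level quality rules in one pass: an inclusive length
#' window (16S communities are typically filtered to the expected amplicon
#' window, e.g. keeping lengths of at most 260 bp; ITS is usually left
#' unfiltered because the region's length is highly variable), removal of
#' SVs observed in negative controls, and a minimum total read count
#' across all samples ("fewer than 100 reads" removed means totals of
#' exactly 100 are kept). Surviving feature order is preserved and a
#' per-rule removal report is attached (retrievable with
#' \code{\link{processingReport}}). Control removal is applied before the
#' read-count rule; the report records the order.
#'
#' @param x an SV-level \linkS4class{MicrobiomeExperiment} whose rowData
#'   carries \code{length} and \code{control} when those rules are used.
#' @param lengthWindow \code{c(min, max)} inclusive window in bp, or NULL
#'   to skip length filtering.
#' @param dropControl drop features flagged as negative-control-derived?
#' @param minTotalReads keep features with total reads >= this value.
#' @return the filtered \linkS4class{MicrobiomeExperiment}; idempotent.
#' @examples
#' m <- matrix(c(99, 0, 100, 0, 250, 0), 3, 2, byrow = TRUE,
#'             dimnames = list(paste0("sv", 1:3), c("s1", "s2")))
#' me <- MicrobiomeExperiment(m)
#' rownames(countMatrix(filterFeatures(me, minTotalReads = 100)))
#' @export
filterFeatures <- function(x, lengthWindow = NULL, dropControl = FALSE,
                           minTotalReads = 0) {
    m <- countMatrix(x)
    rd <- SummarizedExperiment::rowData(x)
    keep <- rep(TRUE, nrow(m))
    report <- data.frame(rule = character(), removed = integer())

    if (dropControl) {
        if (is.null(rd$control))
            stop("control flags requested but rowData has no 'control' column")
        if (anyNA(rd$control))
            stop("missing control flag for feature(s): ",
                 paste(rownames(m)[is.na(rd$control)], collapse = ", "))
        drop <- keep & rd$control
        report <- rbind(report, data.frame(rule = "negative_control",
                                           removed = sum(drop)))
        keep <- keep & !rd$control
    }
    if (!is.null(lengthWindow)) {
        if (is.null(rd$length))
            stop("length window requested but rowData has no 'length' column")
        if (anyNA(rd$length))
            stop("missing length for feature(s): ",
                 paste(rownames(m)[is.na(rd$length)], collapse = ", "))
        ok <- rd$length >= lengthWindow[1] & rd$length <= lengthWindow[2]
        report <- rbind(report, data.frame(rule = "length_window",
                                           removed = sum(keep & !ok)))
        keep <- keep & ok
    }
    if (minTotalReads > 0) {
        ok <- rowSums(m) >= minTotalReads
        report <- rbind(report, data.frame(rule = "min_total_reads",
                                           removed = sum(keep & !ok)))
        keep <- keep & ok
    }
    out <- x[keep, ]
    S4Vectors::metadata(out)$report <- report
    methods::validObject(out)
    out
}

#' Fill missing taxonomy downward
#'
#' Propagates the deepest assigned rank into all missing lower ranks,
#' marking filled entries as \code{"<Rank>_<name>"} (e.g. a feature
#' assigned only to family Prevotellaceae gets genus and species
#' \code{"Family_Prevotellaceae"}). This keeps unassigned features from
#' being dropped by rank agglomeration while making the provenance of the
#' name explicit. Already-assigned ranks are untouched and the operation
#' is idempotent.
#'
#' @param x a \linkS4class{MicrobiomeExperiment} with taxonomy in rowData,
#'   or a plain taxonomy data.frame with rank columns.
#' @return same class as the input, with a complete 7-rank taxonomy.
#' @export
fillTaxonomy <- function(x) {
    if (methods::is(x, "MicrobiomeExperiment")) {
        tax <- taxonomy(x)
        filled <- fillTaxonomyFrame(tax)
        for (r in colnames(filled))
            SummarizedExperiment::rowData(x)[[r]] <- filled[[r]]
        return(x)
    }
    fillTaxonomyFrame(x)
}

fillTaxonomyFrame <- function(tax) {
    ranks <- intersect(TAXONOMY_RANKS, colnames(tax))
    tax <- as.data.frame(tax)
    missing_all <- apply(tax[, ranks, drop = FALSE], 1,
                         function(z) all(is.na(z) | z == ""))
    if (any(missing_all))
        stop("feature(s) with no assigned rank at any level: ",
             paste(rownames(tax)[missing_all], collapse = ", "))
    if ("Kingdom" %in% ranks) {
        nok <- is.na(tax$Kingdom) | tax$Kingdom == ""
        if (any(nok))
            stop("feature(s) missing a kingdom assignment: ",
                 paste(rownames(tax)[nok], collapse = ", "))
    }
    for (i in seq_len(nrow(tax))) {
        fill <- NULL
        for (r in ranks) {
            v <- tax[i, r]
            if (is.na(v) || v == "") {
                tax[i, r] <- fill
            } else {
                ## refresh marker only from genuinely assigned entries
                fill <- paste0(r, "_", v)
            }
        }
    }
    tax
}

#' Agglomerate features to a taxonomic rank
#'
#' Sums counts over all features sharing a name at the requested rank.
#' Taxonomy must have been filled down first so no feature is dropped for
#' a missing assignment. Per-sample totals are conserved.
#'
#' @param x a \linkS4class{MicrobiomeExperiment}.
#' @param rank one of Kingdom, Phylum, Class, Order, Family, Genus,
#'   Species.
#' @return a \linkS4class{MicrobiomeExperiment} with one feature per
#'   distinct name at \code{rank}; rowData keeps the ranks at or above
#'   \code{rank}.
#' @export
agglomerate <- function(x, rank = "Genus") {
    if (!rank %in% TAXONOMY_RANKS)
        stop("unknown rank '", rank, "'")
    tax <- taxonomy(x)
    if (is.null(tax) || !rank %in% colnames(tax))
        stop("taxonomy with rank '", rank, "' required")
    key <- tax[[rank]]
    if (anyNA(key))
        stop("missing '", rank, "' assignments; run fillTaxonomy() first")
    m <- countMatrix(x)
    agg <- rowsum(m, group = key, reorder = FALSE)
    keepRanks <- TAXONOMY_RANKS[seq_len(match(rank, TAXONOMY_RANKS))]
    keepRanks <- intersect(keepRanks, colnames(tax))
    first <- !duplicated(key)
    newtax <- tax[first, keepRanks, drop = FALSE]
    rownames(newtax) <- key[first]
    newtax <- newtax[rownames(agg), , drop = FALSE]
    meta <- as.data.frame(SummarizedExperiment::colData(x))
    meta$sample_id <- rownames(meta)
    km <- kingdomMap(x)
    MicrobiomeExperiment(agg, taxonomy = newtax, metadata = meta,
        rank = rank,
        kingdom = if (is.null(km)) NULL else km[first])
}

## Exact sampling without replacement of `depth` reads from a count vector
## via sequential conditional hypergeometric draws.
rarefyVector <- function(x, depth) {
    n <- length(x)
    out <- numeric(n)
    totrem <- sum(x)
    rem <- depth
    for (f in seq_len(n)) {
        if (rem == 0) break
        k <- rhyper(1, x[f], totrem - x[f], rem)
        out[f] <- k
        rem <- rem - k
        totrem <- totrem - x[f]
    }
    out
}

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly
#' \code{depth}; samples whose totals fall below \code{depth} are dropped
#' with a warning (recorded in the report). Features reduced to all-zero
#' rows are retained by default so feature axes stay comparable across
#' iterations; set \code{dropEmpty = TRUE} to remove them.
#'
#' @param x a \linkS4class{MicrobiomeExperiment}.
#' @param depth target reads per sample; defaults to the minimum sample
#'   total (the depth of the shallowest sample).
#' @param seed integer seed for reproducibility.
#' @param dropEmpty drop features left with zero total counts?
#' @return a rarefied \linkS4class{MicrobiomeExperiment}; every retained
#'   column sums to \code{depth}.
#' @export
rarefy <- function(x, depth = NULL, seed = 1L, dropEmpty = FALSE) {
    m <- countMatrix(x)
    totals <- colSums(m)
    if (is.null(depth)) depth <- min(totals)
    if (depth < 1) stop("depth must be >= 1")
    if (all(totals < depth))
        stop("depth ", depth, " exceeds every sample's total")
    keep <- totals >= depth
    dropped <- colnames(m)[!keep]
    if (length(dropped))
        warning("dropping ", length(dropped),
                " sample(s) below depth ", depth, ": ",
                paste(dropped, collapse = ", "))
    set.seed(seed)
    sub <- vapply(which(keep), function(j) rarefyVector(m[, j], depth),
                  numeric(nrow(m)))
    sub <- matrix(sub, nrow = nrow(m))
    rownames(sub) <- rownames(m)
    colnames(sub) <- colnames(m)[keep]
    out <- x[, keep]
    SummarizedExperiment::assay(out, "counts") <- sub
    if (dropEmpty) out <- out[rowSums(sub) > 0, ]
    S4Vectors::metadata(out)$report <- list(
        depth = depth, dropped_samples = dropped, seed = seed)
    out
}

#' Merge bacterial and fungal tables into one cross-kingdom table
#'
#' Row-wise concatenation with kingdom-prefixed feature ids, after
#' checking that both tables are at the same rank and cover the same
#' samples. Sample order is canonicalized (sorted) so merged output does
#' not depend on input column order.
#'
#' @param bacteria,fungi \linkS4class{MicrobiomeExperiment}s at a common
#'   rank over equal sample sets.
#' @return a merged \linkS4class{MicrobiomeExperiment}; per-feature
#'   kingdoms are available via \code{\link{kingdomMap}}.
#' @export
mergeKingdoms <- function(bacteria, fungi) {
    if (!identical(axisRank(bacteria), axisRank(fungi)))
        stop("tables must be agglomerated to the same rank")
    sb <- colnames(bacteria)
    sf <- colnames(fungi)
    if (nrow(fungi) > 0 && nrow(bacteria) > 0 && !setequal(sb, sf))
        stop("sample sets differ; only in bacteria: ",
             paste(setdiff(sb, sf), collapse = ", "),
             "; only in fungi: ", paste(setdiff(sf, sb), collapse = ", "))
    smp <- sort(unique(c(sb, sf)))
    prefix <- function(x, k) {
        if (nrow(x) == 0) return(NULL)
        m <- countMatrix(x)[, smp, drop = FALSE]
        rownames(m) <- paste0(k, "|", rownames(m))
        m
    }
    mb <- prefix(bacteria, "bacteria")
    mf <- prefix(fungi, "fungi")
    merged <- rbind(mb, mf)
    km <- c(rep("bacteria", NROW(mb)), rep("fungi", NROW(mf)))
    base <- if (nrow(bacteria) > 0) bacteria else fungi
    meta <- as.data.frame(SummarizedExperiment::colData(base))
    meta$sample_id <- rownames(meta)
    meta <- meta[smp, , drop = FALSE]
    MicrobiomeExperiment(merged, metadata = meta, rank = axisRank(bacteria),
                         kingdom = km)
}

#' Split a merged cross-kingdom table back into its kingdoms
#'
#' Inverse of \code{\link{mergeKingdoms}}: strips the kingdom prefix and
#' partitions rows by the kingdom map.
#'
#' @param x a merged \linkS4class{MicrobiomeExperiment}.
#' @return list with \code{bacteria} and \code{fungi} count matrices.
#' @export
splitKingdoms <- function(x) {
    km <- kingdomMap(x)
    m <- countMatrix(x)
    lapply(split(seq_len(nrow(m)), km), function(idx) {
        sub <- m[idx, , drop = FALSE]
        rownames(sub) <- sub("^[^|]+\\|", "", rownames(sub))
        sub
    })
}

#' Group-averaged relative-abundance profiles at a rank
#'
#' Converts each sample to relative abundances (sample sums to 1),
#' aggregates to the requested rank, and averages within treatment
#' groups. Taxa are ordered by overall mean abundance; the table can be
#' truncated to the top \code{topN} taxa and/or filtered to taxa whose
#' combined relative abundance summed across groups exceeds
#' \code{minCombined} (e.g. 0.01 reproduces a "> 1 percent combined
#' abundance" heatmap filter).
#'
#' @param x a \linkS4class{MicrobiomeExperiment} with filled taxonomy and
#'   sample metadata containing a \code{group} column.
#' @param rank taxonomic rank to profile (e.g. "Family").
#' @param topN keep only this many top taxa (NULL keeps all).
#' @param minCombined keep taxa whose summed across-group mean relative
#'   abundance exceeds this value (NULL disables).
#' @param groups optional character vector restricting/ordering the
#'   treatment groups.
#' @return data.frame: one row per taxon, one column per group, plus
#'   \code{overall_mean}; rows in descending overall mean.
#' @export
taxonProfiles <- function(x, rank = "Family", topN = NULL,
                          minCombined = NULL, groups = NULL) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    if (is.null(cd$group))
        stop("sample metadata must contain a 'group' column")
    miss <- colnames(x)[is.na(cd$group)]
    if (length(miss))
        stop("samples missing group metadata: ", paste(miss, collapse = ", "))
    agg <- agglomerate(x, rank)
    m <- countMatrix(agg)
    rel <- sweep(m, 2, colSums(m), "/")
    g <- cd[colnames(m), "group"]
    if (is.null(groups)) groups <- unique(g)
    prof <- vapply(groups, function(gg)
        rowMeans(rel[, g == gg, drop = FALSE]), numeric(nrow(rel)))
    prof <- matrix(prof, nrow = nrow(rel),
                   dimnames = list(rownames(rel), groups))
    prof <- as.data.frame(prof)
    prof$overall_mean <- rowMeans(rel)
    prof <- prof[order(-prof$overall_mean), ]
    if (!is.null(minCombined))
        prof <- prof[rowSums(prof[, groups, drop = FALSE]) > minCombined, ]
    if (!is.null(topN)) prof <- head(prof, topN)
    prof
}
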