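#' Default pipeline configuration
#'
#' A single structured configuration object covering every stage of the
#' analysis. Every default the underlying study design leaves open is
#' surfaced here so the run log doubles as a record of the choices made:
#' filter thresholds (bacterial length window 240-260 bp inclusive, no
#' fungal length filter, control removal before the 100-read rule),
#' rarefaction to the shallowest sample, 100 richness trials, 999
#' permutations, raw p < 0.05 with |rho| tiers 0.5/0.75, binary Jaccard.
#'
#' @param scenario a \linkS4class{SyntheticScenario} (or NULL when input
#'   paths are given).
#' @param seed master seed; per-stage child seeds derive from it.
#' @param ... overrides for any config entry.
#' @return a named list of class \code{"pipelineConfig"}.
#' @export
defaultPipelineConfig <- function(scenario = defaultScenario(), seed = 1L,
                                  ...) {
    cfg <- list(
        scenario = scenario,
        inputs = NULL,              # or list(bacteria=, fungi=, metadata=)
        seed = as.integer(seed),
        filters = list(
            bacteria = list(lengthWindow = c(240, 260), dropControl = TRUE,
                            minTotalReads = 100),
            fungi = list(lengthWindow = NULL, dropControl = TRUE,
                         minTotalReads = 100)),
        richness_trials = 100L,
        metrics = c("jsd", "jaccard_binary"),
        ordination_metric = "bray_curtis",
        n_permutations = 999L,
        nmds_k = 2L, nmds_restarts = 20L,
        cooccurrence = list(alpha = 0.05, moderate = 0.5, strong = 0.75),
        profile_rank = "Family", profile_top_n = 10L)
    over <- list(...)
    cfg[names(over)] <- over
    errs <- character()
    cc <- cfg$cooccurrence
    if (!(cc$alpha > 0 && cc$alpha < 1))
        errs <- c(errs, "cooccurrence$alpha must lie in (0,1)")
    if (!(cc$moderate > 0 && cc$strong < 1 && cc$moderate < cc$strong))
        errs <- c(errs, "cooccurrence thresholds must satisfy 0 < moderate < strong < 1")
    if (is.null(cfg$scenario) && is.null(cfg$inputs))
        errs <- c(errs, "either a scenario or input paths must be given")
    if (cfg$richness_trials < 1)
        errs <- c(errs, "richness_trials must be >= 1")
    if (length(errs))
        stop("invalid pipeline configuration:\n  - ",
             paste(errs, collapse = "\n  - "))
    class(cfg) <- c("pipelineConfig", "list")
    cfg
}

#' Run the full analysis pipeline
#'
#' Executes the stages in the order a root-microbiome analysis runs them:
#' simulate (or load) paired kingdom tables; expand to sequence variants
#' and apply quality filters; fill taxonomy; group relative-abundance
#' profiles; Bray-Curtis ordination (NMDS) and PERMANOVA per kingdom on
#' root samples; iterative rarefied richness; JSD and Jaccard distances
#' with a Mantel test between the kingdoms; rarefaction to the shallowest
#' sample; genus agglomeration and cross-kingdom merge; per-treatment-
#' group Spearman co-occurrence with tiered interaction counts and
#' networks. Every stochastic stage uses a child seed derived
#' deterministically from the master seed, so re-running an identical
#' configuration is byte-identical. Soil samples are carried through the
#' preprocessing stages but excluded from ordination, inference and
#' networks by contract.
#'
#' @param config a \code{pipelineConfig} from
#'   \code{\link{defaultPipelineConfig}}.
#' @return a \code{reportBundle} list: filter reports, profiles,
#'   ordinations, PERMANOVA/Mantel records, richness, per-group tiered
#'   summaries and networks, the formatted interaction table, and a run
#'   log.
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
    stopifnot(inherits(config, "pipelineConfig"))
    log <- character()
    note <- function(...) log <<- c(log, sprintf(...))
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    bundle <- list(config = config)

    ## -- inputs ------------------------------------------------------
    if (!is.null(config$inputs)) {
        inp <- config$inputs
        sim <- stage("load", {
            meta <- readSampleMetadata(inp$metadata)
            mk <- function(p, tp, k) MicrobiomeExperiment(
                readCountTable(p), taxonomy = readTaxonomyTable(tp),
                metadata = meta, rank = "Genus", kingdom = k)
            list(bacteria = mk(inp$bacteria, inp$bacteria_taxonomy, "bacteria"),
                 fungi = mk(inp$fungi, inp$fungi_taxonomy, "fungi"),
                 metadata = meta, truth = NULL)
        })
        svb <- sim$bacteria; svf <- sim$fungi
        note("loaded input tables from disk")
    } else {
        scen <- config$scenario
        scen@seed <- childSeed(config$seed, "simulate")
        sim <- stage("simulate", simulateExperiment(scen))
        note("simulated scenario (seed %d)", scen@seed)
        if (length(sim$truth$log)) note("%s", sim$truth$log)
        svb <- stage("sv_expansion", expandToSVLevel(
            sim$bacteria, scen, seed = childSeed(config$seed, "sv_b")))
        svf <- stage("sv_expansion", expandToSVLevel(
            sim$fungi, scen, seed = childSeed(config$seed, "sv_f")))
        note("expanded to %d bacterial and %d fungal SVs",
             nrow(svb), nrow(svf))
    }
    bundle$truth <- sim$truth
    meta <- sim$metadata

    ## -- filtering + taxonomy ---------------------------------------
    filt <- stage("filter", lapply(
        list(bacteria = svb, fungi = svf), function(sv) {
            k <- unname(kingdomMap(sv)[1])
            f <- config$filters[[k]]
            hasAttrs <- "length" %in%
                colnames(SummarizedExperiment::rowData(sv))
            filterFeatures(sv,
                lengthWindow = if (hasAttrs) f$lengthWindow else NULL,
                dropControl = hasAttrs && f$dropControl,
                minTotalReads = f$minTotalReads)
        }))
    bundle$filter_reports <- lapply(filt, processingReport)
    note("filtering: bacteria %d -> %d, fungi %d -> %d features",
         nrow(svb), nrow(filt$bacteria), nrow(svf), nrow(filt$fungi))
    filt <- stage("fill_taxonomy", lapply(filt, fillTaxonomy))

    root <- meta$sample_id[meta$sample_type == "root"]
    groups <- setNames(meta$group, meta$sample_id)[root]

    ## -- profiles ----------------------------------------------------
    bundle$profiles <- stage("profiles", lapply(filt, function(f)
        taxonProfiles(f[, root], rank = config$profile_rank,
                      topN = config$profile_top_n)))

    ## -- ordination + PERMANOVA -------------------------------------
    bundle$ordination <- list()
    bundle$permanova <- list()
    for (k in c("bacteria", "fungi")) {
        dm <- stage("ordination",
                    distanceMatrix(filt[[k]][, root],
                                   config$ordination_metric))
        bundle$ordination[[k]] <- stage("ordination", nmds(
            dm, k = config$nmds_k, nRestarts = config$nmds_restarts,
            seed = childSeed(config$seed, paste0("nmds_", k))))
        bundle$permanova[[k]] <- stage("permanova", permanova(
            dm, groups, nPermutations = config$n_permutations,
            seed = childSeed(config$seed, paste0("permanova_", k))))
    }

    ## -- richness ----------------------------------------------------
    bundle$richness <- stage("richness", lapply(filt, function(f)
        iterativeRichness(f, nTrials = config$richness_trials,
                          seed = childSeed(config$seed, "richness"))))

    ## -- cross-kingdom distance concordance -------------------------
    if (length(config$metrics) >= 1) {
        bundle$distances <- list()
        for (met in config$metrics)
            bundle$distances[[met]] <- lapply(filt, function(f)
                stage("distances", distanceMatrix(f[, root], met)))
        bundle$mantel <- stage("mantel", lapply(
            setNames(config$metrics, config$metrics), function(met)
                mantelTest(bundle$distances[[met]]$bacteria,
                           bundle$distances[[met]]$fungi,
                           nPermutations = config$n_permutations,
                           seed = childSeed(config$seed,
                                            paste0("mantel_", met)))))
    } else {
        bundle$mantel <- NULL
        note("mantel stage skipped: fewer than one distance metric configured")
    }

    ## -- rarefy, agglomerate, merge ---------------------------------
    rar <- stage("rarefy", lapply(
        setNames(c("bacteria", "fungi"), c("bacteria", "fungi")),
        function(k) rarefy(filt[[k]][, root],
                           seed = childSeed(config$seed,
                                            paste0("rarefy_", k)))))
    for (k in names(rar))
        note("rarefied %s to depth %d", k, processingReport(rar[[k]])$depth)
    gen <- stage("agglomerate", lapply(rar, agglomerate, rank = "Genus"))
    merged <- stage("merge", mergeKingdoms(gen$bacteria, gen$fungi))
    bundle$merged_features <- nrow(merged)

    ## -- co-occurrence networks per treatment group -----------------
    cc <- config$cooccurrence
    rootKept <- intersect(colnames(merged), root)
    grpKept <- groups[rootKept]
    bundle$cooccurrence <- list()
    bundle$networks <- list()
    summaries <- NULL
    for (g in unique(meta$group[meta$sample_type == "root"])) {
        smp <- rootKept[grpKept == g]
        res <- stage("cooccurrence",
                     spearmanCooccurrence(merged, samples = smp, group = g))
        if (length(res@excluded))
            note("group %s: %d zero-variance features excluded",
                 g, length(res@excluded))
        bundle$cooccurrence[[g]] <- res
        summaries <- rbind(summaries, tieredCounts(
            res, alpha = cc$alpha, moderate = cc$moderate,
            strong = cc$strong))
        bundle$networks[[g]] <- buildNetwork(res, alpha = cc$alpha,
                                             rhoThreshold = cc$strong)
    }
    bundle$tiered_summary <- summaries
    bundle$interaction_table <- formatInteractionTable(summaries)
    bundle$network_stats <- lapply(bundle$networks, networkSummaryStats)

    bundle$log <- c(log, sprintf("master seed %d", config$seed),
                    sprintf("R version %s", getRversion()))
    class(bundle) <- c("reportBundle", "list")
    bundle
}

#' Write a report bundle to a directory
#'
#' Emits every result surface as plain text: filter reports, profiles,
#' richness, ordination coordinates, PERMANOVA/Mantel records (JSON),
#' distance matrices, per-group edge lists and GraphML, the tiered
#' interaction table, and the run log.
#'
#' @param bundle a \code{reportBundle} from \code{\link{runPipeline}}.
#' @param outdir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writeReportBundle <- function(bundle, outdir) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(...) file.path(outdir, ...)
    for (k in names(bundle$filter_reports))
        write.table(bundle$filter_reports[[k]],
                    fp(paste0("filter_report_", k, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    for (k in names(bundle$profiles))
        write.table(data.frame(taxon = rownames(bundle$profiles[[k]]),
                               bundle$profiles[[k]], check.names = FALSE),
                    fp(paste0("profiles_", k, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    for (k in names(bundle$richness))
        write.table(bundle$richness[[k]],
                    fp(paste0("richness_", k, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    for (k in names(bundle$ordination))
        write.table(data.frame(sample_id =
                                   rownames(bundle$ordination[[k]]$points),
                               bundle$ordination[[k]]$points),
                    fp(paste0("nmds_", k, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    inference <- list(
        permanova = lapply(bundle$permanova, unclass),
        mantel = lapply(bundle$mantel, unclass))
    jsonlite::write_json(inference, fp("inference.json"),
                         auto_unbox = TRUE, digits = NA)
    for (met in names(bundle$distances))
        for (k in names(bundle$distances[[met]]))
            writeDistanceMatrix(bundle$distances[[met]][[k]],
                                fp(sprintf("distance_%s_%s.tsv", met, k)))
    for (g in names(bundle$networks)) {
        writeEdgeList(bundle$networks[[g]],
                      fp(paste0("edges_", g, ".tsv")))
        exportGraphML(bundle$networks[[g]],
                      fp(paste0("network_", g, ".graphml")))
    }
    write.table(bundle$interaction_table, fp("interaction_table.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(bundle$log, fp("run_log.txt"))
    invisible(outdir)
}
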