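#' Default synthetic mixed-cropping scenario
#'
#' Mirrors the glasshouse design the package targets: two crop varieties
#' ("A" and "W") grown as mono- or mixed-crops, giving four root
#' treatment groups sized 16/11/11/16 (8 mono pots x 2 plants, 11 mixed
#' pots x 1 plant per variety) plus 3 potting-soil samples.
#' Kingdom-asymmetric mixing defaults (bacterial communities of
#' mixed-cropped A shift towards W, fungal communities of mixed-cropped W
#' shift towards A) reproduce the qualitative ordination geometry such a
#' design is built to detect. Sequencing depths are drawn uniformly over
#' ranges typical of paired 16S/ITS MiSeq runs of this size (bacteria
#' 14020-95216, fungi 2653-13954 reads per sample).
#'
#' @param nSamples named integer vector of group sizes.
#' @param nSoil number of soil samples.
#' @param nGenera named integer vector \code{c(bacteria=, fungi=)}.
#' @param baseLog mean and sd of genus baseline log-abundances.
#' @param varietyEffectSd sd of per-genus variety offsets.
#' @param noiseSd sd of per-sample latent noise.
#' @param mixing per-kingdom, per-variety mixing coefficients in [0, 1].
#' @param plantedBlocks list of planted correlation blocks; each block is
#'   \code{list(members = <feature ids>, r = <latent correlation>,
#'   groups = <treatment groups where active>)}.
#' @param depthRange per-kingdom \code{c(min, max)} sequencing depth.
#' @param svExpansion SV-expansion parameters used by
#'   \code{\link{expandToSVLevel}}.
#' @param seed integer master seed.
#' @return a validated \linkS4class{SyntheticScenario}.
#' @examples
#' sc <- defaultScenario(seed = 1)
#' sc
#' @export
defaultScenario <- function(
        nSamples = c(mono_A = 16L, mixed_A = 11L, mixed_W = 11L,
                     mono_W = 16L),
        nSoil = 3L,
        nGenera = c(bacteria = 100L, fungi = 25L),
        baseLog = c(mean = 0, sd = 1),
        varietyEffectSd = 1,
        noiseSd = 1,
        mixing = list(bacteria = c(A = 0.6, W = 0.05),
                      fungi = c(A = 0.05, W = 0.6)),
        plantedBlocks = list(),
        depthRange = list(bacteria = c(14020, 95216),
                          fungi = c(2653, 13954)),
        svExpansion = list(meanSV = 3, lengthMode = 253, lengthSd = 3,
                           outlierFrac = 0, outlierRange = c(261, 434),
                           contaminants = 0L, rareFrac = 0),
        seed = 1L) {
    methods::new("SyntheticScenario",
        nSamples = setNames(as.integer(nSamples), names(nSamples)),
        nSoil = as.integer(nSoil),
        nGenera = setNames(as.integer(nGenera), names(nGenera)),
        baseLog = baseLog, varietyEffectSd = varietyEffectSd,
        noiseSd = noiseSd, mixing = mixing,
        plantedBlocks = plantedBlocks, depthRange = depthRange,
        svExpansion = svExpansion, seed = as.integer(seed))
}

GROUPS <- c("mono_A", "mixed_A", "mixed_W", "mono_W")

## Build the latent noise correlation matrix for one group: identity plus
## planted blocks active in the group, nearest-PD-repaired if needed.
groupCorrelation <- function(scenario, group, tol = 0.25) {
    ids <- featureIds(scenario)
    G <- length(ids)
    C <- diag(G)
    dimnames(C) <- list(ids, ids)
    active <- character()
    for (i in seq_along(scenario@plantedBlocks)) {
        b <- scenario@plantedBlocks[[i]]
        if (!group %in% b$groups) next
        idx <- match(b$members, ids)
        C[idx, idx] <- b$r
        diag(C)[idx] <- 1
        active <- c(active, sprintf("block%d", i))
    }
    repaired <- FALSE
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-8) {
        Cp <- as.matrix(Matrix::nearPD(C, corr = TRUE)$mat)
        if (max(abs(Cp - C)) > tol)
            stop("correlation for group '", group,
                 "' not positive definite within repair tolerance; ",
                 "offending blocks: ", paste(active, collapse = ", "))
        C <- Cp
        repaired <- TRUE
    }
    list(C = C, repaired = repaired, blocks = active)
}

softmax <- function(x) {
    e <- exp(x - max(x))
    e / sum(e)
}

#' Simulate a paired-kingdom mixed-cropping experiment
#'
#' Generates genus-level bacterial and fungal count tables with the
#' statistical structure the downstream analysis assumes. Per-genus
#' baseline log-abundances are Normal(mean, sd^2); each variety carries
#' Normal(0, varietyEffectSd^2) per-genus offsets; the mixed-cropped
#' centroid of variety V blends in a fraction lambda of the other
#' variety's centroid: \eqn{(1-\lambda)(\mu_0+\delta_V) +
#' \lambda(\mu_0+\delta_{other})}. Per-sample latent vectors add Gaussian
#' noise whose correlation matrix embeds the planted blocks active in that
#' sample's group; bacterial and fungal latents are drawn jointly so
#' cross-kingdom blocks are honoured, then split by kingdom. Counts are
#' multinomial draws from the softmax of each kingdom's latent vector at a
#' depth drawn uniformly from the kingdom's depth range. Identical
#' scenarios and seeds give bit-identical output.
#'
#' @param scenario a \linkS4class{SyntheticScenario}.
#' @return list with elements \code{bacteria} and \code{fungi}
#'   (genus-level \linkS4class{MicrobiomeExperiment}s), \code{taxonomy}
#'   (data.frame over all genera), \code{metadata} (sample data.frame),
#'   and \code{truth} (planted ground truth: \code{pairs} data.frame and
#'   \code{centroids} matrix, plus a \code{log} of any correlation
#'   repairs).
#' @examples
#' sim <- simulateExperiment(defaultScenario(
#'     nGenera = c(bacteria = 20L, fungi = 5L),
#'     depthRange = list(bacteria = c(2000, 4000), fungi = c(500, 900)),
#'     seed = 7))
#' dim(countMatrix(sim$bacteria))
#' @export
simulateExperiment <- function(scenario) {
    methods::validObject(scenario)
    set.seed(scenario@seed)
    ids <- featureIds(scenario)
    G <- length(ids)
    nb <- scenario@nGenera[["bacteria"]]
    kingdom <- setNames(rep(c("bacteria", "fungi"),
                            scenario@nGenera[c("bacteria", "fungi")]), ids)

    mu0 <- rnorm(G, scenario@baseLog[["mean"]], scenario@baseLog[["sd"]])
    dA <- rnorm(G, 0, scenario@varietyEffectSd)
    dW <- rnorm(G, 0, scenario@varietyEffectSd)
    lam <- function(k, v) scenario@mixing[[k]][[v]]
    lamA <- ifelse(kingdom == "bacteria", lam("bacteria", "A"), lam("fungi", "A"))
    lamW <- ifelse(kingdom == "bacteria", lam("bacteria", "W"), lam("fungi", "W"))
    cent <- cbind(
        mono_A  = mu0 + dA,
        mixed_A = (1 - lamA) * (mu0 + dA) + lamA * (mu0 + dW),
        mixed_W = (1 - lamW) * (mu0 + dW) + lamW * (mu0 + dA),
        mono_W  = mu0 + dW)
    rownames(cent) <- ids

    ## samples
    meta <- do.call(rbind, lapply(GROUPS, function(g) {
        n <- scenario@nSamples[[g]]
        data.frame(
            sample_id = sprintf("%s_%02d", g, seq_len(n)),
            variety = if (grepl("_A$", g)) "A" else "W",
            cropping = if (grepl("^mono", g)) "mono" else "mixed",
            group = g, sample_type = "root",
            stringsAsFactors = FALSE)
    }))
    if (scenario@nSoil > 0)
        meta <- rbind(meta, data.frame(
            sample_id = sprintf("soil_%02d", seq_len(scenario@nSoil)),
            variety = "none", cropping = "none", group = "soil",
            sample_type = "soil", stringsAsFactors = FALSE))

    latent <- matrix(NA_real_, G, nrow(meta),
                     dimnames = list(ids, meta$sample_id))
    repair_log <- character()
    for (g in GROUPS) {
        cc <- groupCorrelation(scenario, g)
        if (cc$repaired)
            repair_log <- c(repair_log, sprintf(
                "group %s: correlation repaired to nearest PD (blocks %s)",
                g, paste(cc$blocks, collapse = ",")))
        Sigma <- scenario@noiseSd^2 * cc$C
        smp <- meta$sample_id[meta$group == g]
        noise <- MASS::mvrnorm(length(smp), mu = rep(0, G), Sigma = Sigma)
        latent[, smp] <- cent[, g] + t(noise)
    }
    if (scenario@nSoil > 0) {
        smp <- meta$sample_id[meta$group == "soil"]
        noise <- matrix(rnorm(G * length(smp), 0, scenario@noiseSd),
                        G, length(smp))
        latent[, smp] <- mu0 + noise
    }

    makeCounts <- function(k) {
        idx <- which(kingdom == k)
        dr <- scenario@depthRange[[k]]
        counts <- sapply(meta$sample_id, function(s) {
            depth <- floor(runif(1, dr[1], dr[2] + 1))
            drop(rmultinom(1, depth, softmax(latent[idx, s])))
        })
        rownames(counts) <- ids[idx]
        counts
    }
    cb <- makeCounts("bacteria")
    cf <- makeCounts("fungi")

    tax <- syntheticTaxonomy(scenario, ids, kingdom)

    pairs <- do.call(rbind, lapply(seq_along(scenario@plantedBlocks),
        function(i) {
            b <- scenario@plantedBlocks[[i]]
            if (length(b$members) < 2) return(NULL)
            pr <- t(combn(sort(b$members), 2))
            data.frame(feature_a = pr[, 1], feature_b = pr[, 2],
                       r = b$r, sign = sign(b$r),
                       groups = paste(b$groups, collapse = ";"),
                       block = i, stringsAsFactors = FALSE)
        }))
    if (is.null(pairs))
        pairs <- data.frame(feature_a = character(), feature_b = character(),
                            r = numeric(), sign = numeric(),
                            groups = character(), block = integer())
    ## keep each unordered pair once (overlapping blocks: first wins)
    pairs <- pairs[!duplicated(pairs[, c("feature_a", "feature_b")]), ]

    mkExp <- function(counts, k)
        MicrobiomeExperiment(counts,
            taxonomy = tax[rownames(counts), TAXONOMY_RANKS],
            metadata = meta, rank = "Genus", kingdom = k)

    list(bacteria = mkExp(cb, "bacteria"),
         fungi = mkExp(cf, "fungi"),
         taxonomy = tax, metadata = meta,
         truth = list(pairs = pairs, centroids = cent, log = repair_log))
}

## Invent a nested 7-rank taxonomy for the synthetic genera. A fraction of
## genera is left unassigned below family or class so the fill-down stage
## has realistic work to do; species is never assigned (as is typical for
## amplicon data).
syntheticTaxonomy <- function(scenario, ids, kingdom) {
    tax <- data.frame(row.names = ids)
    tax$Kingdom <- ifelse(kingdom == "bacteria", "Bacteria", "Fungi")
    for (r in TAXONOMY_RANKS[-1]) tax[[r]] <- NA_character_
    for (k in c("bacteria", "fungi")) {
        idx <- which(kingdom == k)
        n <- length(idx)
        fam <- ceiling(seq_len(n) / 3)        # ~3 genera per family
        ord <- ceiling(fam / 2)
        cls <- ceiling(ord / 2)
        phy <- ceiling(cls / 2)
        pre <- if (k == "bacteria") "B" else "F"
        tax$Phylum[idx] <- sprintf("%sphylum%02d", pre, phy)
        tax$Class[idx] <- sprintf("%sclass%02d", pre, cls)
        tax$Order[idx] <- sprintf("%sorder%02d", pre, ord)
        tax$Family[idx] <- sprintf("%sfamily%02d", pre, fam)
        tax$Genus[idx] <- sprintf("%sgenus%03d", pre, seq_len(n))
    }
    tax$Species <- NA_character_
    ## truncate ~10% of genera at family, ~5% at class
    n <- length(ids)
    cut_fam <- sample(n, max(0, round(0.10 * n)))
    tax$Genus[cut_fam] <- NA_character_
    cut_cls <- sample(setdiff(seq_len(n), cut_fam), max(0, round(0.05 * n)))
    tax$Genus[cut_cls] <- NA_character_
    tax$Order[cut_cls] <- NA_character_
    tax$Family[cut_cls] <- NA_character_
    tax
}

#' Expand a genus-level table to synthetic sequence variants
#'
#' Splits each genus's counts across a Poisson-distributed number of
#' sequence variants (SVs) using per-genus Dirichlet weights, assigns SV
#' lengths around a modal contig length with a configurable fraction of
#' length outliers, optionally forces a fraction of SVs to be rare
#' (total reads below 100), and appends a configured number of
#' contaminant SVs flagged as negative-control-derived. Produces the
#' fixtures the SV-level quality filters operate on.
#'
#' @param x genus-level \linkS4class{MicrobiomeExperiment} for one kingdom.
#' @param scenario the \linkS4class{SyntheticScenario} holding
#'   \code{svExpansion} parameters.
#' @param seed optional seed (defaults to the scenario seed + 1).
#' @return an SV-level \linkS4class{MicrobiomeExperiment} whose rowData
#'   carries taxonomy, SV \code{length} (bp) and logical \code{control}
#'   flags.
#' @export
expandToSVLevel <- function(x, scenario, seed = scenario@seed + 1L) {
    sv <- scenario@svExpansion
    set.seed(seed)
    m <- countMatrix(x)
    tax <- taxonomy(x)
    nG <- nrow(m)
    nsv <- 1L + rpois(nG, max(0, sv$meanSV - 1))
    rows <- vector("list", nG)
    svtax <- vector("list", nG)
    for (g in seq_len(nG)) {
        k <- nsv[g]
        w <- rgamma(k, 1)
        w <- w / sum(w)
        split <- vapply(m[g, ], function(cnt) drop(rmultinom(1, cnt, w)),
                        numeric(k))
        if (k == 1) split <- matrix(split, nrow = 1)
        rownames(split) <- if (k == 1) rownames(m)[g] else
            sprintf("%s_sv%02d", rownames(m)[g], seq_len(k))
        rows[[g]] <- split
        svtax[[g]] <- tax[rep(g, k), , drop = FALSE]
    }
    counts <- do.call(rbind, rows)
    colnames(counts) <- colnames(m)
    tax_sv <- do.call(rbind, svtax)
    rownames(tax_sv) <- rownames(counts)
    nSV <- nrow(counts)

    lengths <- pmax(1, round(rnorm(nSV, sv$lengthMode, sv$lengthSd)))
    nOut <- round(sv$outlierFrac * nSV)
    if (nOut > 0) {
        out <- sample(nSV, nOut)
        lengths[out] <- round(runif(nOut, sv$outlierRange[1],
                                    sv$outlierRange[2]))
    }
    control <- rep(FALSE, nSV)

    nRare <- round(sv$rareFrac * nSV)
    if (nRare > 0) {
        rare <- sample(nSV, nRare)
        for (i in rare) {
            tot <- sum(counts[i, ])
            if (tot >= 100) {
                newtot <- sample(99, 1)
                counts[i, ] <- rarefyVector(counts[i, ], newtot)
            }
        }
    }

    nCon <- sv$contaminants
    if (nCon > 0) {
        con <- t(vapply(seq_len(nCon),
                        function(i) rpois(ncol(counts), 5), numeric(ncol(counts))))
        rownames(con) <- sprintf("contam_sv%02d", seq_len(nCon))
        counts <- rbind(counts, con)
        ctax <- data.frame(Kingdom = rep(tax_sv$Kingdom[1], nCon))
        for (r in TAXONOMY_RANKS[-1]) ctax[[r]] <- NA_character_
        rownames(ctax) <- rownames(con)
        tax_sv <- rbind(tax_sv, ctax)
        lengths <- c(lengths, pmax(1, round(rnorm(nCon, sv$lengthMode,
                                                  sv$lengthSd))))
        control <- c(control, rep(TRUE, nCon))
    }

    meta <- as.data.frame(SummarizedExperiment::colData(x))
    meta$sample_id <- rownames(meta)
    MicrobiomeExperiment(counts, taxonomy = tax_sv, metadata = meta,
        attributes = data.frame(length = lengths, control = control),
        rank = "SV",
        kingdom = unname(kingdomMap(x)[1]))
}
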