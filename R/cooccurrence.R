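## Average ranks along rows of a matrix.
rowRanks_ <- function(m) t(apply(m, 1, rank, ties.method = "average"))

## Spearman rho of all row pairs: rank each feature across samples, then
## Pearson correlation of the centred rank vectors via crossprod.
spearmanMatrix <- function(m) {
    R <- rowRanks_(m)
    R <- R - rowMeans(R)
    ss <- sqrt(rowSums(R^2))
    C <- tcrossprod(R / ss)
    C[C > 1] <- 1
    C[C < -1] <- -1
    C
}

## two-sided p by the t approximation with df = n - 2
spearmanPvalue <- function(rho, n) {
    tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Spearman co-occurrence matrix for one treatment group
#'
#' Computes, for every unordered pair of features across the given
#' samples, the Spearman rank correlation (average ranks for ties) and a
#' two-sided p-value from the t approximation with \eqn{n - 2} degrees of
#' freedom. Features with zero variance (identical counts in every
#' sample) have undefined rank correlations; they are excluded from pair
#' enumeration and listed in the result. For very small groups
#' (\eqn{n \le 9}) exact permutation p-values over all \eqn{n!} sample
#' orderings are available.
#'
#' @param x a merged cross-kingdom \linkS4class{MicrobiomeExperiment} (or
#'   plain count matrix with a \code{kingdomMap} supplied).
#' @param samples optional character vector restricting to one treatment
#'   group's samples.
#' @param group label recorded in the result.
#' @param kingdoms optional named kingdom vector when \code{x} is a bare
#'   matrix.
#' @param exactP compute exact permutation p-values (only allowed for
#'   groups of at most 9 samples).
#' @return a \linkS4class{CooccurrenceResult}.
#' @export
spearmanCooccurrence <- function(x, samples = NULL, group = "all",
                                 kingdoms = NULL, exactP = FALSE) {
    if (methods::is(x, "MicrobiomeExperiment")) {
        kingdoms <- kingdomMap(x)
        m <- countMatrix(x)
    } else m <- as.matrix(x)
    if (!is.null(samples)) m <- m[, samples, drop = FALSE]
    if (nrow(m) == 0) stop("empty table")
    n <- ncol(m)
    if (n < 4) stop("need at least 4 samples, got ", n)
    constant <- apply(m, 1, function(z) max(z) == min(z))
    excluded <- rownames(m)[constant]
    m <- m[!constant, , drop = FALSE]
    if (nrow(m) < 2) stop("fewer than 2 non-constant features")
    rho <- spearmanMatrix(m)
    if (exactP) {
        if (n > 9) stop("exact permutation p only supported for n <= 9")
        p <- exactSpearmanP(m)
    } else {
        p <- spearmanPvalue(rho, n)
    }
    diag(p) <- NA_real_
    diag(rho) <- 1
    km <- if (is.null(kingdoms))
        setNames(rep(NA_character_, nrow(m)), rownames(m)) else
        kingdoms[rownames(m)]
    methods::new("CooccurrenceResult", rho = rho, p = p,
                 kingdom = setNames(as.character(km), rownames(m)),
                 nSamples = as.integer(n), group = as.character(group),
                 excluded = excluded)
}

## Exact two-sided permutation p-values for all pairs: the null
## distribution of rho is obtained by enumerating every ordering of one
## member of the pair (n! orderings, n <= 9).
exactSpearmanP <- function(m) {
    n <- ncol(m)
    R <- rowRanks_(m)
    perms <- allPermutations(n)
    nf <- nrow(m)
    p <- matrix(NA_real_, nf, nf, dimnames = list(rownames(m), rownames(m)))
    rhoPair <- function(a, b) {
        ca <- a - mean(a); cb <- b - mean(b)
        sum(ca * cb) / sqrt(sum(ca^2) * sum(cb^2))
    }
    for (i in seq_len(nf - 1)) for (j in (i + 1):nf) {
        obs <- rhoPair(R[i, ], R[j, ])
        null <- vapply(perms, function(pm) rhoPair(R[i, pm], R[j, ]),
                       numeric(1))
        pv <- sum(abs(null) >= abs(obs) - 1e-12) / length(null)
        p[i, j] <- p[j, i] <- max(pv, .Machine$double.xmin)
    }
    p
}

#' Tiered interaction counts for one treatment group
#'
#' Summarizes a co-occurrence matrix the way co-occurrence analyses
#' typically tabulate network strength: the number of unordered feature
#' pairs with p below \code{alpha} (significant interactions), and within
#' the significant set, the numbers with \eqn{|\rho|} above the moderate
#' and strong thresholds and with \eqn{\rho} above the strong threshold
#' (strong positive). Percentages are relative to the significant count,
#' rounded to the nearest integer (NA when nothing is significant). The
#' tiers are nested by construction.
#'
#' @param result a \linkS4class{CooccurrenceResult}.
#' @param alpha significance level for the first tier.
#' @param moderate,strong \eqn{|\rho|} thresholds, 0 < moderate < strong
#'   < 1.
#' @return data.frame of class \code{"networkSummary"} with one row:
#'   counts \code{n_significant}, \code{n_moderate}, \code{n_strong},
#'   \code{n_strong_positive} and the corresponding percentages.
#' @export
tieredCounts <- function(result, alpha = 0.05, moderate = 0.5,
                         strong = 0.75) {
    stopifnot(moderate > 0, strong < 1, moderate < strong)
    ut <- upper.tri(result@rho)
    rho <- result@rho[ut]
    p <- result@p[ut]
    ok <- !is.na(rho) & !is.na(p)
    rho <- rho[ok]; p <- p[ok]
    sig <- p < alpha
    nsig <- sum(sig)
    nmod <- sum(sig & abs(rho) > moderate)
    nstr <- sum(sig & abs(rho) > strong)
    npos <- sum(sig & rho > strong)
    out <- data.frame(
        group = result@group,
        n_pairs = length(rho),
        n_significant = nsig,
        n_moderate = nmod,
        n_strong = nstr,
        n_strong_positive = npos,
        pct_moderate = interactionPercent(nmod, nsig),
        pct_strong = interactionPercent(nstr, nsig),
        pct_strong_positive = interactionPercent(npos, nsig),
        stringsAsFactors = FALSE)
    class(out) <- c("networkSummary", "data.frame")
    out
}

#' Percentage of the significant interactions falling in a tier
#'
#' \code{round(100 * tier / nSignificant)} to the nearest integer; NA when
#' the significant count is zero (rendered blank in formatted tables).
#'
#' @param tier tier count.
#' @param nSignificant significant-pair count.
#' @return integer percentage or NA.
#' @export
interactionPercent <- function(tier, nSignificant) {
    if (nSignificant == 0) return(NA_integer_)
    as.integer(round(100 * tier / nSignificant))
}

#' Render tiered counts as a publication-style interaction table
#'
#' One row per treatment group; tier columns show "count (pct\%)" with the
#' percentage relative to the significant count.
#'
#' @param summaries a \code{networkSummary} data.frame (rows from
#'   \code{\link{tieredCounts}}, possibly rbind-ed).
#' @return data.frame of formatted strings.
#' @export
formatInteractionTable <- function(summaries) {
    fmt <- function(cnt, pct)
        ifelse(is.na(pct), as.character(cnt),
               sprintf("%d (%d%%)", cnt, pct))
    data.frame(
        Treatment = summaries$group,
        `Number of interactions` = as.character(summaries$n_significant),
        `abs(rho) > 0.50` = fmt(summaries$n_moderate, summaries$pct_moderate),
        `abs(rho) > 0.75` = fmt(summaries$n_strong, summaries$pct_strong),
        `rho > 0.75` = fmt(summaries$n_strong_positive,
                           summaries$pct_strong_positive),
        check.names = FALSE, stringsAsFactors = FALSE)
}

#' Build a co-occurrence network from significant strong pairs
#'
#' Edges are unordered feature pairs with p below \code{alpha} and
#' \eqn{|\rho|} above \code{rhoThreshold}, signed by the direction of the
#' correlation; nodes are the features incident to at least one edge,
#' labeled by kingdom.
#'
#' @param result a \linkS4class{CooccurrenceResult}.
#' @param alpha significance level.
#' @param rhoThreshold edge strength threshold in (0, 1).
#' @return list of class \code{"coocNetwork"}: \code{nodes} (data.frame
#'   id/kingdom), \code{edges} (data.frame feature_a, feature_b, rho, p,
#'   sign, kingdom_a, kingdom_b), \code{threshold}, \code{alpha},
#'   \code{group}.
#' @export
buildNetwork <- function(result, alpha = 0.05, rhoThreshold = 0.75) {
    stopifnot(rhoThreshold > 0, rhoThreshold < 1)
    ids <- rownames(result@rho)
    ut <- which(upper.tri(result@rho), arr.ind = TRUE)
    rho <- result@rho[ut]
    p <- result@p[ut]
    keep <- !is.na(rho) & !is.na(p) & p < alpha & abs(rho) > rhoThreshold
    km <- result@kingdom
    edges <- data.frame(
        feature_a = ids[ut[keep, 1]],
        feature_b = ids[ut[keep, 2]],
        rho = rho[keep], p = p[keep],
        sign = ifelse(rho[keep] > 0, "positive", "negative"),
        kingdom_a = unname(km[ids[ut[keep, 1]]]),
        kingdom_b = unname(km[ids[ut[keep, 2]]]),
        stringsAsFactors = FALSE)
    nid <- sort(unique(c(edges$feature_a, edges$feature_b)))
    nodes <- data.frame(id = nid, kingdom = unname(km[nid]),
                        stringsAsFactors = FALSE)
    structure(list(nodes = nodes, edges = edges,
                   threshold = rhoThreshold, alpha = alpha,
                   group = result@group),
              class = "coocNetwork")
}

#' Summary metrics of a co-occurrence network
#'
#' @param net a \code{coocNetwork} from \code{\link{buildNetwork}}.
#' @return list: \code{n_edges}, \code{n_nodes},
#'   \code{prop_positive} (NA for an empty network),
#'   \code{n_bacteria_bacteria}, \code{n_fungus_fungus},
#'   \code{n_cross_kingdom}, \code{max_degree}, \code{mean_degree}.
#' @export
networkSummaryStats <- function(net) {
    e <- net$edges
    if (nrow(e) == 0)
        return(list(n_edges = 0L, n_nodes = 0L, prop_positive = NA_real_,
                    n_bacteria_bacteria = 0L, n_fungus_fungus = 0L,
                    n_cross_kingdom = 0L, max_degree = 0,
                    mean_degree = 0))
    deg <- table(c(e$feature_a, e$feature_b))
    bb <- sum(e$kingdom_a == "bacteria" & e$kingdom_b == "bacteria")
    ff <- sum(e$kingdom_a == "fungi" & e$kingdom_b == "fungi")
    list(n_edges = nrow(e), n_nodes = nrow(net$nodes),
         prop_positive = mean(e$sign == "positive"),
         n_bacteria_bacteria = bb, n_fungus_fungus = ff,
         n_cross_kingdom = nrow(e) - bb - ff,
         max_degree = max(deg), mean_degree = mean(deg))
}

#' Export a co-occurrence network
#'
#' \code{writeEdgeList} writes the edge table as TSV;
#' \code{exportGraphML} writes GraphML via \pkg{igraph} for external
#' layout/rendering.
#'
#' @param net a \code{coocNetwork}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeEdgeList <- function(net, path) {
    write.table(net$edges, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' @rdname writeEdgeList
#' @export
exportGraphML <- function(net, path) {
    g <- igraph::graph_from_data_frame(
        net$edges[, c("feature_a", "feature_b", "rho", "p", "sign")],
        directed = FALSE, vertices = net$nodes)
    igraph::write_graph(g, path, format = "graphml")
    invisible(path)
}
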