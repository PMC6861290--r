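#' Community distance matrix
#'
#' Pairwise sample dissimilarities under one of four metrics:
#' \describe{
#'   \item{bray_curtis}{\eqn{\sum_f |x_f - y_f| / \sum_f (x_f + y_f)},
#'     computed on counts as given (rarefy first if depth bias matters).}
#'   \item{jaccard_binary}{\eqn{1 - |A \cap B| / |A \cup B|} on
#'     presence/absence sets.}
#'   \item{jaccard_quant}{abundance-weighted variant,
#'     \eqn{2 BC / (1 + BC)} where BC is Bray-Curtis.}
#'   \item{jsd}{Jensen-Shannon divergence between relative-abundance
#'     profiles, \eqn{\frac12 KL(p\|m) + \frac12 KL(q\|m)} with
#'     \eqn{m = (p+q)/2}, natural logarithm, \eqn{0\log 0 \equiv 0};
#'     bounded by \eqn{\ln 2}.}
#' }
#'
#' @param x a \linkS4class{MicrobiomeExperiment} or a features-x-samples
#'   matrix.
#' @param metric one of \code{"bray_curtis"}, \code{"jaccard_binary"},
#'   \code{"jaccard_quant"}, \code{"jsd"}.
#' @return a \code{\link[stats]{dist}} over samples with
#'   \code{attr(, "metric")} set.
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(3, 2, 1))
#' distanceMatrix(m, "bray_curtis")  # 1/3
#' @export
distanceMatrix <- function(x, metric = c("bray_curtis", "jaccard_binary",
                                         "jaccard_quant", "jsd")) {
    metric <- match.arg(metric)
    m <- if (methods::is(x, "MicrobiomeExperiment")) countMatrix(x) else
        as.matrix(x)
    if (ncol(m) < 2) stop("need at least 2 samples")
    tot <- colSums(m)
    if (any(tot == 0))
        stop("sample(s) with zero total counts: ",
             paste(colnames(m)[tot == 0], collapse = ", "))
    n <- ncol(m)
    d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
    if (metric == "jsd") {
        p <- sweep(m, 2, tot, "/")
        xlx <- function(v) ifelse(v > 0, v * log(v), 0)
        H <- colSums(xlx(p))                 # negative entropy per sample
        for (i in seq_len(n - 1)) for (j in (i + 1):n) {
            mid <- (p[, i] + p[, j]) / 2
            d[i, j] <- d[j, i] <-
                (H[i] + H[j]) / 2 - sum(xlx(mid))
        }
    } else {
        for (i in seq_len(n - 1)) for (j in (i + 1):n) {
            xi <- m[, i]; xj <- m[, j]
            if (metric == "jaccard_binary") {
                a <- xi > 0; b <- xj > 0
                u <- sum(a | b)
                d[i, j] <- d[j, i] <- if (u == 0) 0 else 1 - sum(a & b) / u
            } else {
                bc <- sum(abs(xi - xj)) / sum(xi + xj)
                d[i, j] <- d[j, i] <-
                    if (metric == "bray_curtis") bc else 2 * bc / (1 + bc)
            }
        }
    }
    out <- stats::as.dist(d)
    attr(out, "metric") <- metric
    out
}

#' Iteratively rarefied species richness
#'
#' Estimates per-sample richness free of depth bias: the table is rarefied
#' (without replacement) to the depth of the shallowest sample, non-zero
#' features are counted per sample, and the procedure is repeated
#' \code{nTrials} times (trial seeds derived from the master seed), with
#' the estimates averaged across trials.
#'
#' @param x a \linkS4class{MicrobiomeExperiment} or count matrix.
#' @param nTrials number of rarefaction trials (>= 1).
#' @param seed master seed.
#' @param depth rarefaction depth; defaults to the minimum sample total.
#' @return data.frame with per-sample \code{mean_richness}, \code{sd},
#'   \code{n_trials}, \code{depth}.
#' @export
iterativeRichness <- function(x, nTrials = 100L, seed = 1L, depth = NULL) {
    m <- if (methods::is(x, "MicrobiomeExperiment")) countMatrix(x) else
        as.matrix(x)
    if (nTrials < 1) stop("nTrials must be >= 1")
    tot <- colSums(m)
    if (any(tot == 0))
        stop("sample(s) with zero total counts: ",
             paste(colnames(m)[tot == 0], collapse = ", "))
    if (is.null(depth)) depth <- min(tot)
    rich <- matrix(NA_real_, nTrials, ncol(m))
    for (t in seq_len(nTrials)) {
        set.seed(childSeed(seed, paste0("richness", t)))
        for (j in seq_len(ncol(m)))
            rich[t, j] <- sum(rarefyVector(m[, j], min(depth, tot[j])) > 0)
    }
    data.frame(sample_id = colnames(m),
               mean_richness = colMeans(rich),
               sd = apply(rich, 2, sd),
               n_trials = nTrials, depth = depth,
               row.names = colnames(m))
}

#' Write / read a distance matrix as square TSV
#'
#' @param d a \code{dist} object.
#' @param path file path.
#' @return \code{readDistanceMatrix} returns a \code{dist}.
#' @export
writeDistanceMatrix <- function(d, path) {
    m <- as.matrix(d)
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeDistanceMatrix
#' @export
readDistanceMatrix <- function(path) {
    df <- read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1])
    rownames(m) <- df[[1]]
    stats::as.dist(m)
}
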