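## Sum of squares decomposition sensu Anderson (2001) from a squared
## distance matrix and group labels.
permanovaSS <- function(D2, groups) {
    n <- nrow(D2)
    ss_total <- sum(D2[upper.tri(D2)]) / n
    ss_within <- 0
    for (g in unique(groups)) {
        idx <- which(groups == g)
        sub <- D2[idx, idx, drop = FALSE]
        ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
    c(total = ss_total, within = ss_within, between = ss_total - ss_within)
}

#' One-way PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix:
#' total sum of squares \eqn{SS_T = \frac1n \sum_{i<j} d_{ij}^2}, within-
#' group \eqn{SS_W = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2},
#' pseudo-F = \eqn{[SS_A/(a-1)] / [SS_W/(n-a)]} with \eqn{SS_A = SS_T -
#' SS_W}. The null distribution is built by permuting group labels; the
#' reported p uses the add-one correction \eqn{(\#\{F^\pi \ge F\} + 1) /
#' (n_{perm} + 1)} so p is never zero. When
#' \code{exhaustiveIfFeasible} and the number of distinct label
#' assignments is at most \code{nPermutations}, all assignments are
#' enumerated and p is the exact fraction with \eqn{F^\pi \ge F}.
#' With univariate Euclidean distances the pseudo-F equals the classical
#' one-way ANOVA F.
#'
#' @param d a \code{dist} or symmetric distance matrix.
#' @param groups factor/character of group labels, one per sample.
#' @param nPermutations number of label permutations.
#' @param seed integer seed.
#' @param exhaustiveIfFeasible enumerate all distinct assignments when
#'   their count does not exceed \code{nPermutations}.
#' @return list of class \code{"permanova"}: \code{pseudo_F},
#'   \code{R_squared}, \code{p_value}, \code{df_between},
#'   \code{df_within}, \code{SS_between}, \code{SS_within},
#'   \code{SS_total}, \code{n_permutations}, \code{exhaustive}.
#' @export
permanova <- function(d, groups, nPermutations = 999L, seed = 1L,
                      exhaustiveIfFeasible = FALSE) {
    D <- as.matrix(d)
    n <- nrow(D)
    groups <- as.character(groups)
    if (length(groups) != n) stop("one group label per sample required")
    tb <- table(groups)
    if (length(tb) < 2 || any(tb < 2))
        stop("need >= 2 groups with >= 2 samples each")
    D2 <- D^2
    if (sum(D2) == 0) stop("degenerate distance matrix: all distances zero")
    a <- length(tb)
    ss <- permanovaSS(D2, groups)
    Fobs <- (ss["between"] / (a - 1)) / (ss["within"] / (n - a))

    permF <- function(g) {
        s <- permanovaSS(D2, g)
        (s["between"] / (a - 1)) / (s["within"] / (n - a))
    }
    nAssign <- nDistinctAssignments(groups)
    exhaustive <- exhaustiveIfFeasible && nAssign <= nPermutations
    eps <- 1e-12 * max(1, abs(Fobs))
    if (exhaustive) {
        assigns <- multisetPermutations(groups)
        Fs <- vapply(assigns, permF, numeric(1))
        p <- sum(Fs >= Fobs - eps) / length(Fs)
        nperm <- length(Fs)
    } else {
        set.seed(seed)
        Fs <- vapply(seq_len(nPermutations),
                     function(i) permF(sample(groups)), numeric(1))
        p <- (sum(Fs >= Fobs - eps) + 1) / (nPermutations + 1)
        nperm <- nPermutations
    }
    structure(list(
        pseudo_F = unname(Fobs),
        R_squared = unname(ss["between"] / ss["total"]),
        p_value = p,
        df_between = a - 1L, df_within = n - a,
        SS_between = unname(ss["between"]),
        SS_within = unname(ss["within"]),
        SS_total = unname(ss["total"]),
        n_permutations = nperm, exhaustive = exhaustive),
        class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
    cat(sprintf("PERMANOVA: F(%d,%d) = %.4f, R2 = %.4f, p = %.4g (%s, %d permutations)\n",
                x$df_between, x$df_within, x$pseudo_F, x$R_squared,
                x$p_value,
                if (x$exhaustive) "exhaustive" else "sampled",
                x$n_permutations))
    invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Correlates the upper-triangle vectors of two distance matrices over the
#' same samples; the null distribution is built by simultaneously
#' permuting the rows and columns of the second matrix. The p-value is
#' one-sided for positive association, with the add-one correction; if
#' \code{exhaustiveIfFeasible} and \eqn{n! \le} \code{nPermutations}, all
#' relabelings are enumerated exactly.
#'
#' @param d1,d2 \code{dist} objects or symmetric matrices with identical
#'   sample sets and order.
#' @param nPermutations number of matrix permutations.
#' @param seed integer seed.
#' @param method correlation method, \code{"pearson"} (default) or
#'   \code{"spearman"}.
#' @param exhaustiveIfFeasible enumerate all n! relabelings when feasible.
#' @return list of class \code{"mantel"}: \code{r}, \code{p_value},
#'   \code{n_permutations}, \code{method}, \code{exhaustive}.
#' @export
mantelTest <- function(d1, d2, nPermutations = 999L, seed = 1L,
                       method = c("pearson", "spearman"),
                       exhaustiveIfFeasible = FALSE) {
    method <- match.arg(method)
    M1 <- as.matrix(d1)
    M2 <- as.matrix(d2)
    if (!is.null(rownames(M1)) && !is.null(rownames(M2)) &&
        !identical(rownames(M1), rownames(M2)))
        stop("sample sets/order differ between the two matrices")
    n <- nrow(M1)
    if (n < 4) stop("need at least 4 samples")
    ut <- upper.tri(M1)
    v1 <- M1[ut]
    if (sd(v1) == 0 || sd(M2[ut]) == 0)
        stop("zero-variance distance vector")
    robs <- cor(v1, M2[ut], method = method)
    rperm <- function(p) cor(v1, M2[p, p][ut], method = method)
    nfact <- factorial(n)
    exhaustive <- exhaustiveIfFeasible && nfact <= nPermutations
    eps <- 1e-12
    if (exhaustive) {
        perms <- allPermutations(n)
        rs <- vapply(perms, rperm, numeric(1))
        p <- sum(rs >= robs - eps) / length(rs)
        nperm <- length(rs)
    } else {
        set.seed(seed)
        rs <- vapply(seq_len(nPermutations),
                     function(i) rperm(sample.int(n)), numeric(1))
        p <- (sum(rs >= robs - eps) + 1) / (nPermutations + 1)
        nperm <- nPermutations
    }
    structure(list(r = unname(robs), p_value = p, n_permutations = nperm,
                   method = method, exhaustive = exhaustive),
              class = "mantel")
}

#' @export
print.mantel <- function(x, ...) {
    cat(sprintf("Mantel: r = %.4f, p = %.4g (%s, %d permutations, %s)\n",
                x$r, x$p_value,
                if (x$exhaustive) "exhaustive" else "sampled",
                x$n_permutations, x$method))
    invisible(x)
}

## Kruskal stress-1 with monotone (isotonic) regression of configuration
## distances on dissimilarity rank order.
nmdsStress <- function(dvec, ord, confd) {
    fit <- stats::isoreg(confd[ord])
    dhat <- numeric(length(confd))
    dhat[ord] <- fit$yf
    list(stress = sqrt(sum((confd - dhat)^2) / sum(confd^2)), dhat = dhat)
}

#' Non-metric multidimensional scaling
#'
#' Kruskal NMDS: finds a k-dimensional configuration whose inter-point
#' distances are, as nearly as possible, a monotone function of the input
#' dissimilarities. Stress-1 \eqn{\sqrt{\sum (d - \hat d)^2 / \sum d^2}}
#' is minimized by alternating pool-adjacent-violators monotone
#' regression (the \eqn{\hat d}) with a Guttman-transform configuration
#' update. The best of \code{nRestarts} random initializations plus one
#' classical-MDS initialization is returned; coordinates are centered at
#' the origin. Deterministic under a fixed seed.
#'
#' @param d a \code{dist} or symmetric dissimilarity matrix.
#' @param k embedding dimension (>= 1; fewer than n samples).
#' @param nRestarts number of random restarts.
#' @param seed integer seed.
#' @param maxIter maximum majorization iterations per start.
#' @param tol convergence tolerance on the change in stress.
#' @return list of class \code{"nmds"}: \code{points} (n x k matrix),
#'   \code{stress}, \code{converged}, \code{n_restarts}, \code{seed}.
#' @export
nmds <- function(d, k = 2L, nRestarts = 20L, seed = 1L, maxIter = 500L,
                 tol = 1e-6) {
    Dm <- as.matrix(d)
    n <- nrow(Dm)
    if (k < 1 || n <= k) stop("need k >= 1 and more samples than dimensions")
    dvec <- Dm[upper.tri(Dm)]
    ord <- order(dvec)
    set.seed(seed)
    inits <- c(list(cmdscale(Dm, k = min(k, n - 1))),
               lapply(seq_len(nRestarts),
                      function(i) matrix(rnorm(n * k), n, k)))
    inits[[1]] <- cbind(inits[[1]],
                        matrix(0, n, k - ncol(inits[[1]])))  # pad if needed
    best <- NULL
    for (X in inits) {
        conv <- FALSE
        sPrev <- Inf
        st <- list(stress = Inf)
        for (it in seq_len(maxIter)) {
            confD <- as.matrix(dist(X))
            confd <- confD[upper.tri(confD)]
            if (all(confd == 0)) break
            st <- nmdsStress(dvec, ord, confd)
            if (abs(sPrev - st$stress) < tol) { conv <- TRUE; break }
            sPrev <- st$stress
            ## Guttman transform with dhat as target distances
            Dhat <- matrix(0, n, n)
            Dhat[upper.tri(Dhat)] <- st$dhat
            Dhat <- Dhat + t(Dhat)
            B <- -Dhat / (confD + diag(n))     # guard the zero diagonal
            B[confD == 0] <- 0
            diag(B) <- 0
            diag(B) <- -rowSums(B)
            X <- (B %*% X) / n
        }
        if (is.null(best) || st$stress < best$stress)
            best <- list(X = X, stress = st$stress, converged = conv)
    }
    pts <- scale(best$X, scale = FALSE)
    attr(pts, "scaled:center") <- NULL
    rownames(pts) <- rownames(Dm)
    colnames(pts) <- paste0("NMDS", seq_len(k))
    if (!best$converged)
        warning("NMDS did not converge in any restart")
    structure(list(points = pts, stress = best$stress,
                   converged = best$converged,
                   n_restarts = nRestarts, seed = seed),
              class = "nmds")
}

#' @export
print.nmds <- function(x, ...) {
    cat(sprintf("NMDS (%d points, k = %d): stress = %.6f%s\n",
                nrow(x$points), ncol(x$points), x$stress,
                if (x$converged) "" else " (not converged)"))
    invisible(x)
}
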