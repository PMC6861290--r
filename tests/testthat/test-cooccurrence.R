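## Small count fixture with named features spanning both kingdoms.
coocFixture <- function(n = 12, seed = 1) {
    set.seed(seed)
    m <- matrix(rpois(5 * n, 20), nrow = 5,
                dimnames = list(c("bacteria|g1", "bacteria|g2",
                                  "bacteria|g3", "fungi|g1", "fungi|g2"),
                                paste0("s", seq_len(n))))
    km <- setNames(c(rep("bacteria", 3), rep("fungi", 2)), rownames(m))
    list(m = m, km = km)
}

test_that("perfect monotone pairs give rho of +1 and -1", {
    m <- rbind(up = 1:8, alsoUp = (1:8)^2, down = 8:1)
    rownames(m) <- c("up", "alsoUp", "down")
    colnames(m) <- paste0("s", 1:8)
    res <- spearmanCooccurrence(m, group = "g")
    expect_equal(res@rho["up", "alsoUp"], 1)
    expect_equal(res@rho["up", "down"], -1)
    expect_equal(res@rho["alsoUp", "down"], -1)
})

test_that("tied data match the rank-then-Pearson oracle and stats::cor", {
    x <- c(1, 2, 2, 4)
    y <- c(3, 1, 1, 2)
    m <- rbind(x = x, y = y)
    colnames(m) <- paste0("s", 1:4)
    res <- spearmanCooccurrence(m, group = "g")
    oracle <- cor(rank(x), rank(y))                 # rank-then-Pearson
    expect_equal(res@rho["x", "y"], oracle, tolerance = 1e-12)
    expect_equal(res@rho["x", "y"], cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
})

test_that("whole-matrix rho agrees with stats::cor(method = 'spearman')", {
    fx <- coocFixture(n = 15, seed = 3)
    res <- spearmanCooccurrence(fx$m, kingdoms = fx$km, group = "g")
    oracle <- cor(t(fx$m), method = "spearman")
    expect_equal(unname(res@rho), unname(oracle), tolerance = 1e-12)
})

test_that("asymptotic p-values match the t approximation used by cor.test", {
    fx <- coocFixture(n = 20, seed = 4)
    res <- spearmanCooccurrence(fx$m, kingdoms = fx$km, group = "g")
    ct <- suppressWarnings(
        cor.test(fx$m[1, ], fx$m[2, ], method = "spearman", exact = FALSE))
    expect_equal(res@p["bacteria|g1", "bacteria|g2"], ct$p.value,
                 tolerance = 1e-9)
})

test_that("exact permutation p at n = 6 matches full enumeration", {
    set.seed(5)
    ## tie-free vectors so cor.test's exact p is a valid oracle
    m <- rbind(a = sample(100, 6), b = sample(100, 6), c = sample(100, 6))
    colnames(m) <- paste0("s", 1:6)
    res <- spearmanCooccurrence(m, group = "g", exactP = TRUE)
    for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
        ct <- cor.test(m[pair[1], ], m[pair[2], ], method = "spearman",
                       exact = TRUE)
        expect_equal(res@p[pair[1], pair[2]], ct$p.value,
                     tolerance = 1e-12)
    }
    expect_error(spearmanCooccurrence(coocFixture()$m, exactP = TRUE),
                 "n <= 9")
})

test_that("zero-variance features are excluded and reported", {
    fx <- coocFixture(n = 10, seed = 6)
    fx$m["fungi|g2", ] <- 7
    res <- spearmanCooccurrence(fx$m, kingdoms = fx$km, group = "g")
    expect_identical(res@excluded, "fungi|g2")
    expect_false("fungi|g2" %in% rownames(res@rho))
    expect_error(spearmanCooccurrence(fx$m[, 1:3], group = "g"),
                 "at least 4")
})

test_that("tiered counts enumerate the significance and strength tiers correctly", {
    ## 4 features, 6 pairs with hand-set rho/p; verified by hand:
    ## pairs (1,2) rho .9 p .01 | (1,3) rho .6 p .02 | (1,4) rho -.8 p .03
    ##       (2,3) rho .3 p .04 | (2,4) rho .95 p .5 | (3,4) rho -.2 p .9
    rho <- diag(4)
    p <- matrix(NA_real_, 4, 4)
    vals <- list(c(1, 2, .9, .01), c(1, 3, .6, .02), c(1, 4, -.8, .03),
                 c(2, 3, .3, .04), c(2, 4, .95, .5), c(3, 4, -.2, .9))
    for (v in vals) {
        rho[v[1], v[2]] <- rho[v[2], v[1]] <- v[3]
        p[v[1], v[2]] <- p[v[2], v[1]] <- v[4]
    }
    dimnames(rho) <- dimnames(p) <-
        list(paste0("f", 1:4), paste0("f", 1:4))
    res <- methods::new("CooccurrenceResult", rho = rho, p = p,
                        kingdom = setNames(rep("bacteria", 4),
                                           paste0("f", 1:4)),
                        nSamples = 10L, group = "toy",
                        excluded = character())
    tc <- tieredCounts(res, alpha = 0.05, moderate = 0.5, strong = 0.75)
    ## significant: 4 pairs; |rho|>.5 of those: 3; |rho|>.75: 2; rho>.75: 1
    expect_identical(tc$n_significant, 4L)
    expect_identical(tc$n_moderate, 3L)
    expect_identical(tc$n_strong, 2L)
    expect_identical(tc$n_strong_positive, 1L)
    expect_identical(tc$pct_moderate, 75L)
    expect_identical(tc$pct_strong, 50L)
    expect_identical(tc$pct_strong_positive, 25L)
    ## all p = 1: every count zero, percentages blank
    p1 <- p; p1[!is.na(p1)] <- 1
    res1 <- methods::new("CooccurrenceResult", rho = rho, p = p1,
                         kingdom = res@kingdom, nSamples = 10L,
                         group = "toy", excluded = character())
    tc1 <- tieredCounts(res1)
    expect_identical(tc1$n_significant, 0L)
    expect_true(is.na(tc1$pct_strong))
})

test_that("tier counts are nested on arbitrary random inputs", {
    for (i in 1:20) {
        set.seed(i)
        n <- sample(5:30, 1)
        m <- matrix(rpois(n * 12, 10), nrow = n,
                    dimnames = list(paste0("f", seq_len(n)),
                                    paste0("s", 1:12)))
        res <- spearmanCooccurrence(m, group = "g")
        tc <- tieredCounts(res)
        expect_lte(tc$n_strong_positive, tc$n_strong)
        expect_lte(tc$n_strong, tc$n_moderate)
        expect_lte(tc$n_moderate, tc$n_significant)
        expect_lte(tc$n_significant, tc$n_pairs)
    }
})

test_that("counts are invariant to feature order", {
    fx <- coocFixture(n = 14, seed = 9)
    res1 <- tieredCounts(spearmanCooccurrence(fx$m, kingdoms = fx$km,
                                              group = "g"))
    perm <- sample(nrow(fx$m))
    res2 <- tieredCounts(spearmanCooccurrence(fx$m[perm, ],
                                              kingdoms = fx$km,
                                              group = "g"))
    for (col in c("n_significant", "n_moderate", "n_strong",
                  "n_strong_positive"))
        expect_identical(res1[[col]], res2[[col]])
})

test_that("interaction table renders counts with bracketed percentages", {
    tc <- data.frame(group = "demo", n_pairs = 100L, n_significant = 11952L,
                     n_moderate = 11303L, n_strong = 762L,
                     n_strong_positive = 531L,
                     pct_moderate = interactionPercent(11303, 11952),
                     pct_strong = interactionPercent(762, 11952),
                     pct_strong_positive = interactionPercent(531, 11952))
    ft <- formatInteractionTable(tc)
    expect_identical(ft$`abs(rho) > 0.50`, "11303 (95%)")
    expect_identical(ft$`abs(rho) > 0.75`, "762 (6%)")
    expect_identical(ft$`rho > 0.75`, "531 (4%)")
})

test_that("network construction keeps only significant strong pairs with signs", {
    rho <- diag(4)
    p <- matrix(1, 4, 4); diag(p) <- NA
    rho[1, 2] <- rho[2, 1] <- 0.9;  p[1, 2] <- p[2, 1] <- 0.001
    rho[3, 4] <- rho[4, 3] <- -0.85; p[3, 4] <- p[4, 3] <- 0.01
    rho[1, 3] <- rho[3, 1] <- 0.95; p[1, 3] <- p[3, 1] <- 0.2  # not significant
    dimnames(rho) <- dimnames(p) <-
        list(c("bacteria|a", "bacteria|b", "fungi|c", "fungi|d"),
             c("bacteria|a", "bacteria|b", "fungi|c", "fungi|d"))
    res <- methods::new("CooccurrenceResult", rho = rho, p = p,
                        kingdom = setNames(c("bacteria", "bacteria",
                                             "fungi", "fungi"),
                                           rownames(rho)),
                        nSamples = 20L, group = "toy",
                        excluded = character())
    net <- buildNetwork(res, alpha = 0.05, rhoThreshold = 0.75)
    expect_identical(nrow(net$edges), 2L)
    expect_setequal(net$edges$sign, c("positive", "negative"))
    expect_identical(nrow(net$nodes), 4L)
    stats <- networkSummaryStats(net)
    expect_equal(stats$prop_positive, 0.5)
    expect_identical(stats$n_bacteria_bacteria, 1L)
    expect_identical(stats$n_fungus_fungus, 1L)
    expect_identical(stats$n_cross_kingdom, 0L)

    ## nothing passes -> empty network with blank proportion
    resNone <- methods::new("CooccurrenceResult", rho = rho,
                            p = matrix(1, 4, 4,
                                       dimnames = dimnames(p)),
                            kingdom = res@kingdom, nSamples = 20L,
                            group = "toy", excluded = character())
    netNone <- buildNetwork(resNone)
    expect_identical(nrow(netNone$edges), 0L)
    expect_true(is.na(networkSummaryStats(netNone)$prop_positive))
})

test_that("planted strong blocks are recovered as network edges with few false positives", {
    sc <- defaultScenario(
        nSamples = c(mono_A = 100L, mixed_A = 4L, mixed_W = 4L,
                     mono_W = 4L),
        nSoil = 0L,
        nGenera = c(bacteria = 30L, fungi = 10L),
        plantedBlocks = list(
            list(members = c("B001", "B002"), r = 0.95, groups = "mono_A"),
            list(members = c("B003", "F001"), r = -0.95,
                 groups = "mono_A")),
        depthRange = list(bacteria = c(5000, 5000), fungi = c(5000, 5000)),
        seed = 17L)
    sim <- simulateExperiment(sc)
    g <- groupsOf(sim$metadata)
    smp <- names(g)[g == "mono_A"]
    merged <- mergeKingdoms(sim$bacteria, sim$fungi)
    res <- spearmanCooccurrence(merged, samples = smp, group = "mono_A")
    net <- buildNetwork(res, alpha = 0.05, rhoThreshold = 0.75)
    key <- paste(net$edges$feature_a, net$edges$feature_b)
    expect_true("bacteria|B001 bacteria|B002" %in% key)
    expect_true("bacteria|B003 fungi|F001" %in% key)
    expect_identical(net$edges$sign[key == "bacteria|B003 fungi|F001"],
                     "negative")
    ## false edges are a small fraction of all pairs
    nPairs <- choose(nrow(res@rho), 2)
    expect_lte((nrow(net$edges) - 2) / nPairs, 0.05)
})

test_that("variable sequencing depth inflates raw-count correlations; rarefaction restores calibration", {
    ## depth acts as a common positive driver of every feature, so the
    ## null p < 0.05 rate on raw counts exceeds the nominal level, while
    ## the rarefied chain stays near it
    sc <- defaultScenario(
        nSamples = c(mono_A = 30L, mixed_A = 3L, mixed_W = 3L,
                     mono_W = 3L),
        nSoil = 0L, nGenera = c(bacteria = 50L, fungi = 20L),
        seed = 201L)
    sim <- simulateExperiment(sc)
    g <- groupsOf(sim$metadata)
    smp <- names(g)[g == "mono_A"]
    rate <- function(b, f) {
        res <- spearmanCooccurrence(mergeKingdoms(b, f), samples = smp,
                                    group = "null")
        p <- res@p[upper.tri(res@p)]
        mean(p[!is.na(p)] < 0.05)
    }
    raw <- rate(sim$bacteria, sim$fungi)
    rarefied <- rate(rarefy(sim$bacteria, seed = 301L),
                     rarefy(sim$fungi, seed = 401L))
    expect_gt(raw, 0.07)
    expect_lt(rarefied, raw)
    expect_lt(rarefied, 0.08)
})

test_that("edge lists and GraphML exports round-trip through igraph", {
    fx <- coocFixture(n = 20, seed = 11)
    fx$m[2, ] <- fx$m[1, ] + rpois(20, 2)    # force one strong pair
    res <- spearmanCooccurrence(fx$m, kingdoms = fx$km, group = "g")
    net <- buildNetwork(res, alpha = 0.05, rhoThreshold = 0.5)
    expect_gt(nrow(net$edges), 0)
    tsv <- tempfile(fileext = ".tsv")
    writeEdgeList(net, tsv)
    back <- read.delim(tsv)
    expect_identical(nrow(back), nrow(net$edges))
    gml <- tempfile(fileext = ".graphml")
    exportGraphML(net, gml)
    g <- igraph::read_graph(gml, format = "graphml")
    expect_identical(igraph::gsize(g), as.numeric(nrow(net$edges)))
    expect_identical(igraph::vcount(g), as.numeric(nrow(net$nodes)))
})
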