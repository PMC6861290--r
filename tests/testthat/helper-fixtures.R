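## Small in-code fixtures shared across test files.

## A tiny MicrobiomeExperiment with known counts / taxonomy / attributes.
toyExperiment <- function(counts = NULL, ...) {
    if (is.null(counts))
        counts <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3, byrow = TRUE,
                         dimnames = list(paste0("sv", 1:3),
                                         c("s1", "s2")))
    MicrobiomeExperiment(counts, ...)
}

## A fast scenario for simulation-heavy tests: few genera, shallow depths.
smallScenario <- function(..., seed = 11L) {
    defaultScenario(
        nGenera = c(bacteria = 20L, fungi = 8L),
        depthRange = list(bacteria = c(2000, 4000), fungi = c(500, 900)),
        seed = seed, ...)
}

## Group labels of a metadata frame, named by sample id.
groupsOf <- function(meta) setNames(meta$group, meta$sample_id)

## data.frame with single-value recycling plus row names (base data.frame
## refuses row.names when recycling).
taxFrame <- function(..., row.names) {
    df <- data.frame(..., stringsAsFactors = FALSE)
    df <- df[rep(seq_len(nrow(df)), length.out = length(row.names)), ,
             drop = FALSE]
    rownames(df) <- row.names
    df
}

## Sample Spearman rho between two features of a count matrix.
rhoOf <- function(m, a, b) cor(m[a, ], m[b, ], method = "spearman")
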