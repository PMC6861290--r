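## Deterministic child seed: stage name hashed into the master seed so
## individual stages can be re-run in isolation reproducibly. Kept below
## 2^31 - 1.
childSeed <- function(master, stage) {
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
    as.integer((as.numeric(master) * 7919 + h) %% 2147483647)
}

## All distinct permutations of a label multiset (exhaustive tests only;
## callers bound the count before asking).
multisetPermutations <- function(labels) {
    labels <- sort(labels)
    res <- list()
    recurse <- function(prefix, remaining) {
        if (!length(remaining)) {
            res[[length(res) + 1]] <<- prefix
            return(invisible())
        }
        for (u in unique(remaining)) {
            i <- match(u, remaining)
            recurse(c(prefix, u), remaining[-i])
        }
    }
    recurse(character(0), labels)
    res
}

## All permutations of 1..n (n small).
allPermutations <- function(n) {
    if (n == 1) return(list(1L))
    out <- list()
    for (i in seq_len(n)) {
        sub <- allPermutations(n - 1L)
        for (p in sub) {
            q <- c(i, ifelse(p >= i, p + 1L, p))
            out[[length(out) + 1]] <- as.integer(q)
        }
    }
    out
}

## number of distinct assignments of a label multiset
nDistinctAssignments <- function(labels) {
    tb <- table(labels)
    exp(lgamma(length(labels) + 1) - sum(lgamma(tb + 1)))
}
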