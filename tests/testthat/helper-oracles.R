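# Independent oracles, deliberately naive: these re-derive expected values
# by brute force and must stay free of the package code paths they check.

# Double-loop interval-overlap tally of fragments against the two regions.
bruteForceCounts <- function(starts, ends, chroms, model) {
    cS <- GenomicRanges::start(commonRegion(model))
    cE <- GenomicRanges::end(commonRegion(model))
    sS <- GenomicRanges::start(specificRegion(model))
    sE <- GenomicRanges::end(specificRegion(model))
    chr <- as.character(GenomeInfoDb::seqnames(commonRegion(model)))
    n <- c(common = 0L, specific = 0L, spanning = 0L, outside = 0L)
    for (i in seq_along(starts)) {
        if (chroms[i] != chr) { n["outside"] <- n["outside"] + 1L; next }
        hitC <- starts[i] <= cE && ends[i] >= cS
        hitS <- starts[i] <= sE && ends[i] >= sS
        if (hitC && hitS) n["spanning"] <- n["spanning"] + 1L
        else if (hitC) n["common"] <- n["common"] + 1L
        else if (hitS) n["specific"] <- n["specific"] + 1L
        else n["outside"] <- n["outside"] + 1L
    }
    n
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
enumerateMannWhitneyP <- function(a, b) {
    pool <- c(a, b)
    n1 <- length(a)
    idx <- utils::combn(length(pool), n1)
    uOf <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    u0 <- uOf(a, b)
    us <- apply(idx, 2, function(s) uOf(pool[s], pool[-s]))
    pLo <- mean(us <= u0)
    pHi <- mean(us >= u0)
    min(1, 2 * min(pLo, pHi))
}

# Pearson chi-square statistic straight from the definition.
chisqStatistic <- function(tab) {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - E)^2 / E)
}

# Permutation-null p-value for independence in a contingency table.
permutationChisqP <- function(tab, nPerm = 1e4, seed = 1) {
    rows <- rep(seq_len(nrow(tab)), rowSums(tab))
    cols <- rep.int(rep(seq_len(ncol(tab)), nrow(tab)), as.vector(t(tab)))
    obs <- chisqStatistic(tab)
    set.seed(seed)
    hits <- 0L
    for (i in seq_len(nPerm)) {
        t2 <- table(rows, sample(cols))
        if (chisqStatistic(t2) >= obs - 1e-12) hits <- hits + 1L
    }
    hits / nPerm
}

# Spearman rho from the rank formula (mid-ranks, no ties assumed for d^2).
spearmanRho <- function(x, y) {
    rx <- rank(x); ry <- rank(y)
    1 - 6 * sum((rx - ry)^2) / (length(x) * (length(x)^2 - 1))
}
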