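test_that("the printed locus coordinates give the published region lengths", {
    m <- neat1RegionModel()
    L <- regionLengths(m)
    expect_equal(unname(L["common"]), 3735)
    expect_equal(unname(L["specific"]), 19008)
    expect_equal(unname(L["locus"]), 22743)
    expect_equal(round(L[["common"]] / 1000, 1), 3.7)
})

test_that("RegionModel rejects non-adjacent or degenerate regions", {
    expect_error(RegionModel("chr11", 100, 200, 250, 300), "adjacent")
    expect_error(RegionModel("chr11", 100, 200, 201, 150))
})

test_that("fragment classification follows the junction-exclusion rule", {
    m <- neat1RegionModel()
    frags <- alignedFragments(
        chrom = c("chr11", "chr11", "chr11", "chr11", "chr11", "chr11", "chr1"),
        start = c(65423000, 65426500, 65422798, 70000000, 65426533, 65422000, 65423000),
        end   = c(65423300, 65426700, 65422798, 70000300, 65426533, 65423000, 65423300))
    lab <- classifyFragments(frags, m)
    expect_equal(as.character(lab),
                 c("common",    # strictly inside the common region
                   "spanning",  # covers the 65426532|65426533 junction
                   "common",    # 1 bp at the printed common start (inclusive)
                   "outside",   # far downstream on the same contig
                   "specific",  # 1 bp at the specific start
                   "common",    # overhangs the upstream outer boundary
                   "outside"))  # wrong contig
    # exactly one label per fragment, always
    expect_true(all(!is.na(lab)))
})

test_that("counting is conservative and spanning fragments are excluded", {
    m <- neat1RegionModel()
    empty <- countFragments(alignedFragments(character(), integer(), integer()), m)
    expect_equal(unlist(empty[c("rm_common", "rm_specific",
                                "n_spanning_excluded", "rm_total")]),
                 c(rm_common = 0, rm_specific = 0,
                   n_spanning_excluded = 0, rm_total = 0))

    frags <- alignedFragments(
        chrom = rep(c("chr11", "background"), c(17, 3)),
        start = c(rep(65423000, 10), rep(65430000, 5), rep(65426400, 2),
                  rep(1000, 3)),
        end   = c(rep(65423200, 10), rep(65430200, 5), rep(65426700, 2),
                  rep(1300, 3)))
    cnt <- countFragments(frags, m)
    expect_equal(cnt$rm_common, 10)
    expect_equal(cnt$rm_specific, 5)
    expect_equal(cnt$n_spanning_excluded, 2)
    expect_equal(cnt$rm_total, 20)
    expect_equal(cnt$rm_common + cnt$rm_specific + cnt$n_spanning_excluded +
                 cnt$rm_outside, cnt$rm_total)
})

test_that("counting matches a brute-force interval-overlap oracle on random fragments", {
    m <- neat1RegionModel()
    set.seed(42)
    n <- 10000
    chrom <- sample(c("chr11", "background"), n, replace = TRUE, prob = c(0.9, 0.1))
    start <- ifelse(chrom == "chr11",
                    sample(65420000:65450000, n, replace = TRUE),
                    sample(1:1e6, n, replace = TRUE))
    len <- sample(50:600, n, replace = TRUE)
    frags <- alignedFragments(chrom, start, start + len - 1L)
    cnt <- countFragments(frags, m)
    oracle <- bruteForceCounts(start, start + len - 1L, chrom, m)
    expect_equal(cnt$rm_common, unname(oracle["common"]))
    expect_equal(cnt$rm_specific, unname(oracle["specific"]))
    expect_equal(cnt$n_spanning_excluded, unname(oracle["spanning"]))
    expect_equal(cnt$rm_outside, unname(oracle["outside"]))
})

test_that("FPKM follows the printed formula and its scaling laws", {
    expect_equal(fpkm(0, 1e6, 1000), 0)
    expect_equal(fpkm(1000, 1e6, 1000), 1000)
    expect_equal(fpkm(100, 2e6, 3735), 13.387, tolerance = 1e-3 / 13.387)
    # homogeneity: degree 1 in counts, degree -1 in library size
    expect_equal(fpkm(300, 1e6, 2000) * 7, fpkm(7 * 300, 1e6, 2000))
    expect_equal(fpkm(300, 1e6, 2000) / 7, fpkm(300, 7e6, 2000))
    expect_error(fpkm(10, 0, 1000), "rmT")
    expect_error(fpkm(10, 1e6, 0), "lengthBp")
})

test_that("sample quantification applies the specific-region FPKM filter at the stated boundary", {
    m <- neat1RegionModel()
    # zero locus fragments, nonzero library
    bg <- alignedFragments(rep("background", 5), 1:5 * 1000L, 1:5 * 1000L + 299L)
    q0 <- quantifySample("s0", bg, m)
    expect_equal(q0$fpkm_common, 0)
    expect_equal(q0$fpkm_specific, 0)
    expect_true(q0$neat1_1_eligible)

    # engineered FPKM_specific == 1.0 exactly: rm_s * 1e9 = rm_t * L, with
    # the library size passed as RMt (only the locus fragments are loaded)
    rmS <- 297; rmT <- rmS * 1e9 / 19008   # = 15,625,000
    expect_equal(fpkm(rmS, rmT, 19008), 1.0)
    spec <- alignedFragments(rep("chr11", rmS),
                             rep(65430000L, rmS), rep(65430299L, rmS))
    qb <- quantifySample("boundary", spec, m, rmTotal = rmT)
    expect_equal(qb$fpkm_specific, 1.0)
    expect_false(qb$neat1_1_eligible)   # FPKM >= 1.0 is filtered out
    expect_true(is.na(qb$neat1_1_fpkm))
})

test_that("filtering retains exactly the eligible samples, order preserved", {
    q <- data.frame(sample_id = c("a", "b", "c"),
                    neat1_1_eligible = c(TRUE, FALSE, TRUE))
    expect_message(kept <- selectNeat1_1Samples(q), "1 sample")
    expect_equal(kept$sample_id, c("a", "c"))
    expect_equal(attr(kept, "n_removed"), 1)
    allq <- data.frame(sample_id = "a", neat1_1_eligible = TRUE)
    expect_equal(nrow(suppressMessages(selectNeat1_1Samples(allq))), 1)
    noneq <- data.frame(sample_id = "a", neat1_1_eligible = FALSE)
    expect_equal(nrow(suppressMessages(selectNeat1_1Samples(noneq))), 0)
})

test_that("increasing only the specific-region count never rescues an ineligible sample", {
    m <- neat1RegionModel()
    mkFrags <- function(nSpec) {
        alignedFragments(rep(c("chr11", "background"), c(nSpec, 1000)),
                         c(rep(65430000L, nSpec), rep(1000L, 1000)),
                         c(rep(65430299L, nSpec), rep(1299L, 1000)))
    }
    n0 <- 200   # clearly ineligible at this depth
    expect_false(quantifySample("x", mkFrags(n0), m)$neat1_1_eligible)
    for (extra in c(1, 10, 100, 1000))
        expect_false(quantifySample("x", mkFrags(n0 + extra), m)$neat1_1_eligible)
})

test_that("a pure long-isoform library has near-equal FPKM in both regions", {
    sim <- simulateLocusFragments(ReadSimParams(nLong = 6000, nBackground = 1000,
                                                seed = 101))
    q <- quantifySample("long", sim$fragments, neat1RegionModel())
    expect_gt(q$fpkm_specific / q$fpkm_common, 0.9)
    expect_lt(q$fpkm_specific / q$fpkm_common, 1.1)
})

test_that("known per-sample isoform mixtures are filtered according to generator truth", {
    m <- neat1RegionModel()
    set.seed(77)
    nLong <- sample(c(0, 0, 5, 2000), 20, replace = TRUE)
    quants <- do.call(rbind, lapply(seq_along(nLong), function(i) {
        sim <- simulateLocusFragments(ReadSimParams(
            nShort = 500, nLong = nLong[i], nBackground = 2000, seed = 1000 + i))
        quantifySample(paste0("s", i), sim$fragments, m)
    }))
    kept <- suppressMessages(selectNeat1_1Samples(quants))
    # oracle: recompute eligibility from a brute-force tally
    oracleKeep <- vapply(seq_along(nLong), function(i) {
        sim <- simulateLocusFragments(ReadSimParams(
            nShort = 500, nLong = nLong[i], nBackground = 2000, seed = 1000 + i))
        fr <- sim$fragments
        cnt <- bruteForceCounts(GenomicRanges::start(fr), GenomicRanges::end(fr),
                                as.character(GenomeInfoDb::seqnames(fr)), m)
        cnt[["specific"]] * 1e9 / (length(fr) * 19008) < 1.0
    }, logical(1))
    expect_equal(kept$sample_id, paste0("s", which(oracleKeep)))
})

test_that("fragments survive a SAM round trip and unmapped records are tallied", {
    sim <- simulateLocusFragments(ReadSimParams(nShort = 200, nLong = 100,
                                                nBackground = 50, seed = 9))
    sam <- tempfile(fileext = ".sam")
    writeFragmentsSAM(sim$fragments, sam)
    back <- readFragmentsSAM(sam)
    expect_equal(length(back), length(sim$fragments))
    expect_equal(attr(back, "n_unmapped"), 0)
    a <- as.data.frame(sort(GenomicRanges::granges(sim$fragments, use.names = FALSE)))
    b <- as.data.frame(sort(GenomicRanges::granges(back, use.names = FALSE)))
    expect_equal(a, b)
    # and counting is identical on the round-tripped fragments
    expect_equal(countFragments(back, neat1RegionModel())$rm_common,
                 countFragments(sim$fragments, neat1RegionModel())$rm_common)
})

test_that("the region model survives a BED round trip", {
    m <- neat1RegionModel()
    bed <- tempfile(fileext = ".bed")
    writeRegionsBED(m, bed)
    # on disk: 0-based half-open
    raw <- read.table(bed, sep = "\t")
    expect_equal(raw$V2, c(65422797, 65426532))
    expect_equal(raw$V3, c(65426532, 65445540))
    m2 <- readRegionsBED(bed)
    expect_equal(regionLengths(m2), regionLengths(m))
    expect_equal(junctionPosition(m2), 65426532)
})
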