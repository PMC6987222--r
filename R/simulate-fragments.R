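#' Parameters for the two-isoform fragment simulator
#'
#' Defines a paired-end library over a two-isoform locus where the short
#' isoform fully overlaps the 5' end of the long isoform: short-isoform
#' fragments are placed uniformly along the common region only, long-isoform
#' fragments along the full locus, and background fragments land on a
#' sentinel contig, contributing only to the total mapped count (they make
#' RMt exceed the locus counts, as in a real library). The locus is treated
#' as intronless; placement is uniform in transcript coordinates.
#'
#' @slot nShort,nLong,nBackground Fragment counts per class.
#' @slot fragmentLengthMean,fragmentLengthSd Insert-size distribution (bp):
#'   normal, re-drawn until the length lies in \code{[readLength,
#'   transcript length]}. The defaults (300 +/- 50) are a common polyA
#'   library convention.
#' @slot readLength Read length in bp.
#' @slot seed Mandatory RNG seed; no hidden global state.
#' @export
setClass("ReadSimParams", representation(
    nShort = "integer", nLong = "integer", nBackground = "integer",
    fragmentLengthMean = "numeric", fragmentLengthSd = "numeric",
    readLength = "integer", seed = "integer"))

setValidity("ReadSimParams", function(object) {
    msg <- character()
    if (object@nShort < 0L || object@nLong < 0L || object@nBackground < 0L)
        msg <- c(msg, "fragment counts must be >= 0")
    if (object@readLength < 1L)
        msg <- c(msg, "readLength must be >= 1")
    if (object@fragmentLengthMean < object@readLength)
        msg <- c(msg, "fragmentLengthMean must be >= readLength")
    if (object@fragmentLengthSd < 0)
        msg <- c(msg, "fragmentLengthSd must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @rdname ReadSimParams-class
#' @param nShort,nLong,nBackground,fragmentLengthMean,fragmentLengthSd,readLength,seed
#'   See slots.
#' @return A \code{ReadSimParams} object.
#' @export
ReadSimParams <- function(nShort = 0L, nLong = 0L, nBackground = 0L,
                          fragmentLengthMean = 300, fragmentLengthSd = 50,
                          readLength = 48L, seed) {
    if (missing(seed)) stop("seed is a mandatory parameter")
    methods::new("ReadSimParams",
        nShort = stopifnotCount(nShort, "nShort"),
        nLong = stopifnotCount(nLong, "nLong"),
        nBackground = stopifnotCount(nBackground, "nBackground"),
        fragmentLengthMean = fragmentLengthMean,
        fragmentLengthSd = fragmentLengthSd,
        readLength = as.integer(readLength),
        seed = as.integer(seed))
}

# Draw n fragment lengths from a normal truncated to [lo, hi] by redrawing.
rtruncLengths <- function(n, mean, sd, lo, hi) {
    if (n == 0L) return(integer())
    if (sd == 0) {
        len <- rep(round(mean), n)
        if (any(len < lo | len > hi))
            stop("fixed fragment length outside [readLength, transcript length]")
        return(as.integer(len))
    }
    out <- integer(n)
    todo <- seq_len(n)
    for (i in 1:10000) {
        draw <- as.integer(round(stats::rnorm(length(todo), mean, sd)))
        ok <- draw >= lo & draw <= hi
        out[todo[ok]] <- draw[ok]
        todo <- todo[!ok]
        if (!length(todo)) return(out)
    }
    stop("could not draw fragment lengths within the transcript after 10000 rounds")
}

#' Simulate paired-end fragments from the two-isoform locus
#'
#' @param params A \linkS4class{ReadSimParams}.
#' @param model A \linkS4class{RegionModel} (default the NEAT1 model).
#' @return A list with \code{fragments} (GRanges with metadata column
#'   \code{origin} in \{short, long, background\}) and \code{truth} (the
#'   three counts and the seed). Deterministic given \code{params}.
#' @examples
#' sim <- simulateLocusFragments(ReadSimParams(nShort = 100, seed = 1))
#' table(classifyFragments(sim$fragments, neat1RegionModel()))
#' @export
simulateLocusFragments <- function(params, model = neat1RegionModel()) {
    methods::validObject(params)
    L <- regionLengths(model)
    if (params@nShort > 0L && params@fragmentLengthMean > L[["common"]])
        stop("fragmentLengthMean exceeds the common-region length: ",
             "impossible library for the short isoform")
    chrom <- as.character(GenomeInfoDb::seqnames(model@regions))[1]
    g0 <- BiocGenerics::start(model@regions)[1]

    withSeed(params@seed, {
        place <- function(n, txLen) {
            len <- rtruncLengths(n, params@fragmentLengthMean,
                                 params@fragmentLengthSd,
                                 params@readLength, txLen)
            st <- 1L + floor(stats::runif(n) * (txLen - len + 1L))
            cbind(start = as.integer(st), end = as.integer(st + len - 1L))
        }
        shortPos <- place(params@nShort, L[["common"]])
        longPos <- place(params@nLong, L[["locus"]])
        bgLen <- 1e6L
        bgPos <- place(params@nBackground, bgLen)

        frags <- alignedFragments(
            chrom = c(rep(chrom, params@nShort + params@nLong),
                      rep("background", params@nBackground)),
            start = c(g0 + shortPos[, "start"] - 1L,
                      g0 + longPos[, "start"] - 1L,
                      bgPos[, "start"]),
            end = c(g0 + shortPos[, "end"] - 1L,
                    g0 + longPos[, "end"] - 1L,
                    bgPos[, "end"]))
        S4Vectors::mcols(frags)$origin <- rep(
            c("short", "long", "background"),
            c(params@nShort, params@nLong, params@nBackground))
        list(fragments = frags,
             truth = list(n_short = params@nShort, n_long = params@nLong,
                          n_background = params@nBackground,
                          seed = params@seed))
    })
}
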