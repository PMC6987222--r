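#' Two-region locus model for overlapping isoform quantification
#'
#' An S4 container describing the two adjacent genomic intervals used to
#' disambiguate a short isoform that fully overlaps the 5' end of a long
#' isoform: the \emph{common} region (covered by both isoforms) and the
#' \emph{specific} region (unique to the long isoform). The junction between
#' the two regions is the boundary used by the spanning-fragment exclusion
#' rule. Coordinates are 1-based inclusive, as printed in genome-browser
#' style; BED on disk is converted at the boundary (see
#' \code{\link{readRegionsBED}}).
#'
#' @slot regions A \link[GenomicRanges]{GRanges} of length 2 named
#'   \code{"common"} and \code{"specific"}, on the same seqname, with
#'   \code{end(common) + 1 == start(specific)}.
#'
#' @seealso \code{\link{neat1RegionModel}} for the default NEAT1 model,
#'   \code{\link{classifyFragments}} for the classification rule.
#' @export
setClass("RegionModel", representation(regions = "GRanges"))

setValidity("RegionModel", function(object) {
    gr <- object@regions
    msg <- character()
    if (length(gr) != 2L || !identical(names(gr), c("common", "specific")))
        msg <- c(msg, "regions must be a GRanges of length 2 named 'common' and 'specific'")
    else {
        if (length(unique(as.character(GenomeInfoDb::seqnames(gr)))) != 1L)
            msg <- c(msg, "common and specific regions must share one seqname")
        if (BiocGenerics::end(gr)[1] + 1L != BiocGenerics::start(gr)[2])
            msg <- c(msg, "regions must be adjacent: end(common) + 1 == start(specific)")
        if (any(BiocGenerics::width(gr) < 1L))
            msg <- c(msg, "regions must have positive width")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a two-region locus model
#'
#' @param chrom Seqname the two regions live on (e.g. \code{"chr11"}).
#' @param commonStart,commonEnd 1-based inclusive coordinates of the common
#'   region.
#' @param specificStart,specificEnd 1-based inclusive coordinates of the
#'   isoform-specific region; \code{specificStart} must equal
#'   \code{commonEnd + 1}.
#'
#' @return A \linkS4class{RegionModel}.
#' @examples
#' rm <- RegionModel("chr11", 65422798, 65426532, 65426533, 65445540)
#' regionLengths(rm)
#' @export
RegionModel <- function(chrom, commonStart, commonEnd, specificStart, specificEnd) {
    gr <- GenomicRanges::GRanges(
        seqnames = rep(chrom, 2L),
        ranges = IRanges::IRanges(
            start = c(commonStart, specificStart),
            end = c(commonEnd, specificEnd),
            names = c("common", "specific")))
    methods::new("RegionModel", regions = gr)
}

#' Default NEAT1 locus model (GRCh38)
#'
#' The NEAT1 common region chr11:65,422,798-65,426,532 (3,735 bp; the span of
#' the short polyadenylated NEAT1_1 isoform) and the NEAT1_2-specific region
#' chr11:65,426,533-65,445,540 (19,008 bp), 1-based inclusive on GRCh38.
#'
#' @return A \linkS4class{RegionModel}.
#' @export
neat1RegionModel <- function() {
    RegionModel("chr11", 65422798L, 65426532L, 65426533L, 65445540L)
}

#' @describeIn RegionModel-accessors The common region as a GRanges of length 1.
#' @export
commonRegion <- function(model) model@regions["common"]

#' @describeIn RegionModel-accessors The isoform-specific region.
#' @export
specificRegion <- function(model) model@regions["specific"]

#' Accessors for RegionModel
#'
#' @param model A \linkS4class{RegionModel}.
#' @return \code{commonRegion}/\code{specificRegion} return a GRanges of
#'   length 1; \code{regionLengths} a named numeric vector with elements
#'   \code{common}, \code{specific} and \code{locus} (bp, inclusive lengths);
#'   \code{junctionPosition} the last base of the common region.
#' @name RegionModel-accessors
NULL

#' @describeIn RegionModel-accessors Region lengths in bp (the L of the FPKM
#'   formula, one per region, plus the full locus length).
#' @export
regionLengths <- function(model) {
    w <- BiocGenerics::width(model@regions)
    c(common = w[1], specific = w[2], locus = sum(w))
}

#' @describeIn RegionModel-accessors Junction coordinate: the exclusion rule
#'   removes fragments whose span covers both this base and the next.
#' @export
junctionPosition <- function(model) {
    BiocGenerics::end(model@regions)[1]
}

setMethod("show", "RegionModel", function(object) {
    w <- regionLengths(object)
    cat("RegionModel on", as.character(GenomeInfoDb::seqnames(object@regions))[1], "\n")
    cat(sprintf("  common  : %d-%d (%d bp)\n",
        BiocGenerics::start(object@regions)[1],
        BiocGenerics::end(object@regions)[1], w[["common"]]))
    cat(sprintf("  specific: %d-%d (%d bp)\n",
        BiocGenerics::start(object@regions)[2],
        BiocGenerics::end(object@regions)[2], w[["specific"]]))
})

#' Read or write a two-region model as BED
#'
#' On disk the regions are 6-column BED, 0-based half-open; in memory all
#' coordinates are 1-based inclusive. \code{rtracklayer} performs the
#' conversion. The BED names column must contain \code{common} and
#' \code{specific}.
#'
#' @param path BED file path.
#' @param model A \linkS4class{RegionModel} (for writing).
#' @return \code{readRegionsBED} returns a \linkS4class{RegionModel}.
#' @export
readRegionsBED <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    idx <- match(c("common", "specific"), gr$name)
    if (anyNA(idx))
        stop("BED file must contain regions named 'common' and 'specific'")
    gr <- gr[idx]
    RegionModel(as.character(GenomeInfoDb::seqnames(gr))[1],
                BiocGenerics::start(gr)[1], BiocGenerics::end(gr)[1],
                BiocGenerics::start(gr)[2], BiocGenerics::end(gr)[2])
}

#' @rdname readRegionsBED
#' @export
writeRegionsBED <- function(model, path) {
    gr <- model@regions
    gr$name <- names(gr)
    gr$score <- 0L
    BiocGenerics::strand(gr) <- "+"
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}
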