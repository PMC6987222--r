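#' Write fragments as paired-end SAM records
#'
#' Each fragment becomes a properly-paired read pair: the forward read at the
#' fragment's left end, the reverse read ending at its right end, with the
#' template length (TLEN) equal to the fragment span. Records are
#' coordinate-sorted when \code{sort = TRUE}. Sequence and quality are
#' omitted (\code{*}): classification needs only coordinates.
#'
#' @param frags GRanges of fragments (see \code{\link{alignedFragments}}).
#' @param path Output SAM path.
#' @param readLength Read length in bp; reads longer than the fragment are
#'   truncated to it.
#' @param seqLengths Named integer vector of contig lengths for the
#'   \code{@SQ} header; defaults cover GRCh38 chr11 plus the
#'   \code{background} sentinel contig.
#' @param sort Coordinate-sort the records (default \code{TRUE}).
#' @return \code{path}, invisibly.
#' @export
writeFragmentsSAM <- function(frags, path, readLength = 48L,
                              seqLengths = c(chr11 = 135086622L,
                                             background = 100000000L),
                              sort = TRUE) {
    chrom <- as.character(GenomeInfoDb::seqnames(frags))
    used <- unique(chrom)
    missing <- setdiff(used, names(seqLengths))
    if (length(missing))
        stop("no @SQ length for contig(s): ", paste(missing, collapse = ", "))
    hdr <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", names(seqLengths), seqLengths))
    if (length(frags) == 0L) {
        writeLines(hdr, path)
        return(invisible(path))
    }
    s <- BiocGenerics::start(frags)
    e <- BiocGenerics::end(frags)
    tlen <- e - s + 1L
    rl <- pmin(as.integer(readLength), tlen)
    pp <- S4Vectors::mcols(frags)$proper_pair
    if (is.null(pp)) pp <- rep(TRUE, length(frags))
    # FLAG 99/147 = paired, proper, mate-reverse/reverse, first/second in pair
    f1 <- ifelse(pp, 99L, 97L)
    f2 <- ifelse(pp, 147L, 145L)
    qname <- sprintf("frag%06d", seq_along(frags))
    p2 <- e - rl + 1L
    cig <- sprintf("%dM", rl)
    r1 <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t*\t*",
                  qname, f1, chrom, s, cig, p2, tlen)
    r2 <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t*\t*",
                  qname, f2, chrom, p2, cig, s, -tlen)
    rec <- c(r1, r2)
    pos <- c(s, p2)
    ctg <- factor(c(chrom, chrom), levels = names(seqLengths))
    if (sort) rec <- rec[order(as.integer(ctg), pos)]
    writeLines(c(hdr, rec), path)
    invisible(path)
}

#' Read paired-end fragments from SAM/BAM
#'
#' Reads alignment records and reconstructs fragment footprints from the
#' leftmost mate of each pair (positive template length): the fragment spans
#' \code{[pos, pos + TLEN - 1]}, the outermost template coordinates of the
#' pair including the insert gap. SAM input is converted through
#' \code{Rsamtools::asBam}. Unmapped records are skipped and tallied in the
#' \code{n_unmapped} attribute.
#'
#' @param path SAM or BAM file.
#' @return GRanges of fragments with metadata column \code{proper_pair} and
#'   attribute \code{n_unmapped}.
#' @export
readFragmentsSAM <- function(path) {
    if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
        dest <- tempfile(fileext = "")
        path <- Rsamtools::asBam(path, destination = dest,
                                 overwrite = TRUE, indexDestination = FALSE)
    }
    p <- Rsamtools::ScanBamParam(what = c("rname", "pos", "isize", "flag"))
    b <- Rsamtools::scanBam(path, param = p)[[1]]
    unmapped <- bitwAnd(b$flag, 4L) > 0L
    keep <- !unmapped & !is.na(b$isize) & b$isize > 0L
    gr <- GenomicRanges::GRanges(
        as.character(b$rname[keep]),
        IRanges::IRanges(b$pos[keep], b$pos[keep] + b$isize[keep] - 1L))
    S4Vectors::mcols(gr)$proper_pair <- bitwAnd(b$flag[keep], 2L) > 0L
    attr(gr, "n_unmapped") <- sum(unmapped)
    gr
}
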