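#' Maximum intensity projection of a z-stack
#'
#' @param stack Numeric 3-D array (z, y, x).
#' @return Numeric (y, x) matrix: the per-pixel maximum over z.
#' @export
maxProject <- function(stack) {
    if (!is.array(stack) || length(dim(stack)) != 3L || any(dim(stack) == 0L))
        stop("stack must be a nonempty 3-D (z, y, x) array")
    apply(stack, c(2, 3), max)
}

#' Segment nuclei in a DAPI projection by automatic thresholding
#'
#' Otsu's threshold on the (min-max normalized) DAPI projection, followed by
#' hole filling, removal of components smaller than \code{minArea}, and
#' connected-component labelling. Normalizing before thresholding makes the
#' segmentation invariant to multiplying the channel by a positive constant.
#' A constant image has no defined threshold and yields an empty mask with a
#' warning. An externally supplied label mask (e.g. manually traced nuclear
#' outlines) can be passed downstream instead of this function's output;
#' every measurement function accepts any integer label mask.
#'
#' @param dapiProjection Numeric (y, x) matrix.
#' @param minArea Minimum component area in pixels (default 200, roughly a
#'   disc of radius 8 px at 40x).
#' @return Integer (y, x) label mask, 0 = background, labels 1..K.
#' @export
segmentNuclei <- function(dapiProjection, minArea = 200L) {
    if (!is.matrix(dapiProjection) || !length(dapiProjection))
        stop("dapiProjection must be a nonempty matrix")
    rng <- range(dapiProjection)
    if (diff(rng) == 0) {
        warning("constant image: threshold undefined, returning empty mask")
        return(matrix(0L, nrow(dapiProjection), ncol(dapiProjection)))
    }
    norm <- (dapiProjection - rng[1]) / diff(rng)
    th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    mask <- EBImage::fillHull(norm > th)
    lab <- EBImage::bwlabel(mask)
    sizes <- tabulate(as.integer(lab))
    keep <- which(sizes >= minArea)
    out <- matrix(0L, nrow(dapiProjection), ncol(dapiProjection))
    m <- as.integer(lab)
    relab <- integer(max(m, 1L))
    relab[keep] <- seq_along(keep)
    pos <- m > 0L
    out[pos] <- relab[m[pos]]
    out
}

#' Measure per-nucleus signal intensity
#'
#' One record per label: pixel area and the arithmetic mean of the signal
#' channel under the label -- the per-nucleus average intensity readout.
#'
#' @param labels Integer (y, x) label mask (0 = background).
#' @param signalProjection Numeric (y, x) matrix, same shape.
#' @return data.frame: \code{nucleus_id}, \code{area},
#'   \code{mean_signal_intensity}.
#' @export
measureNuclei <- function(labels, signalProjection) {
    if (!all(dim(labels) == dim(signalProjection)))
        stop("labels and signalProjection must have the same shape")
    ids <- sort(unique(as.integer(labels[labels > 0L])))
    area <- vapply(ids, function(i) sum(labels == i), integer(1))
    ms <- vapply(ids, function(i) mean(signalProjection[labels == i]), numeric(1))
    data.frame(nucleus_id = ids, area = area, mean_signal_intensity = ms)
}

# Logical (y, x) matrix: pixel >= all 8 neighbours (border pixels compared
# against available neighbours only).
localMaxima8 <- function(img) {
    ny <- nrow(img); nx <- ncol(img)
    pad <- matrix(-Inf, ny + 2L, nx + 2L)
    pad[2:(ny + 1L), 2:(nx + 1L)] <- img
    res <- matrix(TRUE, ny, nx)
    for (dy in -1:1) for (dx in -1:1) {
        if (dy == 0L && dx == 0L) next
        nb <- pad[(2:(ny + 1L)) + dy, (2:(nx + 1L)) + dx]
        res <- res & (img >= nb)
    }
    res
}

#' Detect punctate foci within segmented nuclei
#'
#' A focus is a local intensity maximum (8-neighbourhood) inside a nucleus
#' whose value strictly exceeds that nucleus's background level, defined as
#' median + \code{amplitudeThresholdFactor} x MAD of the signal pixels under
#' the label (robust statistics, so a handful of bright foci do not inflate
#' the background estimate). Candidate maxima are greedily pruned by
#' non-maximum suppression: peaks closer than \code{minSeparation} pixels to
#' an already accepted brighter peak are discarded.
#'
#' @param signalProjection Numeric (y, x) matrix.
#' @param labels Integer (y, x) label mask.
#' @param amplitudeThresholdFactor Multiplier on the per-nucleus MAD
#'   (default 5: well above noise excursions).
#' @param minSeparation Minimum peak separation in pixels (default 2).
#' @return data.frame: \code{nucleus_id}, \code{foci_count}, one row per
#'   label in the mask.
#' @export
detectFoci <- function(signalProjection, labels,
                       amplitudeThresholdFactor = 5, minSeparation = 2) {
    if (!all(dim(labels) == dim(signalProjection)))
        stop("labels and signalProjection must have the same shape")
    ids <- sort(unique(as.integer(labels[labels > 0L])))
    lm <- localMaxima8(signalProjection)
    counts <- vapply(ids, function(i) {
        inNuc <- labels == i
        px <- signalProjection[inNuc]
        thr <- stats::median(px) + amplitudeThresholdFactor * stats::mad(px)
        cand <- which(inNuc & lm & signalProjection > thr, arr.ind = TRUE)
        if (!nrow(cand)) return(0L)
        v <- signalProjection[cand]
        cand <- cand[order(v, decreasing = TRUE), , drop = FALSE]
        keptY <- keptX <- numeric(0)
        for (j in seq_len(nrow(cand))) {
            y <- cand[j, 1]; x <- cand[j, 2]
            if (!length(keptY) ||
                all((keptY - y)^2 + (keptX - x)^2 >= minSeparation^2)) {
                keptY <- c(keptY, y); keptX <- c(keptX, x)
            }
        }
        length(keptY)
    }, integer(1))
    data.frame(nucleus_id = ids, foci_count = counts)
}

#' Ordinal scoring criteria
#'
#' The operational form of the 0-3 paraspeckle score: a nucleus is
#' "positive" when it shows at least \code{positiveFocusMin} punctate foci,
#' and the sample score counts how many of three ascending positive-fraction
#' thresholds the sample reaches. Defaults: a single focus makes a nucleus
#' positive; thresholds 5 percent / 25 percent / 60 percent of nuclei.
#'
#' @slot positiveFocusMin Foci needed for a positive nucleus.
#' @slot fractionThresholds Ascending fractions separating scores 0|1, 1|2,
#'   2|3; each in (0, 1].
#' @export
setClass("ScoreCriteria", representation(
    positiveFocusMin = "integer", fractionThresholds = "numeric"))

setValidity("ScoreCriteria", function(object) {
    t <- object@fractionThresholds
    msg <- character()
    if (length(t) != 3L || any(diff(t) <= 0) || t[1] <= 0 || t[3] > 1)
        msg <- c(msg, "fractionThresholds must be three ascending values in (0, 1]")
    if (object@positiveFocusMin < 1L)
        msg <- c(msg, "positiveFocusMin must be >= 1")
    if (length(msg)) msg else TRUE
})

#' @rdname ScoreCriteria-class
#' @param positiveFocusMin,fractionThresholds See slots.
#' @return A \code{ScoreCriteria} object.
#' @export
ScoreCriteria <- function(positiveFocusMin = 1L,
                          fractionThresholds = c(0.05, 0.25, 0.60)) {
    methods::new("ScoreCriteria",
        positiveFocusMin = as.integer(positiveFocusMin),
        fractionThresholds = fractionThresholds)
}

#' Score a sample 0-3 from its per-nucleus foci counts
#'
#' score 0 if the positive-nucleus fraction is below the first threshold;
#' 1, 2, 3 as it reaches each successive threshold (boundaries inclusive
#' upward: a fraction equal to a threshold attains that score). Samples with
#' score >= 1 are "positive".
#'
#' @param nuclei data.frame with a \code{foci_count} column (one row per
#'   nucleus), e.g. \code{\link{detectFoci}} output.
#' @param criteria A \linkS4class{ScoreCriteria}.
#' @param sampleId Sample identifier carried into the result.
#' @return One-row data.frame: \code{sample_id}, \code{score},
#'   \code{positive_fraction}, \code{n_nuclei}.
#' @export
scoreSample <- function(nuclei, criteria = ScoreCriteria(), sampleId = "sample") {
    if (!nrow(nuclei)) stop("cannot score a sample with no nuclei")
    methods::validObject(criteria)
    frac <- mean(nuclei$foci_count >= criteria@positiveFocusMin)
    data.frame(sample_id = sampleId,
               score = sum(frac >= criteria@fractionThresholds),
               positive_fraction = frac,
               n_nuclei = nrow(nuclei))
}

#' Summarize per-nucleus mean intensities across samples or cell lines
#'
#' Mean and standard deviation of the per-nucleus mean signal intensities
#' for each group, suitable for rank comparison across lines (e.g. with
#' \code{\link{kruskalWallis}}). A single-nucleus group has no spread; its
#' sd is reported as 0 and flagged.
#'
#' @param samples Named list of \code{\link{measureNuclei}}-style
#'   data.frames (one per cell line or sample).
#' @return data.frame: \code{line}, \code{n_nuclei}, \code{mean_intensity},
#'   \code{sd_intensity}, \code{sd_defined}.
#' @export
meanIntensityDistribution <- function(samples) {
    if (!length(samples) || is.null(names(samples)))
        stop("samples must be a named list of nucleus-record tables")
    rows <- lapply(names(samples), function(nm) {
        v <- samples[[nm]]$mean_signal_intensity
        if (!length(v)) stop("group '", nm, "' has no nuclei")
        data.frame(line = nm, n_nuclei = length(v),
                   mean_intensity = mean(v),
                   sd_intensity = if (length(v) > 1L) stats::sd(v) else 0,
                   sd_defined = length(v) > 1L)
    })
    do.call(rbind, rows)
}

#' Run the full FISH quantification on one stack
#'
#' Max-projects both channels, segments nuclei in the DAPI projection (or
#' uses a supplied label mask, bypassing segmentation), measures per-nucleus
#' mean intensity, detects foci, and emits the 0-3 score. FFPE single-plane
#' images are the z = 1 degenerate case.
#'
#' @param dapi,signal 3-D (z, y, x) arrays.
#' @param labels Optional precomputed (y, x) label mask (e.g. manual
#'   outlines); when supplied, segmentation is skipped.
#' @param minArea,criteria,sampleId Passed through.
#' @param amplitudeThresholdFactor,minSeparation Passed to
#'   \code{\link{detectFoci}}.
#' @return List: \code{nuclei} (merged per-nucleus records with foci counts)
#'   and \code{score} (the \code{\link{scoreSample}} row).
#' @export
quantifyFishStack <- function(dapi, signal, labels = NULL, minArea = 200L,
                              criteria = ScoreCriteria(), sampleId = "sample",
                              amplitudeThresholdFactor = 5, minSeparation = 2) {
    dproj <- maxProject(dapi)
    sproj <- maxProject(signal)
    if (is.null(labels)) labels <- segmentNuclei(dproj, minArea = minArea)
    recs <- measureNuclei(labels, sproj)
    foci <- detectFoci(sproj, labels,
                       amplitudeThresholdFactor = amplitudeThresholdFactor,
                       minSeparation = minSeparation)
    nuclei <- merge(recs, foci, by = "nucleus_id")
    list(nuclei = nuclei,
         score = scoreSample(nuclei, criteria, sampleId = sampleId))
}
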