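#' Parameters for the two-channel FISH stack simulator
#'
#' Emulates a confocal z-stack of DAPI-stained nuclei with punctate foci in
#' a second channel: the DAPI channel holds filled discs of constant
#' amplitude replicated across z; the signal channel holds, inside each
#' nucleus, a drawn number of small Gaussian foci each placed on one random
#' z-slice (so a maximum-intensity projection recovers them at full
#' amplitude). Additive Gaussian noise is clipped at zero. Nuclei are placed
#' without overlap by rejection sampling.
#'
#' @slot imageShape Integer (z, y, x); default \code{c(7, 256, 256)}, seven
#'   optical sections as in a typical 40x confocal acquisition.
#' @slot nNuclei Number of nuclei.
#' @slot nucleusRadiusRange Min/max disc radius in pixels.
#' @slot fociMeanPerNucleus Poisson mean focus count per nucleus.
#' @slot fociCounts Optional fixed per-nucleus focus counts overriding the
#'   Poisson draw (length \code{nNuclei}; \code{NA} to disable).
#' @slot focusAmplitude,focusSigma Gaussian focus peak height and width (px).
#' @slot dapiAmplitude Disc intensity in the DAPI channel.
#' @slot noiseSd Gaussian noise standard deviation (both channels).
#' @slot seed Mandatory RNG seed.
#' @export
setClass("FishSimParams", representation(
    imageShape = "integer", nNuclei = "integer",
    nucleusRadiusRange = "numeric", fociMeanPerNucleus = "numeric",
    fociCounts = "numeric", focusAmplitude = "numeric", focusSigma = "numeric",
    dapiAmplitude = "numeric", noiseSd = "numeric", seed = "integer"))

setValidity("FishSimParams", function(object) {
    msg <- character()
    if (length(object@imageShape) != 3L || any(object@imageShape < 1L))
        msg <- c(msg, "imageShape must be (z, y, x) with all >= 1")
    if (object@nNuclei < 0L) msg <- c(msg, "nNuclei must be >= 0")
    if (length(object@nucleusRadiusRange) != 2L ||
        any(object@nucleusRadiusRange <= 0) ||
        diff(object@nucleusRadiusRange) < 0)
        msg <- c(msg, "nucleusRadiusRange must be increasing positive (min, max)")
    if (object@focusAmplitude <= 0 || object@dapiAmplitude <= 0)
        msg <- c(msg, "amplitudes must be > 0")
    if (object@focusSigma <= 0) msg <- c(msg, "focusSigma must be > 0")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@fociMeanPerNucleus < 0) msg <- c(msg, "fociMeanPerNucleus must be >= 0")
    if (!all(is.na(object@fociCounts)) &&
        length(object@fociCounts) != object@nNuclei)
        msg <- c(msg, "fociCounts must have length nNuclei (or be NA)")
    if (length(msg)) msg else TRUE
})

#' @rdname FishSimParams-class
#' @param imageShape,nNuclei,nucleusRadiusRange,fociMeanPerNucleus,fociCounts,focusAmplitude,focusSigma,dapiAmplitude,noiseSd,seed
#'   See slots.
#' @return A \code{FishSimParams} object.
#' @export
FishSimParams <- function(imageShape = c(7L, 256L, 256L), nNuclei = 10L,
                          nucleusRadiusRange = c(12, 18),
                          fociMeanPerNucleus = 4, fociCounts = NA_real_,
                          focusAmplitude = 200, focusSigma = 1.5,
                          dapiAmplitude = 100, noiseSd = 5, seed) {
    if (missing(seed)) stop("seed is a mandatory parameter")
    methods::new("FishSimParams",
        imageShape = as.integer(imageShape),
        nNuclei = stopifnotCount(nNuclei, "nNuclei"),
        nucleusRadiusRange = as.numeric(nucleusRadiusRange),
        fociMeanPerNucleus = fociMeanPerNucleus,
        fociCounts = as.numeric(fociCounts),
        focusAmplitude = focusAmplitude, focusSigma = focusSigma,
        dapiAmplitude = dapiAmplitude, noiseSd = noiseSd,
        seed = as.integer(seed))
}

#' Simulate a two-channel nuclei-plus-foci image stack
#'
#' @param params A \linkS4class{FishSimParams}.
#' @return A list: \code{dapi} and \code{signal}, numeric arrays of shape
#'   (z, y, x); and \code{truth} holding nucleus centers (x, y), radii,
#'   per-nucleus focus counts, and the (y, x) integer label mask (0 =
#'   background, 1..K = nuclei in placement order). Fails if the requested
#'   nuclei cannot be placed without overlap within 1000 attempts each.
#' @export
simulateFishStack <- function(params) {
    methods::validObject(params)
    z <- params@imageShape[1]; ny <- params@imageShape[2]; nx <- params@imageShape[3]

    withSeed(params@seed, {
        rmin <- params@nucleusRadiusRange[1]; rmax <- params@nucleusRadiusRange[2]
        cx <- cy <- rr <- numeric(0)
        for (i in seq_len(params@nNuclei)) {
            placed <- FALSE
            for (att in seq_len(1000L)) {
                r <- stats::runif(1, rmin, rmax)
                x <- stats::runif(1, r + 2, nx - r - 1)
                y <- stats::runif(1, r + 2, ny - r - 1)
                if (!length(cx) ||
                    all(sqrt((cx - x)^2 + (cy - y)^2) > rr + r + 2)) {
                    cx <- c(cx, x); cy <- c(cy, y); rr <- c(rr, r)
                    placed <- TRUE
                    break
                }
            }
            if (!placed)
                stop("could not place nucleus ", i,
                     " without overlap in 1000 attempts")
        }

        xg <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
        yg <- matrix(seq_len(ny), ny, nx)
        labels <- matrix(0L, ny, nx)
        dapiPlane <- matrix(0, ny, nx)
        for (i in seq_along(cx)) {
            inside <- (xg - cx[i])^2 + (yg - cy[i])^2 <= rr[i]^2
            labels[inside] <- i
            dapiPlane[inside] <- params@dapiAmplitude
        }

        if (params@nNuclei > 0L) {
            k <- if (all(is.na(params@fociCounts)))
                stats::rpois(params@nNuclei, params@fociMeanPerNucleus)
            else as.integer(params@fociCounts)
        } else k <- integer(0)

        signal <- array(0, dim = c(z, ny, nx))
        sig <- params@focusSigma
        for (i in seq_along(cx)) {
            # foci placed well inside the nucleus and, like resolvable
            # puncta, at least ~3 sigma from each other (best effort)
            fxs <- fys <- numeric(0)
            for (j in seq_len(k[i])) {
                for (att in seq_len(100L)) {
                    rpos <- sqrt(stats::runif(1)) * max(rr[i] - 3 * sig, 0.5)
                    th <- stats::runif(1, 0, 2 * pi)
                    fx <- cx[i] + rpos * cos(th); fy <- cy[i] + rpos * sin(th)
                    if (!length(fxs) ||
                        all((fxs - fx)^2 + (fys - fy)^2 >= (3 * sig)^2) ||
                        att == 100L) break
                }
                fxs <- c(fxs, fx); fys <- c(fys, fy)
                zi <- sample.int(z, 1L)
                d2 <- (xg - fx)^2 + (yg - fy)^2
                signal[zi, , ] <- signal[zi, , ] +
                    params@focusAmplitude * exp(-d2 / (2 * sig^2))
            }
        }

        dapi <- aperm(array(dapiPlane, dim = c(ny, nx, z)), c(3, 1, 2))
        if (params@noiseSd > 0) {
            dapi <- pmax(dapi + stats::rnorm(length(dapi), 0, params@noiseSd), 0)
            signal <- pmax(signal + stats::rnorm(length(signal), 0, params@noiseSd), 0)
            dim(dapi) <- dim(signal) <- c(z, ny, nx)
        }
        list(dapi = dapi, signal = signal,
             truth = list(centers = cbind(x = cx, y = cy), radii = rr,
                          fociCounts = k, labels = labels,
                          seed = params@seed))
    })
}

#' Write or read a two-channel stack as multi-page TIFF
#'
#' Pages are channel-major: all DAPI z-slices first, then all signal
#' z-slices. Intensities are rescaled to [0, 1] and written as 32-bit float
#' samples; a JSON sidecar (\code{<path>.json}) records the shape and the
#' intensity scale so the stack is re-read on its original scale.
#'
#' @param stack A list with \code{dapi} and \code{signal} (z, y, x) arrays.
#' @param path TIFF path.
#' @return \code{writeFishStackTIFF}: \code{path} invisibly;
#'   \code{readFishStackTIFF}: a list with \code{dapi} and \code{signal}.
#' @export
writeFishStackTIFF <- function(stack, path) {
    z <- dim(stack$dapi)[1]
    scale <- max(stack$dapi, stack$signal, 1)
    pages <- c(lapply(seq_len(z), function(i) stack$dapi[i, , ] / scale),
               lapply(seq_len(z), function(i) stack$signal[i, , ] / scale))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    jsonlite::write_json(list(z = z, scale = scale,
                              channels = c("dapi", "signal")),
                         paste0(path, ".json"), auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writeFishStackTIFF
#' @export
readFishStackTIFF <- function(path) {
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    pages <- tiff::readTIFF(path, all = TRUE)
    z <- length(pages) / length(meta$channels)
    if (z != floor(z)) stop("page count is not a multiple of channel count")
    toArray <- function(ps) {
        a <- array(0, dim = c(z, nrow(ps[[1]]), ncol(ps[[1]])))
        for (i in seq_len(z)) a[i, , ] <- ps[[i]] * meta$scale
        a
    }
    list(dapi = toArray(pages[seq_len(z)]),
         signal = toArray(pages[z + seq_len(z)]))
}
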