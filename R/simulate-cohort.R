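#' Parameters for the cohort simulator
#'
#' Draws a patient cohort whose ordinal expression score (0-3) is
#' conditional on a stratifying clinicopathological variable (e.g. tumor
#' grade or HER2 status): each stratum carries its own probability vector
#' over the four scores. The default strata and probabilities are the
#' grade-row proportions of the screening-cohort cross-tabulation (grade 1
#' samples mostly score 0, grade 3 samples concentrate at scores 2-3).
#'
#' @slot nPatients Cohort size.
#' @slot scoreProbs Named list: one probability vector of length 4 (scores
#'   0..3, summing to 1 within 1e-9) per stratum.
#' @slot strataProbs Named numeric: marginal probability of each stratum
#'   (same names as \code{scoreProbs}, summing to 1 within 1e-9).
#' @slot seed Mandatory RNG seed.
#' @export
setClass("CohortSimParams", representation(
    nPatients = "integer", scoreProbs = "list", strataProbs = "numeric",
    seed = "integer"))

setValidity("CohortSimParams", function(object) {
    msg <- character()
    if (object@nPatients < 0L) msg <- c(msg, "nPatients must be >= 0")
    if (is.null(names(object@scoreProbs)) ||
        !identical(names(object@scoreProbs), names(object@strataProbs)))
        msg <- c(msg, "scoreProbs and strataProbs must share stratum names")
    for (p in object@scoreProbs)
        if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
            msg <- c(msg, "each score probability vector must be length 4, nonnegative, summing to 1")
    if (abs(sum(object@strataProbs) - 1) > 1e-9 || any(object@strataProbs < 0))
        msg <- c(msg, "strataProbs must be nonnegative and sum to 1")
    if (length(msg)) msg else TRUE
})

#' @rdname CohortSimParams-class
#' @param nPatients,scoreProbs,strataProbs,seed See slots. Defaults:
#'   the grade strata of the screening cohort (row proportions of the
#'   printed grade-by-score table, marginals 18/74, 23/74, 33/74).
#' @return A \code{CohortSimParams} object.
#' @export
CohortSimParams <- function(nPatients = 74L,
                            scoreProbs = list(
                                grade1 = c(10, 5, 3, 0) / 18,
                                grade2 = c(8, 9, 5, 1) / 23,
                                grade3 = c(7, 6, 15, 5) / 33),
                            strataProbs = c(grade1 = 18, grade2 = 23,
                                            grade3 = 33) / 74,
                            seed) {
    if (missing(seed)) stop("seed is a mandatory parameter")
    methods::new("CohortSimParams",
        nPatients = stopifnotCount(nPatients, "nPatients"),
        scoreProbs = scoreProbs, strataProbs = strataProbs,
        seed = as.integer(seed))
}

#' Simulate a scored patient cohort
#'
#' @param params A \linkS4class{CohortSimParams}.
#' @return A data.frame with one row per patient: \code{patient_id},
#'   \code{stratum} (factor over the parameter's strata), \code{score}
#'   (integer 0-3). Deterministic given \code{params}.
#' @export
simulateCohort <- function(params) {
    methods::validObject(params)
    strata <- names(params@scoreProbs)
    withSeed(params@seed, {
        st <- sample(strata, params@nPatients, replace = TRUE,
                     prob = params@strataProbs)
        score <- vapply(st, function(s)
            sample(0:3, 1L, prob = params@scoreProbs[[s]]), integer(1))
        data.frame(
            patient_id = sprintf("P%04d", seq_len(params@nPatients)),
            stratum = factor(st, levels = strata),
            score = unname(score),
            stringsAsFactors = FALSE)
    })
}

#' Parameters for the qPCR plate simulator
#'
#' Emits a long-format Cq table for one target gene plus a three-gene
#' reference panel, with a designated calibrator sample. Target Cq values
#' are generated as calibrator Cq minus the sample's true log2 fold change
#' (one cycle per doubling at 100 percent efficiency) plus Gaussian noise;
#' reference-gene Cq values scatter around their stated means.
#'
#' @slot trueLog2FoldChanges Named per-sample true log2 fold changes vs the
#'   calibrator.
#' @slot referenceCqMeans Named per-gene Cq means for the reference panel
#'   (defaults for GAPDH, B2M, RPLP0).
#' @slot targetGene,calibrator Names used in the emitted table.
#' @slot calibratorTargetCq Target-gene Cq of the calibrator sample.
#' @slot cqNoiseSd Per-well Gaussian Cq noise (>= 0).
#' @slot nReplicates Technical replicates per (sample, gene).
#' @slot seed Mandatory RNG seed.
#' @export
setClass("QpcrSimParams", representation(
    trueLog2FoldChanges = "numeric", referenceCqMeans = "numeric",
    targetGene = "character", calibrator = "character",
    calibratorTargetCq = "numeric", cqNoiseSd = "numeric",
    nReplicates = "integer", seed = "integer"))

setValidity("QpcrSimParams", function(object) {
    msg <- character()
    if (object@cqNoiseSd < 0) msg <- c(msg, "cqNoiseSd must be >= 0")
    if (is.null(names(object@trueLog2FoldChanges)))
        msg <- c(msg, "trueLog2FoldChanges must be named by sample")
    if (is.null(names(object@referenceCqMeans)) ||
        length(object@referenceCqMeans) < 1L)
        msg <- c(msg, "referenceCqMeans must be a named per-gene vector")
    if (object@calibrator %in% names(object@trueLog2FoldChanges))
        msg <- c(msg, "the calibrator is added automatically; do not list it in trueLog2FoldChanges")
    if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
    if (length(msg)) msg else TRUE
})

#' @rdname QpcrSimParams-class
#' @param trueLog2FoldChanges,referenceCqMeans,targetGene,calibrator,calibratorTargetCq,cqNoiseSd,nReplicates,seed
#'   See slots.
#' @return A \code{QpcrSimParams} object.
#' @export
QpcrSimParams <- function(trueLog2FoldChanges,
                          referenceCqMeans = c(GAPDH = 18, B2M = 20, RPLP0 = 22),
                          targetGene = "NEAT1_2", calibrator = "MCF7",
                          calibratorTargetCq = 26, cqNoiseSd = 0,
                          nReplicates = 3L, seed) {
    if (missing(seed)) stop("seed is a mandatory parameter")
    methods::new("QpcrSimParams",
        trueLog2FoldChanges = trueLog2FoldChanges,
        referenceCqMeans = referenceCqMeans,
        targetGene = targetGene, calibrator = calibrator,
        calibratorTargetCq = calibratorTargetCq, cqNoiseSd = cqNoiseSd,
        nReplicates = as.integer(nReplicates), seed = as.integer(seed))
}

#' Simulate a qPCR Cq plate
#'
#' @param params A \linkS4class{QpcrSimParams}.
#' @return A list: \code{plate}, a long data.frame (\code{sample},
#'   \code{gene}, \code{replicate}, \code{cq}) covering the calibrator plus
#'   every sample for the target and all reference genes; and \code{truth}
#'   (the true log2 fold changes, calibrator name, seed).
#' @export
simulateQpcrPlate <- function(params) {
    methods::validObject(params)
    samples <- c(params@calibrator, names(params@trueLog2FoldChanges))
    lfc <- c(0, unname(params@trueLog2FoldChanges))
    genes <- c(params@targetGene, names(params@referenceCqMeans))
    geneMeans <- c(params@calibratorTargetCq, unname(params@referenceCqMeans))

    grid <- expand.grid(replicate = seq_len(params@nReplicates),
                        gene = genes, sample = samples,
                        stringsAsFactors = FALSE)[, c("sample", "gene", "replicate")]
    base <- geneMeans[match(grid$gene, genes)]
    isTarget <- grid$gene == params@targetGene
    shift <- lfc[match(grid$sample, samples)]
    mu <- base - ifelse(isTarget, shift, 0)
    withSeed(params@seed, {
        grid$cq <- mu + stats::rnorm(nrow(grid), 0, params@cqNoiseSd)
        list(plate = grid,
             truth = list(log2FoldChanges = params@trueLog2FoldChanges,
                          calibrator = params@calibrator,
                          seed = params@seed))
    })
}
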