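#' Reference-panel Cq for one sample
#'
#' Combines the reference genes by taking the geometric mean of their
#' relative quantities 2^(-Cq), which in Cq space is the arithmetic mean of
#' the Cq values -- the standard multi-gene reference-panel construction
#' (default panel: GAPDH, B2M, RPLP0).
#'
#' @param cq Named numeric vector of Cq values for one sample (names are
#'   gene symbols; extra genes are ignored).
#' @param referenceGenes Character vector of panel gene names; all must be
#'   present.
#' @return The panel reference Cq (single numeric).
#' @examples
#' referenceCq(c(GAPDH = 18, B2M = 20, RPLP0 = 22))  # 20
#' @export
referenceCq <- function(cq, referenceGenes = c("GAPDH", "B2M", "RPLP0")) {
    missing <- setdiff(referenceGenes, names(cq))
    if (length(missing))
        stop("missing reference gene(s): ", paste(missing, collapse = ", "))
    mean(cq[referenceGenes])
}

#' Delta-delta-Cq fold changes against a calibrator sample
#'
#' Technical replicates of each (sample, gene) pair are averaged first.
#' Then, per sample, delta-Cq = target Cq - reference-panel Cq;
#' delta-delta-Cq subtracts the calibrator's delta-Cq; fold change =
#' 2^(-delta-delta-Cq), assuming 100 percent amplification efficiency. The
#' calibrator's fold change is exactly 1.
#'
#' @param plate Long-format data.frame with columns \code{sample},
#'   \code{gene}, \code{cq} (and optionally \code{replicate}).
#' @param target Target gene name.
#' @param referenceGenes Reference panel gene names.
#' @param calibrator Calibrator sample name (must occur exactly once among
#'   the sample names).
#' @return data.frame, one row per sample: \code{sample_id},
#'   \code{delta_cq}, \code{delta_delta_cq}, \code{fold_change}.
#' @export
ddcqFoldChange <- function(plate, target = "NEAT1_2",
                           referenceGenes = c("GAPDH", "B2M", "RPLP0"),
                           calibrator) {
    stopifnot(all(c("sample", "gene", "cq") %in% names(plate)))
    if (!all(is.finite(plate$cq))) stop("non-finite Cq value(s) in plate")
    samples <- unique(plate$sample)
    if (sum(samples == calibrator) == 0L)
        stop("calibrator sample '", calibrator, "' not found")
    # replicate average per (sample, gene)
    avg <- stats::aggregate(cq ~ sample + gene, data = plate, FUN = mean)
    dcq <- vapply(samples, function(s) {
        rows <- avg[avg$sample == s, ]
        cq <- stats::setNames(rows$cq, rows$gene)
        if (!target %in% names(cq))
            stop("sample '", s, "' has no Cq for target gene ", target)
        unname(cq[target]) - referenceCq(cq, referenceGenes)
    }, numeric(1))
    ddcq <- dcq - dcq[samples == calibrator]
    data.frame(sample_id = samples,
               delta_cq = unname(dcq),
               delta_delta_cq = unname(ddcq),
               fold_change = 2^(-unname(ddcq)),
               row.names = NULL)
}
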