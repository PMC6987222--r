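#' Printed cross-tabulations of the 74-patient screening cohort
#'
#' The variable-by-score contingency tables of the breast cancer screening
#' cohort (n = 74; scores 0/1/2/3 with column totals 25/20/23/6), as
#' published: age at diagnosis, histologic grade, tumor type, tumor
#' diameter (5 patients missing), lymph node status (3 missing), ER, PgR
#' and HER2 status. Rows are variable levels, columns scores 0-3.
#'
#' @return Named list of integer matrices in table order.
#' @seealso \code{\link{screeningCohort}} for a patient-level
#'   reconstruction.
#' @export
table1Counts <- function() {
    list(
        age = rbind("<55" = c(10, 8, 8, 3), ">=55" = c(15, 12, 15, 3)),
        grade = rbind("1" = c(10, 5, 3, 0), "2" = c(8, 9, 5, 1),
                      "3" = c(7, 6, 15, 5)),
        tumor_type = rbind(NST = c(20, 20, 22, 5), ILC = c(3, 0, 0, 0),
                           other = c(2, 0, 1, 1)),
        diameter = rbind("<20mm" = c(14, 12, 7, 4), ">=20mm" = c(11, 6, 13, 2)),
        lymph_node = rbind(negative = c(17, 14, 13, 4),
                           positive = c(8, 6, 7, 2)),
        er = rbind(negative = c(4, 7, 11, 2), positive = c(21, 13, 12, 4)),
        pgr = rbind(negative = c(6, 8, 12, 3), positive = c(19, 12, 11, 3)),
        her2 = rbind(negative = c(22, 13, 15, 2), positive = c(3, 7, 8, 4)))
}

# Expand one variable's per-score level counts into a patient-level column
# aligned with score blocks of sizes blockSizes; short blocks (missing
# patients) are padded with NA at the end of the block.
expandVariable <- function(counts, blockSizes) {
    lev <- rownames(counts)
    unlist(lapply(seq_along(blockSizes), function(s) {
        col <- counts[, s]
        c(rep(lev, col), rep(NA_character_, blockSizes[s] - sum(col)))
    }), use.names = FALSE)
}

#' Patient-level reconstruction of the screening cohort
#'
#' Rebuilds a 74-row patient table whose per-variable cross-tabulations
#' against the 0-3 score equal the printed tables exactly (including the
#' per-variable missingness: 5 patients without diameter, 3 without lymph
#' node status). Only the variable-by-score margins are published, so the
#' joint distribution across variables is synthetic -- within each score
#' block, levels are assigned in order. Every per-variable association
#' statistic computed from this table is therefore identical to one
#' computed from the printed tables, while multi-variable joint analyses
#' are not meaningful on it.
#'
#' @return data.frame with \code{patient_id}, \code{score} and the eight
#'   clinicopathological variables (character, \code{NA} where missing).
#' @export
screeningCohort <- function() {
    blocks <- c(25L, 20L, 23L, 6L)
    counts <- table1Counts()
    df <- data.frame(patient_id = sprintf("BC%02d", 1:74),
                     score = rep(0:3, blocks),
                     stringsAsFactors = FALSE)
    for (v in names(counts)) df[[v]] <- expandVariable(counts[[v]], blocks)
    df
}

#' Benign and lactating comparison cohorts
#'
#' Score vectors for the non-cancerous comparison groups: 27 benign breast
#' samples of which 2 scored "1" (the rest "0"), and 8 samples from
#' lactating women of which 6 were positive. Per-sample scores beyond
#' positivity are not published for the lactating group; the reconstruction
#' assigns score 1 to each positive sample, which preserves every
#' positivity-based quantity.
#'
#' @return Integer score vector.
#' @export
benignScores <- function() rep(c(0L, 1L), c(25L, 2L))

#' @rdname benignScores
#' @export
lactatingScores <- function() rep(c(0L, 1L), c(2L, 6L))
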