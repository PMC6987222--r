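#' Association test battery for scored cohorts
#'
#' Thin, uniformly-shaped wrappers around the classical tests used to relate
#' an ordinal expression score (or a continuous intensity) to
#' clinicopathological variables: Pearson chi-square on contingency tables,
#' Mann-Whitney/Wilcoxon rank-sum for two groups, Kruskal-Wallis for several,
#' pairwise rank-sum post-tests, and Spearman rank correlation. Every
#' function returns a \code{TestResult}: a list with \code{statistic},
#' \code{df}, \code{p_value}, \code{method}, \code{n}.
#'
#' @name assoc-stats
NULL

testResult <- function(statistic, df, p, method, n) {
    structure(list(statistic = unname(statistic), df = unname(df),
                   p_value = unname(p), method = method, n = n),
              class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
    cat(x$method, ": statistic = ", format(x$statistic, digits = 4),
        if (!is.null(x$df) && !is.na(x$df)) paste0(", df = ", x$df) else "",
        ", p = ", format.pval(x$p_value, digits = 3),
        " ", starAnnotation(x$p_value), " (n = ", x$n, ")\n", sep = "")
    invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' Plain Pearson chi-square (no continuity correction, no cell pooling):
#' X^2 = sum (O - E)^2 / E with expectations from the row/column margins,
#' df = (r-1)(c-1), upper-tail p. A table with a zero row or column margin
#' is degenerate and rejected.
#'
#' @param counts Integer matrix, at least 2 x 2, of observed counts.
#' @return A \code{TestResult}.
#' @export
pearsonChiSquare <- function(counts) {
    counts <- as.matrix(counts)
    if (nrow(counts) < 2L || ncol(counts) < 2L)
        stop("contingency table must be at least 2 x 2")
    if (sum(counts) <= 0) stop("grand total must be > 0")
    if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
        stop("degenerate table: zero row or column margin")
    ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    testResult(ht$statistic, ht$parameter, ht$p.value,
               "Pearson chi-square", sum(counts))
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact enumeration when both groups are small and untied; otherwise the
#' normal approximation with tie correction. The statistic is the
#' Mann-Whitney U of the first group.
#'
#' @param a,b Numeric vectors (e.g. scores or intensities), both nonempty.
#' @return A \code{TestResult}.
#' @export
mannWhitney <- function(a, b) {
    if (!length(a) || !length(b)) stop("both groups must be nonempty")
    if (length(unique(c(a, b))) == 1L)   # fully tied: central U, no evidence
        return(testResult(length(a) * length(b) / 2, NA_integer_, 1,
                          "Mann-Whitney rank-sum", length(a) + length(b)))
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL,
                                              correct = FALSE))
    testResult(ht$statistic, NA_integer_, ht$p.value,
               "Mann-Whitney rank-sum", length(a) + length(b))
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with the chi-square approximation on k - 1 df.
#'
#' @param groups List of at least two nonempty numeric vectors.
#' @return A \code{TestResult}.
#' @export
kruskalWallis <- function(groups) {
    if (length(groups) < 2L || any(!lengths(groups)))
        stop("need at least two nonempty groups")
    if (length(unique(unlist(groups))) == 1L)   # fully tied: H = 0 by convention
        return(testResult(0, length(groups) - 1L, 1, "Kruskal-Wallis",
                          sum(lengths(groups))))
    ht <- stats::kruskal.test(groups)
    testResult(ht$statistic, ht$parameter, ht$p.value,
               "Kruskal-Wallis", sum(lengths(groups)))
}

#' Pairwise Wilcoxon rank-sum post-tests
#'
#' Every pair of groups is compared with \code{\link{mannWhitney}}.
#' Unadjusted p-values are reported alongside Holm-adjusted ones, each
#' labelled, so either convention can be read off.
#'
#' @param groups Named list of at least two nonempty numeric vectors.
#' @return data.frame: \code{group1}, \code{group2}, \code{statistic},
#'   \code{p_value} (unadjusted), \code{p_holm}.
#' @export
pairwiseWilcoxon <- function(groups) {
    if (length(groups) < 2L || any(!lengths(groups)))
        stop("need at least two nonempty groups")
    if (is.null(names(groups))) names(groups) <- seq_along(groups)
    pairs <- utils::combn(names(groups), 2L)
    res <- lapply(seq_len(ncol(pairs)), function(i) {
        p <- pairs[, i]
        tr <- mannWhitney(groups[[p[1]]], groups[[p[2]]])
        data.frame(group1 = p[1], group2 = p[2],
                   statistic = tr$statistic, p_value = tr$p_value)
    })
    out <- do.call(rbind, res)
    out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
    out
}

#' Spearman rank correlation
#'
#' rho on mid-ranks; exact p for small untied samples, otherwise the
#' t/AS89 approximation. A constant vector has undefined rank correlation:
#' the result carries \code{statistic = NA} and a warning is raised.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return A \code{TestResult} whose \code{statistic} is rho.
#' @export
spearmanCorr <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 3L) stop("need n >= 3")
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        warning("constant vector: Spearman rho undefined")
        return(testResult(NA_real_, NA_integer_, NA_real_,
                          "Spearman rank correlation", length(x)))
    }
    ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    testResult(ht$estimate, NA_integer_, ht$p.value,
               "Spearman rank correlation", length(x))
}

#' Fraction of positive samples
#'
#' Samples scoring 1, 2 or 3 are positive; the rate is the fraction of
#' scores at or above 1.
#'
#' @param scores Integer vector of ordinal scores 0-3, nonempty.
#' @return Fraction in [0, 1].
#' @examples
#' positivityRate(rep(0:3, c(25, 20, 23, 6)))  # 49/74
#' @export
positivityRate <- function(scores) {
    if (!length(scores)) stop("empty score vector")
    if (any(!scores %in% 0:3)) stop("scores must be in 0..3")
    mean(scores >= 1)
}

#' Significance stars for a p-value
#'
#' \code{"****"} for p <= 1e-4, \code{"***"} for p <= 1e-3, \code{"**"} for
#' p <= 0.01, \code{"*"} for p <= 0.05, \code{"ns"} above -- boundaries
#' inclusive toward the stronger annotation.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Character vector of annotations.
#' @export
starAnnotation <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must be in [0, 1]")
    out <- rep("ns", length(p))
    out[p <= 0.05] <- "*"
    out[p <= 0.01] <- "**"
    out[p <= 0.001] <- "***"
    out[p <= 0.0001] <- "****"
    out[is.na(p)] <- NA_character_
    out
}

#' Cross-tabulate a cohort and test every variable against the score
#'
#' For each named variable, builds the variable-by-score contingency table
#' (rows = variable levels, columns = scores 0-3, patients missing that
#' variable excluded pairwise), runs \code{\link{pearsonChiSquare}}, and
#' reports counts with row percentages -- the machine twin of a
#' clinicopathological association table. Variables with a single observed
#' level are skipped with a warning.
#'
#' @param records data.frame with a \code{score} column (0-3) plus the
#'   variables to test; missing values allowed per variable.
#' @param variables Character vector of column names to test (default: all
#'   columns except \code{score} and \code{patient_id}).
#' @return List of class \code{CohortSummary}: per variable a list with
#'   \code{table} (counts), \code{row_percent} (1 d.p.), \code{test}
#'   (a \code{TestResult}), \code{n}; plus attribute \code{p_values}, the
#'   named vector of p-values in variable order.
#' @export
summarizeCohort <- function(records, variables = NULL) {
    if (!nrow(records)) stop("empty cohort")
    stopifnot("score" %in% names(records))
    if (is.null(variables))
        variables <- setdiff(names(records), c("score", "patient_id"))
    out <- list()
    for (v in variables) {
        keep <- !is.na(records[[v]])
        lev <- records[[v]][keep]
        if (!is.factor(lev)) lev <- factor(lev, levels = unique(lev))
        lev <- droplevels(lev)
        if (nlevels(lev) < 2L) {
            warning("variable '", v, "' has a single level; skipped")
            next
        }
        tab <- table(lev, factor(records$score[keep], levels = 0:3))
        tab <- unclass(tab)
        names(dimnames(tab)) <- NULL
        tr <- pearsonChiSquare(tab)
        out[[v]] <- list(table = tab,
                         row_percent = round(100 * prop.table(tab, 1), 1),
                         test = tr, n = sum(keep))
    }
    attr(out, "p_values") <- vapply(out, function(x) x$test$p_value, numeric(1))
    class(out) <- "CohortSummary"
    out
}

#' @export
print.CohortSummary <- function(x, ...) {
    for (v in names(x)) {
        cat("==", v, sprintf("(n = %d, p = %.3f %s)\n", x[[v]]$n,
            x[[v]]$test$p_value, starAnnotation(x[[v]]$test$p_value)))
        print(x[[v]]$table)
    }
    invisible(x)
}
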