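## Placement values: for each x in a, the fraction of b strictly below
## it plus half the fraction tied (O(n log n) via sorted b).
.placements <- function(a, b) {
    sb <- sort(b)
    leq <- findInterval(a, sb)
    less <- findInterval(a, sb, left.open = TRUE)
    (less + 0.5 * (leq - less)) / length(b)
}

#' ROC curve with AUC and DeLong variance
#'
#' Builds the empirical ROC curve of a score separating cases from
#' controls (predicted positive iff score >= threshold) and computes
#' the AUC as the Mann-Whitney U statistic divided by
#' n_case * n_ctrl, ties weighted one half. The AUC variance is
#' DeLong's: var(case placements)/n_case + var(control placements)/
#' n_ctrl.
#'
#' @param caseScores,ctrlScores numeric score vectors, both non-empty;
#'   \code{NA}s are dropped.
#' @return list of class \code{psgrsRoc} with \code{points} (data.frame
#'   threshold/fpr/tpr running from (0,0) to (1,1)), \code{auc},
#'   \code{varAuc}, \code{nCase}, \code{nCtrl} and the placement
#'   vectors \code{v10} (cases) and \code{v01} (controls).
#' @examples
#' rocCurve(c(3, 2), c(1, 2))$auc   # 0.875
#' @export
rocCurve <- function(caseScores, ctrlScores) {
    x <- caseScores[!is.na(caseScores)]
    y <- ctrlScores[!is.na(ctrlScores)]
    if (!length(x) || !length(y))
        stop("both classes need at least one score")
    v10 <- .placements(x, y)    # P(Y < X) per case
    v01 <- 1 - .placements(y, x)
    auc <- mean(v10)
    varAuc <- if (length(x) > 1L && length(y) > 1L)
        stats::var(v10) / length(x) + stats::var(v01) / length(y)
    else NA_real_
    thr <- sort(unique(c(x, y)), decreasing = TRUE)
    tpr <- vapply(thr, function(t) mean(x >= t), 0)
    fpr <- vapply(thr, function(t) mean(y >= t), 0)
    points <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                         tpr = c(0, tpr))
    if (points$fpr[nrow(points)] < 1 || points$tpr[nrow(points)] < 1)
        points <- rbind(points, data.frame(threshold = -Inf, fpr = 1,
                                           tpr = 1))
    structure(list(points = points, auc = auc, varAuc = varAuc,
                   nCase = length(x), nCtrl = length(y),
                   v10 = v10, v01 = v01),
              class = "psgrsRoc")
}

#' @export
print.psgrsRoc <- function(x, ...) {
    cat(sprintf("ROC: AUC = %.4f (DeLong SE %.4f), %d cases / %d controls\n",
                x$auc, sqrt(x$varAuc), x$nCase, x$nCtrl))
    invisible(x)
}

#' Compare two AUCs by DeLong's method
#'
#' Paired mode (two scores on the same samples): the covariance of the
#' two AUCs is estimated from the shared DeLong placement values and
#' z = (AUC_a - AUC_b) / sqrt(v_a + v_b - 2 cov), with a two-sided
#' normal p-value. Samples missing either score are dropped from both
#' before comparison, so the pairing stays valid. Unpaired mode (two
#' disjoint cohorts): the covariance is zero.
#'
#' @param caseA,ctrlA scores of panel/model A.
#' @param caseB,ctrlB scores of panel/model B; in paired mode these must
#'   align sample-for-sample with A (equal lengths, same subjects in
#'   the same order).
#' @param paired logical.
#' @return list of class \code{psgrsAucComparison}: \code{aucA},
#'   \code{aucB}, \code{delta}, \code{z}, \code{p}, \code{paired}.
#' @export
compareAuc <- function(caseA, ctrlA, caseB, ctrlB, paired = TRUE) {
    if (paired) {
        if (length(caseA) != length(caseB) ||
            length(ctrlA) != length(ctrlB))
            stop("paired comparison needs score pairs on identical samples")
        okCase <- !is.na(caseA) & !is.na(caseB)
        okCtrl <- !is.na(ctrlA) & !is.na(ctrlB)
        caseA <- caseA[okCase]; caseB <- caseB[okCase]
        ctrlA <- ctrlA[okCtrl]; ctrlB <- ctrlB[okCtrl]
    }
    ra <- rocCurve(caseA, ctrlA)
    rb <- rocCurve(caseB, ctrlB)
    delta <- ra$auc - rb$auc
    if (paired) {
        covAuc <- stats::cov(ra$v10, rb$v10) / ra$nCase +
                  stats::cov(ra$v01, rb$v01) / ra$nCtrl
        vDelta <- ra$varAuc + rb$varAuc - 2 * covAuc
    } else {
        vDelta <- ra$varAuc + rb$varAuc
    }
    if (vDelta <= .Machine$double.eps) {
        z <- 0
        p <- 1
    } else {
        z <- delta / sqrt(vDelta)
        p <- 2 * stats::pnorm(-abs(z))
    }
    structure(list(aucA = ra$auc, aucB = rb$auc, delta = delta, z = z,
                   p = p, paired = paired),
              class = "psgrsAucComparison")
}

#' Compare the AUCs of two ScoreSets
#'
#' [ScoreSet-class]-level front end to [compareAuc()]. In paired mode
#' the two sets must score the same cohort; samples incomplete on
#' either panel are dropped from both (complete-case intersection by
#' sample id) so the pairing stays valid.
#'
#' @param a,b [ScoreSet-class]s.
#' @param paired logical; \code{FALSE} compares disjoint cohorts with
#'   zero covariance.
#' @return as [compareAuc()].
#' @export
compareAucSets <- function(a, b, paired = TRUE) {
    stopifnot(is(a, "ScoreSet"), is(b, "ScoreSet"))
    if (paired) {
        if (!setequal(a@sampleIds, b@sampleIds))
            stop("paired comparison needs ScoreSets over the same samples")
        ids <- a@sampleIds[a@complete]
        ids <- ids[ids %in% b@sampleIds[b@complete]]
        sa <- scores(a)[ids]
        sb <- scores(b)[ids]
        st <- sampleStatus(a)[ids]
        compareAuc(sa[st == "case"], sa[st == "control"],
                   sb[st == "case"], sb[st == "control"], paired = TRUE)
    } else {
        ca <- completeScores(a)
        cb <- completeScores(b)
        compareAuc(ca$case, ca$control, cb$case, cb$control,
                   paired = FALSE)
    }
}

#' @export
print.psgrsAucComparison <- function(x, ...) {
    cat(sprintf("AUC %.4f vs %.4f (%s): delta = %+0.4f, z = %.3f, p = %.3g\n",
                x$aucA, x$aucB,
                if (x$paired) "paired DeLong" else "unpaired",
                x$delta, x$z, x$p))
    invisible(x)
}

#' Classification metrics at a score threshold
#'
#' Standard 2x2 classification ratios with predicted-positive iff
#' score >= threshold: sensitivity, specificity, positive and negative
#' predictive value, and accuracy. A metric with an empty denominator
#' is returned as \code{NaN} and flagged via the \code{"undefined"}
#' attribute.
#'
#' @param caseScores,ctrlScores numeric score vectors (\code{NA}s
#'   dropped).
#' @param threshold finite classification threshold.
#' @return named numeric vector (sensitivity, specificity, ppv, npv,
#'   accuracy) with attribute \code{"undefined"} naming any undefined
#'   metric.
#' @export
confusionMetrics <- function(caseScores, ctrlScores, threshold) {
    stopifnot(is.finite(threshold))
    x <- caseScores[!is.na(caseScores)]
    y <- ctrlScores[!is.na(ctrlScores)]
    tp <- sum(x >= threshold); fn <- length(x) - tp
    fp <- sum(y >= threshold); tn <- length(y) - fp
    out <- c(sensitivity = tp / (tp + fn),
             specificity = tn / (tn + fp),
             ppv = tp / (tp + fp),
             npv = tn / (tn + fn),
             accuracy = (tp + tn) / (tp + fn + fp + tn))
    attr(out, "undefined") <- names(out)[is.nan(out)]
    out
}

#' Youden-optimal classification threshold
#'
#' The threshold maximising Youden's J = sensitivity + specificity - 1
#' over an exhaustive scan of candidate cut-offs (midpoints between
#' consecutive distinct pooled scores, plus sentinels outside the
#' range). Ties are broken toward the lowest threshold.
#'
#' @param caseScores,ctrlScores numeric score vectors.
#' @return the selected threshold, with attribute \code{"J"}.
#' @export
youdenThreshold <- function(caseScores, ctrlScores) {
    x <- caseScores[!is.na(caseScores)]
    y <- ctrlScores[!is.na(ctrlScores)]
    if (!length(x) || !length(y))
        stop("both classes need at least one score")
    u <- sort(unique(c(x, y)))
    cand <- if (length(u) > 1L)
        c(u[1L] - 1, (u[-length(u)] + u[-1L]) / 2, u[length(u)] + 1)
    else c(u - 1, u + 1)
    j <- vapply(cand, function(t) mean(x >= t) - mean(y >= t), 0)
    best <- cand[which.max(j)]   # which.max takes the first (lowest) tie
    attr(best, "J") <- max(j)
    best
}
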