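.PANEL_VARIANTS <- c("ALL", "0.1", "N", "B", "HLA", "N(+)HLA(-)",
                     "N(subst.)", "custom")

#' Build a named GRS panel from association results
#'
#' Translates a per-SNP association table into a weighted panel: SNP
#' membership follows [selectPanel()] for the variant's rule, and each
#' SNP's weight is the natural log of its (in-sample) odds ratio.
#' Variants: \code{ALL} (every SNP minus the LD drop), \code{0.1}
#' (p < 0.1), \code{N} (p < 0.05), \code{B} (Bonferroni), \code{HLA}
#' (the HLA-C tag SNP rs4406273 alone), \code{N(+)HLA(-)} (N without
#' rs4406273) and \code{N(subst.)} (N with rs4406273 replaced by its LD
#' partner rs10484554, weighted by rs10484554's own odds ratio).
#' \code{custom} takes membership from \code{snpIds}.
#'
#' @param results data.frame with columns \code{snp_id}, \code{or},
#'   \code{p} (e.g. from [associationTable()] or
#'   [referenceSnpSummary()]).
#' @param variant panel variant name (see above).
#' @param snpIds SNP ids for \code{variant = "custom"}.
#' @param ldDrop SNP ids never scored (default \code{"rs10484554"}).
#' @param m Bonferroni factor for variant \code{B}.
#' @param hlaSnp the HLA-C tag SNP id.
#' @return a [GrsPanel-class].
#' @examples
#' panel <- buildPanel(referenceSnpSummary(), "B", m = 38)
#' length(panel)   # 6
#' @export
buildPanel <- function(results, variant = .PANEL_VARIANTS, snpIds = NULL,
                       ldDrop = "rs10484554", m = nrow(results),
                       hlaSnp = "rs4406273") {
    variant <- match.arg(variant)
    ids <- switch(variant,
        "ALL" = selectPanel(results, "all", ldDrop),
        "0.1" = selectPanel(results, "p<0.1", ldDrop),
        "N" = selectPanel(results, "p<0.05", ldDrop),
        "B" = selectPanel(results, "bonferroni", ldDrop, m = m),
        "HLA" = hlaSnp,
        "N(+)HLA(-)" = setdiff(selectPanel(results, "p<0.05", ldDrop),
                               hlaSnp),
        "N(subst.)" = {
            nIds <- selectPanel(results, "p<0.05", ldDrop)
            sub <- ldDrop[1L]
            ids <- replace(nIds, nIds == hlaSnp, sub)
            if (!hlaSnp %in% nIds) ids <- c(ids, sub)
            ids
        },
        "custom" = {
            if (is.null(snpIds)) stop("variant 'custom' needs snpIds")
            snpIds
        })
    miss <- setdiff(ids, results$snp_id)
    if (length(miss))
        stop("required SNP(s) missing from results: ",
             paste(miss, collapse = ", "))
    w <- log(results$or[match(ids, results$snp_id)])
    GrsPanel(variant, ids, w)
}

#' Score a cohort with a GRS panel
#'
#' The genetic risk score of each sample: the sum over panel SNPs of
#' risk-allele dosage times the SNP's ln(OR) weight. A sample missing
#' any panel dosage is flagged incomplete and scored \code{NA}
#' (listwise exclusion downstream).
#'
#' @param cohort a [GrsCohort-class] containing every panel SNP.
#' @param panel a [GrsPanel-class].
#' @return a [ScoreSet-class].
#' @export
scoreCohort <- function(cohort, panel) {
    stopifnot(is(cohort, "GrsCohort"), is(panel, "GrsPanel"))
    miss <- setdiff(panelSnps(panel), rownames(cohort))
    if (length(miss))
        stop("panel SNP(s) absent from cohort: ",
             paste(miss, collapse = ", "))
    d <- dosages(cohort)[panelSnps(panel), , drop = FALSE]
    complete <- colSums(is.na(d)) == 0L
    sc <- as.vector(crossprod(d, panelWeights(panel)))
    ScoreSet(colnames(cohort), sc, complete,
             phenotypes(cohort)$status, panelName(panel))
}

#' Quartile cut-points of a score distribution
#'
#' Empirical quartiles (25th, 50th, 75th percentiles) of the complete
#' scores of the reference stratum, used to stratify the score for the
#' dose-response analysis. Binning downstream is half-open,
#' [Qk, Qk+1), so with continuous scores the reference stratum splits
#' as evenly as its size allows. Degenerate (tied) cut-points are
#' flagged via the \code{"degenerate"} attribute.
#'
#' @param scoreSet a [ScoreSet-class].
#' @param reference \code{"controls"} (default: cut-points from the
#'   control distribution) or \code{"combined"}.
#' @return numeric length-3 cut-points with attribute
#'   \code{"degenerate"}.
#' @export
quartileCutpoints <- function(scoreSet, reference = c("controls",
                                                      "combined")) {
    stopifnot(is(scoreSet, "ScoreSet"))
    reference <- match.arg(reference)
    cs <- completeScores(scoreSet)
    ref <- if (reference == "controls") cs$control
           else c(cs$case, cs$control)
    if (length(ref) < 4L)
        stop("need at least 4 complete reference samples")
    q <- unname(stats::quantile(ref, c(0.25, 0.5, 0.75)))
    attr(q, "degenerate") <- anyDuplicated(q) > 0L
    q
}

#' Quartile dose-response table from per-quartile counts
#'
#' Given case and control counts in the four score quartiles (bottom
#' first), computes for every quartile above the bottom the odds ratio
#' relative to the bottom quartile from the 2x2 counts,
#' (case_k * ctrl_1) / (ctrl_k * case_1), with a Woolf 95\% confidence
#' interval and an uncorrected chi-square p-value, plus each quartile's
#' share of all cases.
#'
#' @param nCase,nCtrl integer vectors of length 4, bottom quartile
#'   first.
#' @return data.frame with columns \code{quartile}, \code{n_case},
#'   \code{pct_case}, \code{n_ctrl}, \code{or}, \code{ci_lo},
#'   \code{ci_hi}, \code{p}; the bottom row has OR 1 (reference) and
#'   \code{NA} CI/p.
#' @examples
#' quartileOrFromCounts(c(26, 39, 90, 317), c(123, 122, 122, 123))
#' @export
quartileOrFromCounts <- function(nCase, nCtrl) {
    stopifnot(length(nCase) == 4L, length(nCtrl) == 4L)
    if (nCase[1L] < 1L || nCtrl[1L] < 1L)
        stop("bottom (reference) quartile needs at least one case and one control")
    out <- data.frame(quartile = paste0("Q", 1:4), n_case = nCase,
                      pct_case = 100 * nCase / sum(nCase), n_ctrl = nCtrl,
                      or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                      p = NA_real_)
    out$or[1L] <- 1
    for (k in 2:4) {
        at <- allelicTest(nCase[k], nCtrl[k], nCase[1L], nCtrl[1L])
        out$or[k] <- at$or
        out$ci_lo[k] <- at$ci[1L]
        out$ci_hi[k] <- at$ci[2L]
        out$p[k] <- at$p
    }
    out
}

#' Quartile dose-response analysis of a score set
#'
#' Stratifies complete scores into quartiles at the given (or
#' reference-derived) cut-points with half-open bins [Qk, Qk+1),
#' cross-tabulates case status, and reports per-quartile odds ratios
#' relative to the bottom quartile. \code{method = "counts"} uses the
#' 2x2 count ratio with Woolf CI and chi-square p;
#' \code{method = "logistic"} fits a logistic regression of status on
#' the quartile factor and reports Wald CIs and p-values (identical OR
#' point estimates, different intervals).
#'
#' @param scoreSet a [ScoreSet-class].
#' @param cutpoints optional length-3 cut-points; computed from
#'   \code{reference} when omitted.
#' @param reference passed to [quartileCutpoints()].
#' @param method \code{"counts"} or \code{"logistic"}.
#' @return as [quartileOrFromCounts()], plus attributes
#'   \code{"cutpoints"} and \code{"method"}.
#' @export
quartileOrTable <- function(scoreSet, cutpoints = NULL,
                            reference = c("controls", "combined"),
                            method = c("counts", "logistic")) {
    stopifnot(is(scoreSet, "ScoreSet"))
    method <- match.arg(method)
    if (is.null(cutpoints))
        cutpoints <- quartileCutpoints(scoreSet, match.arg(reference))
    ok <- scoreSet@complete
    sc <- scoreSet@score[ok]
    isCase <- scoreSet@status[ok] == "case"
    qk <- findInterval(sc, cutpoints) + 1L   # [.,Q1) [Q1,Q2) [Q2,Q3) [Q3,.]
    nCase <- tabulate(qk[isCase], 4L)
    nCtrl <- tabulate(qk[!isCase], 4L)
    if (nCtrl[1L] < 1L || nCase[1L] < 1L)
        stop("empty reference quartile")
    out <- quartileOrFromCounts(nCase, nCtrl)
    if (method == "logistic") {
        fit <- stats::glm(isCase ~ factor(qk, levels = 1:4),
                          family = stats::binomial())
        sm <- summary(fit)$coefficients
        est <- sm[-1L, "Estimate"]
        se <- sm[-1L, "Std. Error"]
        out$or[2:4] <- exp(est)
        out$ci_lo[2:4] <- exp(est - stats::qnorm(0.975) * se)
        out$ci_hi[2:4] <- exp(est + stats::qnorm(0.975) * se)
        out$p[2:4] <- sm[-1L, "Pr(>|z|)"]
    }
    attr(out, "cutpoints") <- as.numeric(cutpoints)
    attr(out, "method") <- method
    out
}
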