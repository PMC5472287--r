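#' Allelic odds ratio from stratum risk-allele frequencies
#'
#' The allelic odds ratio implied by a case frequency p1 and a control
#' frequency p0: [p1 / (1 - p1)] / [p0 / (1 - p0)]. Identical
#' frequencies give exactly 1.
#'
#' @param p1 case risk-allele frequency, strictly in (0, 1); vectorised.
#' @param p0 control risk-allele frequency, strictly in (0, 1).
#' @return allelic odds ratio (vector).
#' @examples
#' allelicOrFromRaf(0.723, 0.615)  # 1.63 to 2 dp
#' @export
allelicOrFromRaf <- function(p1, p0) {
    if (any(p1 <= 0 | p1 >= 1) || any(p0 <= 0 | p0 >= 1))
        stop("degenerate frequency: RAFs must lie strictly in (0, 1)")
    (p1 / (1 - p1)) / (p0 / (1 - p0))
}

#' Allelic case-control association test on a 2x2 allele table
#'
#' The basic allelic test: risk vs other allele counts compared between
#' cases and controls with an uncorrected 1-df Pearson chi-square, the
#' sample odds ratio (a d)/(b c), and a Woolf (log-OR) 95\% confidence
#' interval using variance 1/a + 1/b + 1/c + 1/d. A zero cell triggers
#' the Haldane-Anscombe +0.5 correction of all four cells for the OR and
#' CI (flagged); an empty stratum is an error.
#'
#' @param a case risk-allele count.
#' @param b case other-allele count.
#' @param c control risk-allele count.
#' @param d control other-allele count.
#' @return list with \code{or}, \code{ci} (length 2), \code{p},
#'   \code{chi2}, \code{rafCase}, \code{rafCtrl},
#'   \code{haldane} (TRUE when the +0.5 correction was used).
#' @examples
#' allelicTest(819, 141, 759, 221)
#' @export
allelicTest <- function(a, b, c, d) {
    counts <- c(a = a, b = b, c = c, d = d)
    if (any(counts < 0)) stop("allele counts must be non-negative")
    if (a + b == 0 || c + d == 0)
        stop("empty stratum: both cases and controls need alleles")
    tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
    if (all(c(a + c, b + d) > 0)) {
        ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        chi2 <- unname(ct$statistic)
        p <- unname(ct$p.value)
    } else {            # monomorphic table: no allelic contrast
        chi2 <- 0
        p <- 1
    }
    haldane <- any(counts == 0)
    if (haldane) counts <- counts + 0.5
    or <- (counts["a"] * counts["d"]) / (counts["b"] * counts["c"])
    se <- sqrt(sum(1 / counts))
    ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
    list(or = unname(or), ci = unname(ci), p = p, chi2 = chi2,
         rafCase = a / (a + b), rafCtrl = c / (c + d),
         haldane = haldane)
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' 1-df chi-square of the observed genotype counts against the
#' Hardy-Weinberg expectations n p^2, 2 n p q, n q^2 at the sample
#' allele frequency p. Deviation is flagged at p-value < 0.05. A
#' monomorphic SNP fits its (degenerate) expectation exactly and is
#' returned with chi2 = 0, p = 1 and a monomorphic flag.
#'
#' @param nHomRisk,nHet,nHomOther genotype counts (risk homozygote,
#'   heterozygote, other homozygote).
#' @return list with \code{chi2}, \code{p}, \code{deviation} and
#'   \code{monomorphic}.
#' @examples
#' hweTest(25, 50, 25)   # exact HWE proportions: chi2 = 0
#' @export
hweTest <- function(nHomRisk, nHet, nHomOther) {
    n <- nHomRisk + nHet + nHomOther
    if (n <= 0) stop("no genotypes")
    pRisk <- (2 * nHomRisk + nHet) / (2 * n)
    if (pRisk == 0 || pRisk == 1)
        return(list(chi2 = 0, p = 1, deviation = FALSE, monomorphic = TRUE))
    e <- n * c(pRisk^2, 2 * pRisk * (1 - pRisk), (1 - pRisk)^2)
    o <- c(nHomRisk, nHet, nHomOther)
    chi2 <- sum((o - e)^2 / e)
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
    list(chi2 = chi2, p = p, deviation = p < 0.05, monomorphic = FALSE)
}

#' Bonferroni significance gate
#'
#' Passes iff p < 0.05 / m, the family-wise gate used to call a SNP
#' significant after testing m SNPs. The inequality is strict.
#'
#' @param p uncorrected p-value(s).
#' @param m number of tests, >= 1.
#' @return logical vector.
#' @export
bonferroniGate <- function(p, m) {
    if (m < 1) stop("m must be >= 1")
    p < 0.05 / m
}

#' Per-SNP allelic association table for a cohort
#'
#' Runs [allelicTest()] and [hweTest()] on every SNP of a cohort (or a
#' stratum subset of it) and applies the Bonferroni gate. Allele counts
#' use non-missing genotypes only; the Hardy-Weinberg test is computed
#' on the combined sample by default, or on controls only.
#'
#' @param cohort a [GrsCohort-class].
#' @param bonferroniM Bonferroni correction factor; defaults to the
#'   number of SNPs tested.
#' @param hweSample \code{"combined"} or \code{"controls"}.
#' @param samples optional sample ids restricting the analysis (e.g. a
#'   training split or a sub-phenotype stratum plus controls).
#' @return data.frame, one row per SNP, with columns \code{snp_id},
#'   \code{raf_case}, \code{raf_ctrl}, \code{or}, \code{ci_lo},
#'   \code{ci_hi}, \code{p}, \code{p_bonf_pass}, \code{hwe_p},
#'   \code{hwe_deviation}, plus \code{gene} when the cohort metadata
#'   carries it.
#' @export
associationTable <- function(cohort, bonferroniM = nrow(cohort),
                             hweSample = c("combined", "controls"),
                             samples = NULL) {
    stopifnot(is(cohort, "GrsCohort"))
    hweSample <- match.arg(hweSample)
    if (!is.null(samples)) cohort <- cohort[, samples]
    d <- dosages(cohort)
    status <- phenotypes(cohort)$status
    dc <- d[, status == "case", drop = FALSE]
    d0 <- d[, status == "control", drop = FALSE]
    dh <- if (hweSample == "combined") d else d0

    rows <- lapply(seq_len(nrow(d)), function(j) {
        a <- sum(dc[j, ], na.rm = TRUE)
        b <- 2 * sum(!is.na(dc[j, ])) - a
        cc <- sum(d0[j, ], na.rm = TRUE)
        dd <- 2 * sum(!is.na(d0[j, ])) - cc
        at <- allelicTest(a, b, cc, dd)
        g <- dh[j, ]
        hw <- hweTest(sum(g == 2, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                      sum(g == 0, na.rm = TRUE))
        data.frame(snp_id = rownames(d)[j], raf_case = at$rafCase,
                   raf_ctrl = at$rafCtrl, or = at$or, ci_lo = at$ci[1],
                   ci_hi = at$ci[2], p = at$p, hwe_p = hw$p,
                   hwe_deviation = hw$deviation,
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    res$p_bonf_pass <- bonferroniGate(res$p, bonferroniM)
    if ("gene" %in% names(snpMeta(cohort)))
        res$gene <- snpMeta(cohort)$gene
    rownames(res) <- NULL
    res
}

#' Select the SNPs of a named panel rule
#'
#' Applies the study's panel membership rules to a per-SNP association
#' table: \code{"all"} keeps every SNP, \code{"p<0.1"} and
#' \code{"p<0.05"} threshold the uncorrected p-value, \code{"bonferroni"}
#' keeps SNPs with p < 0.05 / m, and \code{"hla_only"} keeps only the
#' HLA-C tag SNP. SNPs in \code{ldDrop} (by default the redundant HLA-C
#' proxy rs10484554, the weaker member of the r-squared 0.79 pair) are
#' removed afterwards. Order is the stable input order.
#'
#' @param results data.frame with at least \code{snp_id} and \code{p}
#'   (from [associationTable()] or [referenceSnpSummary()]); a
#'   \code{gene} column, if present, identifies HLA-C tag SNPs for
#'   \code{"hla_only"}.
#' @param rule one of \code{"all"}, \code{"p<0.1"}, \code{"p<0.05"},
#'   \code{"bonferroni"}, \code{"hla_only"}.
#' @param ldDrop SNP ids excluded from every panel (default
#'   \code{"rs10484554"}).
#' @param m Bonferroni factor (default: number of SNPs in
#'   \code{results}).
#' @return character vector of SNP ids.
#' @examples
#' ref <- referenceSnpSummary()
#' length(selectPanel(ref, "p<0.05"))      # 16
#' length(selectPanel(ref, "bonferroni"))  # 6
#' @export
selectPanel <- function(results,
                        rule = c("all", "p<0.1", "p<0.05", "bonferroni",
                                 "hla_only"),
                        ldDrop = "rs10484554", m = nrow(results)) {
    rule <- match.arg(rule)
    keep <- switch(rule,
        "all" = rep(TRUE, nrow(results)),
        "p<0.1" = results$p < 0.1,
        "p<0.05" = results$p < 0.05,
        "bonferroni" = bonferroniGate(results$p, m),
        "hla_only" = if ("gene" %in% names(results))
                         results$gene == "HLA-C"
                     else results$snp_id == "rs4406273")
    setdiff(results$snp_id[keep], ldDrop)
}
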