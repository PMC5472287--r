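# Small cohorts and tables built in code for the unit tests.

makeTinyCohort <- function() {
    d <- matrix(c(0, 1, 2, NA, 1, 0), nrow = 2, byrow = TRUE,
                dimnames = list(c("rs1", "rs2"), c("s1", "s2", "s3")))
    meta <- data.frame(snp_id = c("rs1", "rs2"),
                       risk_allele = c("A", "C"),
                       other_allele = c("G", "T"),
                       chrom_band = c("1p36", "2q12"),
                       gene = c("G1", "G2"),
                       stringsAsFactors = FALSE)
    ph <- data.frame(sample_id = c("s1", "s2", "s3"),
                     status = c("case", "case", "control"),
                     stringsAsFactors = FALSE)
    GrsCohort(d, meta, ph)
}

randomCohort <- function(nSnp = 4, nCase = 12, nCtrl = 15,
                         missingRate = 0.1) {
    snps <- data.frame(snp_id = sprintf("rs%d", seq_len(nSnp)),
                       p0 = runif(nSnp, 0.2, 0.8),
                       or_target = exp(runif(nSnp, -0.5, 0.5)))
    co <- simulateCohort(CohortSpec(snps, nCase = nCase, nCtrl = nCtrl,
                                    seed = sample.int(1e6, 1)))
    applyMissingness(co, missingRate, seed = sample.int(1e6, 1))
}

# Independent brute-force oracle for the 2x2 allelic test: direct
# chi-square summation over expected counts and the log-OR variance
# formula, written without reference to allelicTest().
bruteForce2x2 <- function(a, b, c, d) {
    o <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
    n <- sum(o)
    e <- outer(rowSums(o), colSums(o)) / n
    chi2 <- sum((o - e)^2 / e)
    lor <- log(a) + log(d) - log(b) - log(c)
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    list(or = exp(lor), chi2 = chi2,
         p = pchisq(chi2, df = 1, lower.tail = FALSE),
         ci = exp(lor + c(-1, 1) * qnorm(0.975) * se))
}

# Empirical squared allelic correlation from two dosage vectors.
empiricalR2 <- function(dA, dB) cor(dA, dB, use = "complete.obs")^2
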