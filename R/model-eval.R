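#' Fit a logistic regression by maximum likelihood
#'
#' A thin wrapper over IRLS (stats::glm with a binomial family) that
#' returns the quantities downstream evaluation needs: coefficients and
#' standard errors, the fitted and null log-likelihoods, sample size,
#' and a convergence flag. Perfect separation is detected (fitted
#' probabilities collapsing to 0/1) and flagged as non-converged with a
#' diagnostic.
#'
#' @param design numeric vector or matrix of predictors (no intercept
#'   column; one is added), or \code{NULL} for the intercept-only
#'   model.
#' @param outcome binary outcome, logical or 0/1.
#' @return list of class \code{psgrsLogisticFit}: \code{coefficients},
#'   \code{se}, \code{loglik}, \code{loglikNull}, \code{n},
#'   \code{converged}, \code{separation}, and the underlying \code{glm}
#'   fit.
#' @export
fitLogistic <- function(design, outcome) {
    y <- as.numeric(outcome)
    if (!all(y %in% c(0, 1))) stop("outcome must be binary")
    if (length(unique(y)) < 2L)
        stop("need both outcome classes (at least 2 samples per class)")
    if (is.null(design)) {
        df <- data.frame(y = y)
    } else {
        x <- as.matrix(design)
        if (is.null(colnames(x)))
            colnames(x) <- paste0("x", seq_len(ncol(x)))
        df <- data.frame(y = y, x, check.names = FALSE)
    }
    fit <- suppressWarnings(
        stats::glm(y ~ ., family = stats::binomial(), data = df,
                   control = stats::glm.control(epsilon = 1e-10,
                                                maxit = 100L)))
    null <- stats::glm(y ~ 1, family = stats::binomial(), data = df)
    # perfect separation drives the deviance to zero while the MLE
    # diverges; a (near-)zero residual deviance is the diagnostic
    separation <- length(stats::coef(fit)) > 1L && fit$deviance < 1e-6
    sm <- summary(fit)$coefficients
    structure(list(coefficients = stats::coef(fit),
                   se = sm[, "Std. Error"],
                   loglik = as.numeric(stats::logLik(fit)),
                   loglikNull = as.numeric(stats::logLik(null)),
                   n = length(y),
                   converged = fit$converged && !separation,
                   separation = separation,
                   glm = fit),
              class = "psgrsLogisticFit")
}

#' @export
print.psgrsLogisticFit <- function(x, ...) {
    cat(sprintf("Logistic fit: n = %d, logLik = %.3f (null %.3f)%s\n",
                x$n, x$loglik, x$loglikNull,
                if (!x$converged) " [NOT converged]" else ""))
    print(round(cbind(coef = x$coefficients, se = x$se,
                      or = exp(x$coefficients)), 4))
    invisible(x)
}

#' Variance explained by a logistic model
#'
#' Pseudo-R-squared of a fitted logistic model: McFadden's
#' 1 - logLik / logLik_null, or Nagelkerke's rescaled Cox-Snell,
#' [1 - exp(2 (ll0 - ll1) / n)] / [1 - exp(2 ll0 / n)]. A null model
#' explains 0 under both.
#'
#' @param fit a \code{psgrsLogisticFit} from [fitLogistic()].
#' @param method \code{"nagelkerke"} (default) or \code{"mcfadden"}.
#' @return proportion in [0, 1].
#' @export
varianceExplained <- function(fit, method = c("nagelkerke", "mcfadden")) {
    method <- match.arg(method)
    ll1 <- fit$loglik
    ll0 <- fit$loglikNull
    n <- fit$n
    if (method == "mcfadden") {
        1 - ll1 / ll0
    } else {
        coxSnell <- 1 - exp(2 * (ll0 - ll1) / n)
        coxSnell / (1 - exp(2 * ll0 / n))
    }
}

#' Association of the risk score with a case sub-phenotype
#'
#' Within cases (complete scores only), fits a logistic regression of
#' the trait on the raw score and reports the per-score-unit odds ratio
#' with a Wald 95\% confidence interval and p-value. Traits are binary
#' codings of the phenotype columns: nail / psa / family_history
#' ("yes" vs "no", "unknown" dropped) and onset_class (late onset
#' "T2Ps" vs "T1Ps").
#'
#' @param scoreSet a [ScoreSet-class].
#' @param phenotype the cohort phenotype table ([phenotypes()] output or
#'   data.frame with matching \code{sample_id} rownames).
#' @param trait one of \code{"nail"}, \code{"psa"},
#'   \code{"onset_class"}, \code{"family_history"}.
#' @param standardised if TRUE, the score is standardised (mean 0, SD 1
#'   within the analysed cases) so the OR is per SD rather than per raw
#'   unit.
#' @return list: \code{or}, \code{ci}, \code{p}, \code{n}, \code{fit}.
#' @export
subphenotypeAssociation <- function(scoreSet, phenotype,
                                    trait = c("nail", "psa", "onset_class",
                                              "family_history"),
                                    standardised = FALSE) {
    stopifnot(is(scoreSet, "ScoreSet"))
    trait <- match.arg(trait)
    ph <- as.data.frame(phenotype)
    ids <- scoreSet@sampleIds[scoreSet@complete &
                              scoreSet@status == "case"]
    ids <- intersect(ids, rownames(ph))
    tv <- ph[ids, trait]
    y <- if (trait == "onset_class") {
        ifelse(tv == "T2Ps", 1, ifelse(tv == "T1Ps", 0, NA))
    } else {
        ifelse(tv == "yes", 1, ifelse(tv == "no", 0, NA))
    }
    keep <- !is.na(y)
    if (sum(keep) < 20L)
        stop("fewer than 20 cases with a known '", trait, "' status")
    if (length(unique(y[keep])) < 2L)
        stop("trait '", trait, "' is constant among analysed cases")
    g <- scores(scoreSet)[ids][keep]
    if (standardised) g <- as.vector(scale(g))
    fit <- fitLogistic(matrix(g, dimnames = list(NULL, "grs")), y[keep])
    est <- fit$coefficients[["grs"]]
    se <- fit$se[["grs"]]
    list(or = exp(est),
         ci = exp(est + c(-1, 1) * stats::qnorm(0.975) * se),
         p = 2 * stats::pnorm(-abs(est / se)),
         n = sum(keep), fit = fit)
}

#' Internal validation of a GRS panel by a stratified 75/25 split
#'
#' Randomly splits the cohort into a training set (75\%) and a test set
#' (25\%), stratified by case status, then rebuilds the model on the
#' training data alone: per-SNP association, panel membership and
#' ln(OR) weights are all re-estimated from the training samples. Both
#' sets are scored with the training panel; a classification threshold
#' is chosen on the training set (Youden J); and the two AUCs are
#' compared with the unpaired z-test (disjoint subjects, so the DeLong
#' covariance term is zero).
#'
#' @param cohort a [GrsCohort-class].
#' @param variant panel variant passed to [buildPanel()].
#' @param seed RNG seed for the split (bit-reproducible).
#' @param trainFrac training fraction (default 0.75).
#' @param bonferroniM Bonferroni factor for the training association
#'   table.
#' @return list of class \code{psgrsValidation}: \code{trainAuc},
#'   \code{testAuc}, \code{aucComparison}, \code{trainMetrics},
#'   \code{testMetrics}, \code{threshold}, \code{panel},
#'   \code{trainIds}, \code{testIds}, \code{seed}, \code{split}.
#' @export
internalValidation <- function(cohort, variant = "N", seed = 1L,
                               trainFrac = 0.75,
                               bonferroniM = nrow(cohort)) {
    stopifnot(is(cohort, "GrsCohort"))
    set.seed(seed)
    status <- phenotypes(cohort)$status
    ids <- colnames(cohort)
    trainIds <- unlist(lapply(c("case", "control"), function(s) {
        grp <- ids[status == s]
        sample(grp, round(trainFrac * length(grp)))
    }), use.names = FALSE)
    testIds <- setdiff(ids, trainIds)
    if (!all(c("case", "control") %in% status[ids %in% testIds]) ||
        !all(c("case", "control") %in% status[ids %in% trainIds]))
        stop("a split stratum is empty; cohort too small for validation")

    resTrain <- associationTable(cohort, bonferroniM = bonferroniM,
                                 samples = trainIds)
    panel <- buildPanel(resTrain, variant,
                        ldDrop = intersect("rs10484554", resTrain$snp_id),
                        m = bonferroniM,
                        hlaSnp = intersect("rs4406273", resTrain$snp_id))
    ssTrain <- scoreCohort(cohort[, trainIds], panel)
    ssTest <- scoreCohort(cohort[, testIds], panel)
    csTrain <- completeScores(ssTrain)
    csTest <- completeScores(ssTest)
    cmpAuc <- compareAuc(csTrain$case, csTrain$control,
                         csTest$case, csTest$control, paired = FALSE)
    thr <- youdenThreshold(csTrain$case, csTrain$control)
    structure(list(trainAuc = cmpAuc$aucA, testAuc = cmpAuc$aucB,
                   aucComparison = cmpAuc,
                   trainMetrics = confusionMetrics(csTrain$case,
                                                   csTrain$control, thr),
                   testMetrics = confusionMetrics(csTest$case,
                                                  csTest$control, thr),
                   threshold = as.numeric(thr), panel = panel,
                   trainIds = trainIds, testIds = testIds,
                   seed = seed, split = c(trainFrac, 1 - trainFrac)),
              class = "psgrsValidation")
}

#' @export
print.psgrsValidation <- function(x, ...) {
    cat(sprintf(
        "Internal validation (%d/%d split, seed %d, panel '%s', %d SNPs)\n",
        round(100 * x$split[1L]), round(100 * x$split[2L]), x$seed,
        panelName(x$panel), length(x$panel)))
    cat(sprintf("  AUC train %.4f vs test %.4f, unpaired p = %.3g\n",
                x$trainAuc, x$testAuc, x$aucComparison$p))
    cat(sprintf("  accuracy train %.3f vs test %.3f (threshold %.3f)\n",
                x$trainMetrics[["accuracy"]],
                x$testMetrics[["accuracy"]], x$threshold))
    invisible(x)
}

#' Power of the two-proportion allelic association test
#'
#' Normal-approximation power to detect an allelic odds ratio
#' \code{orAlt} at significance \code{alpha} (two-sided), for a
#' case-control study genotyping \code{nCase} cases and \code{nCtrl}
#' controls (2n alleles each): the alternative case risk-allele
#' frequency is [caseRaf()]\code{(p0, orAlt)}, the null critical value
#' uses the pooled-frequency standard error and the alternative uses
#' the unpooled one. At \code{orAlt = 1} the power equals \code{alpha}.
#'
#' @param p0 control risk-allele frequency.
#' @param orAlt alternative allelic odds ratio.
#' @param nCase,nCtrl genotyped sample counts per stratum.
#' @param alpha two-sided significance level.
#' @return power in (0, 1).
#' @examples
#' powerAllelic(0.112, 3.98, 480, 490)   # > 0.999
#' @export
powerAllelic <- function(p0, orAlt, nCase, nCtrl, alpha = 0.05) {
    stopifnot(alpha > 0, alpha < 1)
    p1 <- caseRaf(p0, orAlt)
    m1 <- 2 * nCase
    m0 <- 2 * nCtrl
    pBar <- (m1 * p1 + m0 * p0) / (m1 + m0)
    se0 <- sqrt(pBar * (1 - pBar) * (1 / m1 + 1 / m0))
    se1 <- sqrt(p1 * (1 - p1) / m1 + p0 * (1 - p0) / m0)
    zCrit <- stats::qnorm(1 - alpha / 2)
    delta <- p1 - p0
    stats::pnorm((delta - zCrit * se0) / se1) +
        stats::pnorm((-delta - zCrit * se0) / se1)
}
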