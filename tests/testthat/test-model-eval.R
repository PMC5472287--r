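test_that("the intercept-only fit on balanced classes has intercept
           log(n1/n0)", {
    fit <- fitLogistic(NULL, rep(c(0, 1), each = 25))
    expect_equal(unname(fit$coefficients[1]), 0, tolerance = 1e-8)
    fit2 <- fitLogistic(NULL, rep(c(0, 1), c(30, 60)))
    expect_equal(unname(fit2$coefficients[1]), log(2), tolerance = 1e-8)
    expect_equal(fit2$loglik, fit2$loglikNull, tolerance = 1e-10)
})

test_that("the slope on a binary predictor equals the 2x2 contingency
           log odds ratio", {
    set.seed(50)
    for (i in 1:20) {
        k <- sample(3:60, 4, replace = TRUE)   # (y=1,x=1),(1,0),(0,1),(0,0)
        y <- rep(c(1, 1, 0, 0), k)
        x <- rep(c(1, 0, 1, 0), k)
        fit <- fitLogistic(x, y)
        lor <- log(k[1] * k[4] / (k[2] * k[3]))
        expect_equal(unname(fit$coefficients[2]), lor, tolerance = 1e-6)
    }
})

test_that("logistic parameter recovery at n = 5000", {
    set.seed(51)
    x <- rnorm(5000)
    y <- rbinom(5000, 1, plogis(-0.5 + 1.5 * x))
    fit <- fitLogistic(x, y)
    expect_true(fit$converged)
    expect_lt(abs(fit$coefficients[[2]] - 1.5), 3 * fit$se[[2]])
})

test_that("perfect separation is flagged as non-converged", {
    x <- c(1:10, 21:30)
    y <- rep(c(0, 1), each = 10)
    fit <- fitLogistic(x, y)
    expect_true(fit$separation)
    expect_false(fit$converged)
    expect_error(fitLogistic(1:5, rep(1, 5)), "both outcome classes")
})

test_that("variance explained follows the pseudo-R2 formulas and their
           bounds", {
    set.seed(52)
    x <- rnorm(400)
    y <- rbinom(400, 1, plogis(1.2 * x))
    fit <- fitLogistic(x, y)
    # independent evaluation from the two log-likelihoods
    mcf <- 1 - fit$loglik / fit$loglikNull
    cs <- 1 - exp(2 * (fit$loglikNull - fit$loglik) / fit$n)
    nag <- cs / (1 - exp(2 * fit$loglikNull / fit$n))
    expect_equal(varianceExplained(fit, "mcfadden"), mcf,
                 tolerance = 1e-10)
    expect_equal(varianceExplained(fit, "nagelkerke"), nag,
                 tolerance = 1e-10)
    expect_gt(nag, 0)
    expect_lt(nag, 1)

    # null model explains nothing
    nullFit <- fitLogistic(NULL, y)
    expect_equal(varianceExplained(nullFit, "mcfadden"), 0,
                 tolerance = 1e-8)
    expect_equal(varianceExplained(nullFit, "nagelkerke"), 0,
                 tolerance = 1e-8)

    # a near-perfect predictor approaches 1 under Nagelkerke
    y2 <- rep(c(0, 1), each = 100)
    x2 <- y2 + rnorm(200, sd = 0.05)
    fit2 <- fitLogistic(x2, y2)
    expect_gt(varianceExplained(fit2, "nagelkerke"), 0.95)
})

test_that("nagelkerke R2 grows with added signal in nested models", {
    set.seed(53)
    x1 <- rnorm(600); x2 <- rnorm(600)
    y <- rbinom(600, 1, plogis(0.8 * x1 + 0.8 * x2))
    r1 <- varianceExplained(fitLogistic(x1, y))
    r2 <- varianceExplained(fitLogistic(cbind(x1, x2), y))
    expect_gt(r2, r1)
})

test_that("sub-phenotype recovery: family history at OR 1.83 and a
           protective late-onset link", {
    grsN <- selectPanel(referenceSnpSummary(), "p<0.05")
    set.seed(54)
    ors <- replicate(10, {
        co <- simulateCohort(defaultCohortSpec(
            seed = sample.int(1e6, 1), snpIds = grsN))
        w <- S4Vectors::metadata(co)$generating_weights
        ss <- scoreCohort(co, GrsPanel("gen", names(w), w))
        c(fam = subphenotypeAssociation(ss, phenotypes(co),
                                        "family_history")$or,
          onset = subphenotypeAssociation(ss, phenotypes(co),
                                          "onset_class")$or)
    })
    expect_lt(abs(median(ors["fam", ]) - 1.83), 0.45)
    expect_gte(sum(ors["onset", ] < 1), 8)
})

test_that("sub-phenotype association rejects degenerate inputs", {
    ids <- sprintf("s%d", 1:30)
    ss <- ScoreSet(ids, rnorm(30), rep(TRUE, 30),
                   rep("case", 30), "N")
    ph <- data.frame(nail = rep("yes", 30), row.names = ids)
    expect_error(subphenotypeAssociation(ss, ph, "nail"), "constant")
    ph2 <- data.frame(nail = rep(c("yes", "no", "unknown"), 10),
                      row.names = ids)
    expect_error(subphenotypeAssociation(ss, ph2, "pasi"))
})

test_that("internal validation is deterministic, disjoint and
           exhaustive", {
    grsN <- selectPanel(referenceSnpSummary(), "p<0.05")
    co <- simulateCohort(defaultCohortSpec(seed = 303, snpIds = grsN))
    v1 <- internalValidation(co, "N", seed = 17)
    v2 <- internalValidation(co, "N", seed = 17)
    expect_identical(v1$trainIds, v2$trainIds)
    expect_identical(v1$trainAuc, v2$trainAuc)
    expect_identical(v1$testMetrics, v2$testMetrics)
    expect_length(intersect(v1$trainIds, v1$testIds), 0)
    expect_setequal(c(v1$trainIds, v1$testIds), colnames(co))
    expect_equal(length(v1$trainIds), round(0.75 * ncol(co)))
    v3 <- internalValidation(co, "N", seed = 18)
    expect_false(identical(sort(v3$trainIds), sort(v1$trainIds)))
})

test_that("train and test discrimination agree on simulated cohorts", {
    grsN <- selectPanel(referenceSnpSummary(), "p<0.05")
    set.seed(55)
    ps <- replicate(5, {
        co <- simulateCohort(defaultCohortSpec(
            seed = sample.int(1e6, 1), snpIds = grsN))
        internalValidation(co, "N", seed = 1)$aucComparison$p
    })
    expect_gte(sum(ps > 0.05), 4)
})

test_that("a null cohort validates at chance-level AUC", {
    set.seed(56)
    snps <- data.frame(snp_id = sprintf("rs%d", 1:10),
                       p0 = runif(10, 0.2, 0.8), or_target = 1)
    co <- simulateCohort(CohortSpec(snps, nCase = 300, nCtrl = 300,
                                    seed = 56))
    v <- internalValidation(co, "ALL", seed = 2)
    expect_lt(abs(v$testAuc - 0.5),
              3 * sqrt(1 / 12 * (1 / 75 + 1 / 75)))
})

test_that("allelic power equals alpha under the null and is monotone
           in n and effect size", {
    expect_equal(powerAllelic(0.3, 1, 480, 490), 0.05, tolerance = 1e-10)
    expect_equal(powerAllelic(0.3, 1, 480, 490, alpha = 0.01), 0.01,
                 tolerance = 1e-10)
    p1 <- powerAllelic(0.3, 1.3, 200, 200)
    p2 <- powerAllelic(0.3, 1.3, 400, 400)
    expect_gt(p2, p1)
    expect_gt(powerAllelic(0.3, 1.5, 200, 200), p1)
    # symmetric in direction of effect on the log scale
    expect_gt(powerAllelic(0.3, 1 / 1.3, 400, 400), p1)
    expect_gt(powerAllelic(0.112, 3.98, 480, 490), 0.999)
})
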