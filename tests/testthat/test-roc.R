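test_that("AUC equals the tie-aware pair enumeration", {
    # 4 pairs: 3>1, 3>2, 2>1, 2=2 (half) -> 3.5/4
    expect_equal(rocCurve(c(3, 2), c(1, 2))$auc, 0.875)
    expect_equal(rocCurve(c(5, 6), c(1, 2))$auc, 1)
    expect_error(rocCurve(numeric(0), 1), "at least one")
})

test_that("null scores give AUC near one half at large n", {
    set.seed(9)
    x <- rnorm(1e4)
    y <- rnorm(1e4)
    r <- rocCurve(x, y)
    expect_lt(abs(r$auc - 0.5), 3 * sqrt(r$varAuc))
})

test_that("AUC is antisymmetric and invariant under increasing
           transforms", {
    set.seed(30)
    for (i in 1:5) {
        x <- rnorm(40, 0.5)
        y <- rnorm(50)
        a <- rocCurve(x, y)$auc
        expect_equal(a + rocCurve(y, x)$auc, 1, tolerance = 1e-12)
        expect_equal(rocCurve(exp(x), exp(y))$auc, a, tolerance = 1e-12)
        expect_equal(rocCurve(3 * x - 7, 3 * y - 7)$auc, a,
                     tolerance = 1e-12)
    }
})

test_that("ROC points run from (0,0) to (1,1), non-decreasing, and the
           AUC equals their trapezoidal area", {
    set.seed(31)
    x <- c(rnorm(30, 1), rnorm(5))   # include ties via rounding
    y <- round(rnorm(40), 1)
    r <- rocCurve(round(x, 1), y)
    p <- r$points
    expect_equal(c(p$fpr[1], p$tpr[1]), c(0, 0))
    expect_equal(c(p$fpr[nrow(p)], p$tpr[nrow(p)]), c(1, 1))
    expect_true(all(diff(p$fpr) >= 0) && all(diff(p$tpr) >= 0))
    trap <- sum(diff(p$fpr) * (p$tpr[-1] + p$tpr[-nrow(p)]) / 2)
    expect_equal(trap, r$auc, tolerance = 1e-12)
})

test_that("DeLong AUC and variance agree with pROC", {
    skip_if_not_installed("pROC")
    set.seed(17)
    x <- rnorm(60, 0.7)
    y <- rnorm(80)
    r <- rocCurve(x, y)
    pr <- pROC::roc(cases = x, controls = y, quiet = TRUE,
                    direction = "<")
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    expect_equal(r$varAuc, as.numeric(pROC::var(pr, method = "delong")),
                 tolerance = 1e-10)
})

test_that("DeLong variance is close to the bootstrap variance on a
           small fixture", {
    set.seed(23)
    x <- rnorm(40, 0.8)
    y <- rnorm(40)
    r <- rocCurve(x, y)
    boot <- replicate(1e4, rocCurve(sample(x, replace = TRUE),
                                    sample(y, replace = TRUE))$auc)
    expect_lt(abs(r$varAuc - var(boot)) / var(boot), 0.10)
})

test_that("paired DeLong comparison agrees with pROC and degenerates
           to p 1 on identical scores", {
    skip_if_not_installed("pROC")
    set.seed(41)
    base <- c(rnorm(50, 0.8), rnorm(50))
    labels <- rep(c(1, 0), each = 50)
    a <- base + rnorm(100, sd = 0.4)
    b <- base + rnorm(100, sd = 0.9)
    cmp <- compareAuc(a[labels == 1], a[labels == 0],
                      b[labels == 1], b[labels == 0], paired = TRUE)
    pr <- pROC::roc.test(pROC::roc(labels, a, quiet = TRUE,
                                   direction = "<"),
                         pROC::roc(labels, b, quiet = TRUE,
                                   direction = "<"),
                         method = "delong", paired = TRUE)
    expect_equal(cmp$p, as.numeric(pr$p.value), tolerance = 1e-10)
    expect_equal(cmp$delta,
                 as.numeric(pr$estimate[1] - pr$estimate[2]),
                 tolerance = 1e-12)

    same <- compareAuc(a[labels == 1], a[labels == 0],
                       a[labels == 1], a[labels == 0], paired = TRUE)
    expect_identical(same$p, 1)
    expect_identical(same$delta, 0)
})

test_that("the unpaired comparison is the zero-covariance z-test", {
    set.seed(43)
    xa <- rnorm(40, 1); ya <- rnorm(40)
    xb <- rnorm(50, 0.3); yb <- rnorm(60)
    cmp <- compareAuc(xa, ya, xb, yb, paired = FALSE)
    ra <- rocCurve(xa, ya); rb <- rocCurve(xb, yb)
    z <- (ra$auc - rb$auc) / sqrt(ra$varAuc + rb$varAuc)
    expect_equal(cmp$z, z, tolerance = 1e-12)
    expect_equal(cmp$p, 2 * pnorm(-abs(z)), tolerance = 1e-12)
    expect_error(compareAuc(xa, ya, rnorm(3), yb, paired = TRUE),
                 "identical samples")
})

test_that("ScoreSet comparison drops samples incomplete on either
           panel before pairing", {
    ids <- sprintf("s%d", 1:40)
    st <- rep(c("case", "control"), each = 20)
    set.seed(3)
    sa <- rnorm(40, ifelse(st == "case", 0.5, 0))
    sb <- sa + rnorm(40, sd = 0.5)
    ca <- rep(TRUE, 40); ca[c(1, 25)] <- FALSE
    cb <- rep(TRUE, 40); cb[c(2, 25)] <- FALSE
    ssa <- ScoreSet(ids, sa, ca, st, "A")
    ssb <- ScoreSet(ids, sb, cb, st, "B")
    cmp <- compareAucSets(ssa, ssb)
    keep <- ca & cb
    ref <- compareAuc(sa[keep & st == "case"], sa[keep & st == "control"],
                      sb[keep & st == "case"], sb[keep & st == "control"])
    expect_equal(cmp$p, ref$p, tolerance = 1e-12)
})

test_that("confusion metrics count the 2x2 table at the threshold", {
    cases <- c(rep(1, 7), rep(-1, 3))
    ctrls <- c(rep(-1, 8), rep(1, 2))
    m <- confusionMetrics(cases, ctrls, 0)
    expect_equal(m[["sensitivity"]], 0.7)
    expect_equal(m[["specificity"]], 0.8)
    expect_equal(m[["accuracy"]], 0.75)
    expect_equal(m[["ppv"]], 7 / 9)
    expect_equal(m[["npv"]], 8 / 11)

    lo <- confusionMetrics(cases, ctrls, -5)
    expect_equal(lo[["sensitivity"]], 1)
    expect_equal(lo[["specificity"]], 0)
    expect_true("npv" %in% attr(lo, "undefined"))
    hi <- confusionMetrics(cases, ctrls, 5)
    expect_equal(hi[["sensitivity"]], 0)
    expect_equal(hi[["specificity"]], 1)
})

test_that("the Youden threshold matches an exhaustive scan and uses
           the midpoint convention under perfect separation", {
    sep <- youdenThreshold(c(2, 3), c(0, 1))
    expect_equal(as.numeric(sep), 1.5)
    expect_equal(attr(sep, "J"), 1)

    set.seed(77)
    x <- round(rnorm(50, 0.8), 1)
    y <- round(rnorm(60), 1)
    thr <- youdenThreshold(x, y)
    # brute-force scan over a fine grid of cut-offs
    grid <- seq(min(c(x, y)) - 1, max(c(x, y)) + 1, by = 1e-3)
    jGrid <- vapply(grid, function(t) mean(x >= t) - mean(y >= t), 0)
    expect_equal(attr(thr, "J"), max(jGrid), tolerance = 1e-12)

    # null scores: J stays near zero
    expect_lt(attr(youdenThreshold(rnorm(500), rnorm(500)), "J"), 0.2)
})
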