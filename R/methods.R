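#' @rdname GrsCohort-class
#' @export
setMethod("dosages", "GrsCohort", function(x) assay(x, "dosage"))

#' @rdname GrsCohort-class
#' @export
setMethod("snpMeta", "GrsCohort", function(x) rowData(x))

#' @rdname GrsCohort-class
#' @export
setMethod("phenotypes", "GrsCohort", function(x) colData(x))

#' @rdname GrsCohort-class
#' @export
setMethod("missingRate", "GrsCohort",
    function(x, per = c("snp", "sample", "overall")) {
        per <- match.arg(per)
        d <- dosages(x)
        switch(per,
            snp = rowMeans(is.na(d)),
            sample = colMeans(is.na(d)),
            overall = mean(is.na(d)))
    })

setMethod("show", "GrsCohort", function(object) {
    st <- colData(object)$status
    cat(sprintf("GrsCohort: %d SNPs x %d samples (%d cases / %d controls)\n",
                nrow(object), ncol(object),
                sum(st == "case"), sum(st == "control")))
    cat(sprintf("  overall missing dosage fraction: %.4f\n",
                mean(is.na(assay(object, "dosage")))))
    cat("  snpMeta columns:", paste(names(rowData(object)), collapse = ", "),
        "\n")
    cat("  phenotype columns:",
        paste(names(colData(object)), collapse = ", "), "\n")
})

#' @rdname GrsPanel-class
#' @export
setMethod("panelName", "GrsPanel", function(x) x@name)

#' @rdname GrsPanel-class
#' @export
setMethod("panelSnps", "GrsPanel", function(x) x@snpIds)

#' @rdname GrsPanel-class
#' @export
setMethod("panelWeights", "GrsPanel", function(x) x@weights)

#' @rdname GrsPanel-class
#' @export
setMethod("length", "GrsPanel", function(x) length(x@snpIds))

setMethod("show", "GrsPanel", function(object) {
    cat(sprintf("GrsPanel '%s': %d SNPs\n", object@name,
                length(object@snpIds)))
    w <- object@weights
    k <- min(length(w), 5L)
    if (k > 0L)
        cat("  weights (ln OR):",
            paste(sprintf("%s=%.3f", names(w)[seq_len(k)], w[seq_len(k)]),
                  collapse = ", "),
            if (length(w) > k) "..." else "", "\n")
})

#' @rdname ScoreSet-class
#' @param x,object a \code{ScoreSet}.
#' @export
setMethod("scores", "ScoreSet", function(x) {
    stats::setNames(x@score, x@sampleIds)
})

#' @rdname ScoreSet-class
#' @export
setMethod("isComplete", "ScoreSet", function(x) {
    stats::setNames(x@complete, x@sampleIds)
})

#' @rdname ScoreSet-class
#' @export
setMethod("sampleStatus", "ScoreSet", function(x) {
    stats::setNames(x@status, x@sampleIds)
})

#' @rdname ScoreSet-class
#' @export
setMethod("length", "ScoreSet", function(x) length(x@sampleIds))

setMethod("show", "ScoreSet", function(object) {
    ok <- object@complete
    cat(sprintf("ScoreSet (panel '%s'): %d samples, %d complete\n",
                object@panelName, length(ok), sum(ok)))
    if (any(ok))
        cat(sprintf("  score range (complete): [%.3f, %.3f]\n",
                    min(object@score[ok]), max(object@score[ok])))
})

#' Per-stratum complete scores
#'
#' Convenience splitter: the scores of complete cases and complete
#' controls of a [ScoreSet-class], the form every downstream statistic
#' (ROC, quartiles, regression) consumes.
#'
#' @param x a \code{ScoreSet}.
#' @return list with numeric vectors \code{case} and \code{control}.
#' @export
completeScores <- function(x) {
    stopifnot(is(x, "ScoreSet"))
    ok <- x@complete
    list(case = x@score[ok & x@status == "case"],
         control = x@score[ok & x@status == "control"])
}
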