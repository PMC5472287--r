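#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowData colData assay<- colData<-
#' @importFrom stats setNames
NULL

.VALID_STATUS <- c("case", "control")
.VALID_ONSET <- c("T1Ps", "T2Ps", "none")
.VALID_YNU <- c("yes", "no", "unknown")
.BASES <- c("A", "C", "G", "T")

#' GrsCohort: a genotyped case-control cohort
#'
#' An S4 container for a case-control cohort genotyped at a panel of SNPs,
#' extending \linkS4class{SummarizedExperiment}. The single assay,
#' \code{"dosage"}, holds additive risk-allele dosages (0, 1, 2 or \code{NA}
#' for a failed genotype) with SNPs as rows and samples as columns.
#' \code{rowData} carries the SNP metadata (chromosomal band, gene label,
#' risk and other allele, and optionally literature odds ratio and control
#' risk-allele frequency); \code{colData} carries the phenotype table
#' (case/control status, onset class, nail psoriasis, psoriatic arthritis,
#' family history).
#'
#' Dosages are always oriented to the declared risk allele: a dosage of 2
#' means homozygous for the risk allele. Controls always have onset class
#' \code{"none"}.
#'
#' @seealso [GrsCohort()] the constructor, [readCohort()], [simulateCohort()]
#' @name GrsCohort-class
#' @aliases GrsCohort-class
#' @exportClass GrsCohort
setClass("GrsCohort", contains = "SummarizedExperiment")

setValidity("GrsCohort", function(object) {
    msg <- character()
    if (!"dosage" %in% names(assays(object)))
        return("assay 'dosage' is required")
    d <- assay(object, "dosage")
    ok <- is.na(d) | d %in% c(0, 1, 2)
    if (!all(ok))
        msg <- c(msg, "dosages must be 0, 1, 2 or NA")
    if (nrow(object) > 0L &&
        (is.null(rownames(object)) || anyDuplicated(rownames(object))))
        msg <- c(msg, "SNP ids (rownames) must be present and unique")
    if (ncol(object) > 0L &&
        (is.null(colnames(object)) || anyDuplicated(colnames(object))))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    rd <- rowData(object)
    for (col in c("risk_allele", "other_allele")) {
        if (!col %in% names(rd))
            msg <- c(msg, sprintf("rowData column '%s' is required", col))
    }
    if (all(c("risk_allele", "other_allele") %in% names(rd))) {
        if (!all(rd$risk_allele %in% .BASES) ||
            !all(rd$other_allele %in% .BASES))
            msg <- c(msg, "alleles must be single bases A/C/G/T")
        if (any(rd$risk_allele == rd$other_allele))
            msg <- c(msg, "risk_allele must differ from other_allele")
    }
    cd <- colData(object)
    if (!"status" %in% names(cd)) {
        msg <- c(msg, "colData column 'status' is required")
    } else {
        if (!all(cd$status %in% .VALID_STATUS))
            msg <- c(msg, "status must be 'case' or 'control'")
        if ("onset_class" %in% names(cd)) {
            if (!all(cd$onset_class %in% .VALID_ONSET))
                msg <- c(msg, "onset_class must be T1Ps, T2Ps or none")
            bad <- cd$status == "control" & cd$onset_class != "none"
            if (any(bad))
                msg <- c(msg, "controls must have onset_class 'none'")
        }
        for (col in intersect(c("nail", "psa", "family_history"), names(cd)))
            if (!all(cd[[col]] %in% .VALID_YNU))
                msg <- c(msg, sprintf("'%s' must be yes/no/unknown", col))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a GrsCohort
#'
#' @param dosage numeric matrix of risk-allele dosages, SNPs in rows and
#'   samples in columns; values 0/1/2/\code{NA}. Row and column names supply
#'   the SNP and sample identifiers.
#' @param snpMeta data.frame (or DataFrame) with one row per SNP, in matrix
#'   row order; must contain \code{risk_allele} and \code{other_allele},
#'   and may carry \code{chrom_band}, \code{gene}, \code{ref_or},
#'   \code{ref_raf}.
#' @param phenotype data.frame with one row per sample, in matrix column
#'   order; must contain \code{status} ("case"/"control"); the
#'   sub-phenotype columns \code{onset_class}, \code{nail}, \code{psa},
#'   \code{family_history} are optional and default to
#'   "none"/"unknown".
#'
#' @return a [GrsCohort-class] object.
#' @examples
#' d <- matrix(c(0, 1, 2, NA), nrow = 2,
#'             dimnames = list(c("rs1", "rs2"), c("s1", "s2")))
#' meta <- data.frame(risk_allele = c("A", "C"), other_allele = c("G", "T"))
#' ph <- data.frame(status = c("case", "control"))
#' GrsCohort(d, meta, ph)
#' @export
GrsCohort <- function(dosage, snpMeta, phenotype) {
    dosage <- as.matrix(dosage)
    storage.mode(dosage) <- "double"
    snpMeta <- as.data.frame(snpMeta)
    phenotype <- as.data.frame(phenotype)
    if (nrow(snpMeta) != nrow(dosage))
        stop("snpMeta must have one row per SNP")
    if (nrow(phenotype) != ncol(dosage))
        stop("phenotype must have one row per sample")
    if ("snp_id" %in% names(snpMeta) && is.null(rownames(dosage)))
        rownames(dosage) <- snpMeta$snp_id
    if ("sample_id" %in% names(phenotype) && is.null(colnames(dosage)))
        colnames(dosage) <- phenotype$sample_id
    phenotype$sample_id <- NULL
    snpMeta$snp_id <- NULL
    if (!"onset_class" %in% names(phenotype))
        phenotype$onset_class <- ifelse(phenotype$status == "case",
                                        "T1Ps", "none")
    for (col in c("nail", "psa", "family_history"))
        if (!col %in% names(phenotype))
            phenotype[[col]] <- rep("unknown", nrow(phenotype))
    se <- SummarizedExperiment(
        assays = list(dosage = dosage),
        rowData = DataFrame(snpMeta, row.names = rownames(dosage)),
        colData = DataFrame(phenotype, row.names = colnames(dosage)))
    new("GrsCohort", se)
}

#' GrsPanel: a named set of score SNPs with log-odds weights
#'
#' A weighted SNP panel used to compute a genetic risk score. The score of
#' a sample is the sum over panel SNPs of risk-allele dosage times the
#' SNP's weight, the natural log of its allelic odds ratio.
#'
#' Named variants follow the study's panel hierarchy: \code{ALL} (every
#' analysed SNP minus the LD-dropped proxy), \code{0.1} (uncorrected
#' p < 0.1), \code{N} (nominal, p < 0.05), \code{B} (Bonferroni
#' survivors), \code{HLA} (the HLA-C tag SNP alone), \code{N(+)HLA(-)}
#' (N without the HLA-C tag) and \code{N(subst.)} (N with the HLA-C tag
#' replaced by its LD partner).
#'
#' @slot name character; panel variant label.
#' @slot snpIds character; SNP identifiers, unique, in stable order.
#' @slot weights named numeric; finite ln(OR) weight per SNP.
#' @seealso [buildPanel()], [scoreCohort()]
#' @exportClass GrsPanel
setClass("GrsPanel",
    representation(name = "character", snpIds = "character",
                   weights = "numeric"))

setValidity("GrsPanel", function(object) {
    msg <- character()
    if (length(object@name) != 1L)
        msg <- c(msg, "name must be a single string")
    if (anyDuplicated(object@snpIds))
        msg <- c(msg, "snpIds must be unique")
    if (length(object@weights) != length(object@snpIds))
        msg <- c(msg, "one weight per SNP required")
    if (!identical(names(object@weights), object@snpIds))
        msg <- c(msg, "weights must be named by snpIds, in order")
    if (any(!is.finite(object@weights)))
        msg <- c(msg, "weights must be finite")
    if (length(msg)) msg else TRUE
})

#' @describeIn GrsPanel-class constructor.
#' @param name panel label.
#' @param snpIds SNP identifiers.
#' @param weights ln(OR) weights, either named by SNP or in \code{snpIds}
#'   order.
#' @export
GrsPanel <- function(name, snpIds, weights) {
    if (is.null(names(weights))) names(weights) <- snpIds
    new("GrsPanel", name = as.character(name),
        snpIds = as.character(snpIds),
        weights = weights[snpIds])
}

#' ScoreSet: per-sample genetic risk scores
#'
#' Holds the genetic risk score of each sample under one panel, together
#' with a completeness flag: a sample is complete only if none of the
#' panel SNP dosages is missing for it. Incomplete samples carry an
#' \code{NA} score and are excluded from every downstream statistic
#' (quartiles, ROC, regression), mirroring listwise exclusion of
#' partially genotyped subjects.
#'
#' @slot sampleIds character sample identifiers.
#' @slot score numeric; \code{NA} where incomplete.
#' @slot complete logical completeness flags.
#' @slot status character "case"/"control" per sample.
#' @slot panelName label of the generating panel.
#' @seealso [scoreCohort()]
#' @exportClass ScoreSet
setClass("ScoreSet",
    representation(sampleIds = "character", score = "numeric",
                   complete = "logical", status = "character",
                   panelName = "character"))

setValidity("ScoreSet", function(object) {
    n <- length(object@sampleIds)
    msg <- character()
    if (length(object@score) != n || length(object@complete) != n ||
        length(object@status) != n)
        msg <- c(msg, "sampleIds, score, complete, status must align")
    if (any(!object@complete & !is.na(object@score)))
        msg <- c(msg, "incomplete samples must have NA score")
    if (any(object@complete & is.na(object@score)))
        msg <- c(msg, "complete samples must have a score")
    if (!all(object@status %in% .VALID_STATUS))
        msg <- c(msg, "status must be 'case' or 'control'")
    if (length(msg)) msg else TRUE
})

ScoreSet <- function(sampleIds, score, complete, status, panelName) {
    score[!complete] <- NA_real_
    new("ScoreSet", sampleIds = sampleIds, score = as.numeric(score),
        complete = complete, status = as.character(status),
        panelName = as.character(panelName))
}

#' CohortSpec: parameters of a simulated case-control cohort
#'
#' Describes the generating model of [simulateCohort()]: per-SNP control
#' risk-allele frequency and target allelic odds ratio, stratum sizes, an
#' optional pair of SNPs in linkage disequilibrium at a target r-squared,
#' a missing-genotype rate, and logistic links from the genetic risk
#' score to case sub-phenotypes.
#'
#' @slot snps data.frame with columns \code{snp_id}, \code{p0} (control
#'   RAF in (0,1)) and \code{or_target} (> 0), plus optional allele and
#'   annotation columns carried through to the simulated cohort.
#' @slot nCase,nCtrl stratum sizes.
#' @slot ldPair either an empty list or \code{list(a=, b=, r2=)} naming
#'   two spec SNPs and the target squared allelic correlation.
#' @slot missingRate per-cell probability a genotype is set missing;
#'   must be below 0.05.
#' @slot subphenoEffects named numeric log-odds per unit of GRS for the
#'   traits \code{nail}, \code{psa}, \code{onset_class} (probability of
#'   late onset) and \code{family_history}.
#' @slot subphenoPrevalence named numeric target marginal prevalence of
#'   each trait among cases.
#' @slot seed integer RNG seed.
#' @seealso [defaultCohortSpec()], [simulateCohort()]
#' @exportClass CohortSpec
setClass("CohortSpec",
    representation(snps = "data.frame", nCase = "integer", nCtrl = "integer",
                   ldPair = "list", missingRate = "numeric",
                   subphenoEffects = "numeric",
                   subphenoPrevalence = "numeric", seed = "integer"))

setValidity("CohortSpec", function(object) {
    msg <- character()
    s <- object@snps
    if (!all(c("snp_id", "p0", "or_target") %in% names(s)))
        return("snps needs columns snp_id, p0, or_target")
    if (anyDuplicated(s$snp_id))
        msg <- c(msg, "snp_id must be unique")
    if (any(s$p0 <= 0 | s$p0 >= 1))
        msg <- c(msg, "p0 must lie strictly in (0, 1)")
    if (any(s$or_target <= 0))
        msg <- c(msg, "or_target must be positive")
    if (object@nCase < 1L || object@nCtrl < 1L)
        msg <- c(msg, "both strata must be non-empty")
    if (object@missingRate < 0 || object@missingRate >= 0.05)
        msg <- c(msg, "missingRate must be in [0, 0.05)")
    if (length(object@ldPair)) {
        lp <- object@ldPair
        if (!all(c("a", "b", "r2") %in% names(lp)))
            msg <- c(msg, "ldPair needs elements a, b, r2")
        else {
            if (!all(c(lp$a, lp$b) %in% s$snp_id))
                msg <- c(msg, "ldPair SNPs must be in the spec")
            if (lp$r2 < 0 || lp$r2 > 1)
                msg <- c(msg, "r2 must lie in [0, 1]")
        }
    }
    extra <- setdiff(names(object@subphenoEffects),
                     c("nail", "psa", "onset_class", "family_history"))
    if (length(extra))
        msg <- c(msg, paste("unknown sub-phenotype trait(s):",
                            paste(extra, collapse = ", ")))
    if (length(msg)) msg else TRUE
})
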