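#' Read a SNP metadata table
#'
#' Tab-separated, one row per SNP with columns \code{snp_id},
#' \code{risk_allele}, \code{other_allele} and any annotation columns
#' (\code{chrom_band}, \code{gene}, \code{ref_or}, \code{ref_raf}).
#'
#' @param path file path.
#' @return data.frame of SNP metadata.
#' @export
readSnpMeta <- function(path) {
    meta <- utils::read.delim(path, stringsAsFactors = FALSE,
                              check.names = FALSE)
    need <- c("snp_id", "risk_allele", "other_allele")
    miss <- setdiff(need, names(meta))
    if (length(miss))
        stop("SNP metadata lacks column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(meta$snp_id))
        stop("duplicate snp_id in ", path)
    bad <- !(meta$risk_allele %in% .BASES) | !(meta$other_allele %in% .BASES)
    if (any(bad))
        stop("allele not in {A,C,G,T} for SNP(s): ",
             paste(meta$snp_id[bad], collapse = ", "))
    meta
}

#' Read a phenotype table
#'
#' Tab-separated with columns \code{sample_id}, \code{status}
#' (case/control) and optionally \code{onset_class}, \code{nail},
#' \code{psa}, \code{family_history}.
#'
#' @param path file path.
#' @return data.frame of phenotypes.
#' @export
readPhenotypes <- function(path) {
    ph <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character", check.names = FALSE)
    if (!all(c("sample_id", "status") %in% names(ph)))
        stop("phenotype table needs columns sample_id and status")
    if (anyDuplicated(ph$sample_id))
        stop("duplicate sample_id in ", path)
    ph
}

#' Read a genotype matrix
#'
#' Two carriers are supported. \code{"tsv"}: a tab-separated table whose
#' header row names the SNPs, whose first column (\code{sample_id}) names
#' the samples, and whose cells are risk-allele dosages 0/1/2 with
#' missing genotypes written \code{NA}. \code{"pedmap"}: a PLINK-style
#' text ped/map pair; the map file gives SNP order, the ped file carries
#' six leading columns (family id, sample id, father, mother, sex,
#' phenotype) followed by one space-separated allele pair per SNP, with
#' allele code \code{0} meaning missing. Dosages are oriented to the risk
#' allele declared in \code{meta}; an allele pair containing a base that
#' is neither the risk nor the other allele of that SNP is treated as an
#' inconsistent call and set missing.
#'
#' @param path the genotype TSV, or the ped file.
#' @param format \code{"tsv"} or \code{"pedmap"}.
#' @param meta SNP metadata data.frame, required for \code{"pedmap"}
#'   (allele orientation); optional for \code{"tsv"}.
#' @param mapPath the map file (defaults to \code{path} with its
#'   extension replaced by \code{.map}).
#' @return numeric matrix of dosages, SNPs x samples.
#' @export
readGenotypes <- function(path, format = c("tsv", "pedmap"), meta = NULL,
                          mapPath = NULL) {
    format <- match.arg(format)
    if (format == "tsv") .readGenotypesTsv(path)
    else .readGenotypesPedmap(path, mapPath, meta)
}

.readGenotypesTsv <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    if (names(tab)[1L] != "sample_id")
        stop("malformed genotype header: first column must be sample_id")
    if (ncol(tab) < 2L)
        stop("malformed genotype header: no SNP columns")
    snps <- names(tab)[-1L]
    if (anyDuplicated(snps))
        stop("duplicate SNP id in genotype header")
    if (anyDuplicated(tab$sample_id))
        stop("duplicate sample id in genotype file")
    d <- t(as.matrix(tab[, -1L, drop = FALSE]))
    storage.mode(d) <- "double"
    bad <- !is.na(d) & !(d %in% c(0, 1, 2))
    if (any(bad))
        stop("dosage outside {0,1,2,NA} in genotype file")
    dimnames(d) <- list(snps, tab$sample_id)
    d
}

.readGenotypesPedmap <- function(path, mapPath, meta) {
    if (is.null(meta))
        stop("ped/map import needs SNP metadata for allele orientation")
    if (is.null(mapPath))
        mapPath <- sub("\\.ped$", ".map", path)
    map <- utils::read.table(mapPath, stringsAsFactors = FALSE)
    if (ncol(map) < 4L) stop("malformed map file: expected 4 columns")
    snps <- map[[2L]]
    if (anyDuplicated(snps)) stop("duplicate SNP id in map file")
    unknown <- setdiff(snps, meta$snp_id)
    if (length(unknown))
        stop("map SNP(s) absent from metadata: ",
             paste(unknown, collapse = ", "))
    meta <- meta[match(snps, meta$snp_id), ]

    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    nSnp <- length(snps)
    d <- matrix(NA_real_, nrow = nSnp, ncol = length(lines),
                dimnames = list(snps, NULL))
    ids <- character(length(lines))
    for (i in seq_along(lines)) {
        f <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
        if (length(f) != 6L + 2L * nSnp)
            stop(sprintf("ped line %d: expected %d fields, found %d",
                         i, 6L + 2L * nSnp, length(f)))
        ids[i] <- f[2L]
        a1 <- f[seq(7L, by = 2L, length.out = nSnp)]
        a2 <- f[seq(8L, by = 2L, length.out = nSnp)]
        bad <- !(a1 %in% c(.BASES, "0")) | !(a2 %in% c(.BASES, "0"))
        if (any(bad))
            stop(sprintf("ped line %d: allele not in {A,C,G,T,0} at SNP %s",
                         i, snps[which(bad)[1L]]))
        known <- a1 != "0" & a2 != "0"
        consistent <- known &
            a1 %in% c(meta$risk_allele, meta$other_allele) &
            a2 %in% c(meta$risk_allele, meta$other_allele) &
            (a1 == meta$risk_allele | a1 == meta$other_allele) &
            (a2 == meta$risk_allele | a2 == meta$other_allele)
        dose <- (a1 == meta$risk_allele) + (a2 == meta$risk_allele)
        dose[!consistent] <- NA_real_
        d[, i] <- dose
    }
    if (anyDuplicated(ids)) stop("duplicate sample id in ped file")
    colnames(d) <- ids
    d
}

#' Read a cohort directory
#'
#' Assembles a [GrsCohort-class] from the three files written by
#' [writeCohort()]: \code{genotypes.tsv} (or \code{cohort.ped} /
#' \code{cohort.map}), \code{phenotypes.tsv} and \code{snps.tsv}.
#'
#' @param dir directory path.
#' @param format genotype carrier, \code{"tsv"} or \code{"pedmap"}.
#' @return a [GrsCohort-class].
#' @export
readCohort <- function(dir, format = c("tsv", "pedmap")) {
    format <- match.arg(format)
    meta <- readSnpMeta(file.path(dir, "snps.tsv"))
    ph <- readPhenotypes(file.path(dir, "phenotypes.tsv"))
    d <- if (format == "tsv")
        readGenotypes(file.path(dir, "genotypes.tsv"), "tsv")
    else
        readGenotypes(file.path(dir, "cohort.ped"), "pedmap", meta = meta,
                      mapPath = file.path(dir, "cohort.map"))
    if (!setequal(colnames(d), ph$sample_id))
        stop("genotyped samples and phenotype rows disagree")
    ph <- ph[match(colnames(d), ph$sample_id), ]
    if (!identical(rownames(d), meta$snp_id))
        meta <- meta[match(rownames(d), meta$snp_id), ]
    GrsCohort(d, meta, ph)
}

#' Write a cohort directory
#'
#' Writes \code{snps.tsv}, \code{phenotypes.tsv} and either
#' \code{genotypes.tsv} (dosages, missing as \code{NA}) or a
#' \code{cohort.ped}/\code{cohort.map} pair (allele pairs, missing as
#' \code{0 0}). Output is byte-stable for a given cohort: rows follow
#' the cohort's sample order and columns its SNP order. Round-tripping
#' through [readCohort()] reproduces every dosage, including missing
#' cells.
#'
#' @param cohort a [GrsCohort-class].
#' @param dir output directory, created if absent.
#' @param format genotype carrier, \code{"tsv"} or \code{"pedmap"}.
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir, format = c("tsv", "pedmap")) {
    stopifnot(is(cohort, "GrsCohort"))
    format <- match.arg(format)
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
        stop("cannot create directory ", dir)
    meta <- data.frame(snp_id = rownames(cohort),
                       as.data.frame(snpMeta(cohort)),
                       check.names = FALSE)
    utils::write.table(meta, file.path(dir, "snps.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sampleIds <- colnames(cohort)
    if (is.null(sampleIds)) sampleIds <- character(0)
    ph <- data.frame(sample_id = sampleIds,
                     as.data.frame(phenotypes(cohort)),
                     check.names = FALSE)
    utils::write.table(ph, file.path(dir, "phenotypes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    d <- dosages(cohort)
    if (format == "tsv") {
        tab <- data.frame(sample_id = sampleIds,
                          as.data.frame(t(d), check.names = FALSE),
                          check.names = FALSE)
        utils::write.table(tab, file.path(dir, "genotypes.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    } else {
        .writePedmap(cohort, dir)
    }
    invisible(dir)
}

.writePedmap <- function(cohort, dir) {
    meta <- snpMeta(cohort)
    d <- dosages(cohort)
    map <- data.frame(chr = 0L, snp = rownames(cohort), cm = 0L, pos = 0L)
    utils::write.table(map, file.path(dir, "cohort.map"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    risk <- meta$risk_allele
    other <- meta$other_allele
    ph <- phenotypes(cohort)
    pedPheno <- ifelse(ph$status == "case", 2L, 1L)
    con <- file(file.path(dir, "cohort.ped"), "w")
    on.exit(close(con))
    for (j in seq_len(ncol(d))) {
        dose <- d[, j]
        a1 <- ifelse(is.na(dose), "0", ifelse(dose >= 1, risk, other))
        a2 <- ifelse(is.na(dose), "0", ifelse(dose == 2, risk, other))
        writeLines(paste(c(colnames(d)[j], colnames(d)[j], "0", "0", "0",
                           pedPheno[j], rbind(a1, a2)), collapse = " "),
                   con)
    }
}

#' Flip the risk/other allele orientation of SNPs
#'
#' Re-expresses the dosages of the given SNPs on the opposite allele:
#' every non-missing dosage d becomes 2 - d, and the risk and other
#' alleles are swapped in the metadata. Missing cells stay missing.
#'
#' @param cohort a [GrsCohort-class].
#' @param snps SNP ids to flip (default: all).
#' @return the re-oriented [GrsCohort-class].
#' @export
flipRiskAllele <- function(cohort, snps = rownames(cohort)) {
    stopifnot(is(cohort, "GrsCohort"))
    bad <- setdiff(snps, rownames(cohort))
    if (length(bad))
        stop("unknown SNP(s): ", paste(bad, collapse = ", "))
    d <- dosages(cohort)
    idx <- rownames(cohort) %in% snps
    d[idx, ] <- 2 - d[idx, , drop = FALSE]
    meta <- as.data.frame(snpMeta(cohort))
    tmp <- meta$risk_allele[idx]
    meta$risk_allele[idx] <- meta$other_allele[idx]
    meta$other_allele[idx] <- tmp
    GrsCohort(d, meta, as.data.frame(phenotypes(cohort)))
}

#' Published per-SNP association summary
#'
#' The 38-SNP psoriasis association summary that anchors the package's
#' worked examples and the simulator defaults: for each SNP its
#' chromosomal band, gene label, risk allele, risk-allele frequency in
#' controls and in cases, allelic odds ratio with 95\% confidence
#' interval, and p-value, as published for a Polish case-control cohort
#' of 480 patients and 490 controls. The published table reports only
#' the risk allele; the \code{other_allele} column here is a synthetic
#' placeholder (the transition partner of the risk allele) used solely
#' to label ped-format output, and enters no statistic.
#'
#' @return data.frame with columns \code{snp_id}, \code{chrom_band},
#'   \code{gene}, \code{risk_allele}, \code{other_allele},
#'   \code{raf_ctrl}, \code{raf_case}, \code{or}, \code{ci_lo},
#'   \code{ci_hi}, \code{p}.
#' @examples
#' head(referenceSnpSummary())
#' @export
referenceSnpSummary <- function() {
    path <- system.file("extdata", "ps_snp_summary.tsv", package = "psgrs",
                        mustWork = TRUE)
    utils::read.delim(path, stringsAsFactors = FALSE)
}
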