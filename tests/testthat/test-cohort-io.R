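test_that("genotype TSV round-trips dosages including missing cells", {
    co <- makeTinyCohort()
    dir <- withr::local_tempdir()
    writeCohort(co, dir, format = "tsv")
    back <- readCohort(dir, format = "tsv")
    expect_identical(dosages(back), dosages(co))
    expect_identical(as.data.frame(snpMeta(back))[c("risk_allele",
                                                    "other_allele")],
                     as.data.frame(snpMeta(co))[c("risk_allele",
                                                  "other_allele")])
    expect_identical(phenotypes(back)$status, phenotypes(co)$status)
    expect_identical(sum(is.na(dosages(back))), 1L)
})

test_that("TSV fixture with one NA yields exactly one missing cell", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("sample_id\trsA\trsB",
                 "s1\t0\t2",
                 "s2\tNA\t1",
                 "s3\t1\t0"), path)
    d <- readGenotypes(path, "tsv")
    expect_identical(dim(d), c(2L, 3L))
    expect_identical(sum(is.na(d)), 1L)
    expect_true(is.na(d["rsA", "s2"]))
    expect_identical(d["rsB", ], c(s1 = 2, s2 = 1, s3 = 0))
})

test_that("ped/map parsing matches a hand-parse of the fixture", {
    dir <- withr::local_tempdir()
    meta <- data.frame(snp_id = c("rsA", "rsB"),
                       risk_allele = c("A", "C"),
                       other_allele = c("G", "T"),
                       stringsAsFactors = FALSE)
    writeLines(c("1\trsA\t0\t0", "1\trsB\t0\t0"),
               file.path(dir, "fix.map"))
    # hand-parsed expectations per line: risk-allele counts
    writeLines(c(
        "f1 s1 0 0 0 2 A A C C",   # rsA hom risk (2), rsB hom risk (2)
        "f2 s2 0 0 0 1 G G T T",   # other/other -> 0, 0
        "f3 s3 0 0 0 1 A G C T",   # het -> 1, 1
        "f4 s4 0 0 0 2 0 0 C T",   # ped missing code -> NA, 1
        "f5 s5 0 0 0 1 G A T T",   # order-free het -> 1, 0
        "f6 s6 0 0 0 2 A A C A"    # C/A inconsistent at rsB -> 2, NA
    ), file.path(dir, "fix.ped"))
    d <- readGenotypes(file.path(dir, "fix.ped"), "pedmap", meta = meta,
                       mapPath = file.path(dir, "fix.map"))
    expect_identical(d["rsA", ],
                     c(s1 = 2, s2 = 0, s3 = 1, s4 = NA, s5 = 1, s6 = 2))
    expect_identical(d["rsB", ],
                     c(s1 = 2, s2 = 0, s3 = 1, s4 = 1, s5 = 0, s6 = NA))
})

test_that("ped/map round-trips through writeCohort", {
    set.seed(42)
    co <- randomCohort(nSnp = 3, nCase = 8, nCtrl = 9, missingRate = 0.04)
    dir <- withr::local_tempdir()
    writeCohort(co, dir, format = "pedmap")
    back <- readCohort(dir, format = "pedmap")
    expect_identical(dosages(back), dosages(co))
})

test_that("random cohorts round-trip in both formats", {
    set.seed(99)
    for (i in 1:3) {
        co <- randomCohort()
        for (fmt in c("tsv", "pedmap")) {
            dir <- withr::local_tempdir()
            writeCohort(co, dir, format = fmt)
            expect_identical(dosages(readCohort(dir, format = fmt)),
                             dosages(co))
        }
    }
})

test_that("an empty cohort round-trips", {
    d <- matrix(numeric(0), nrow = 2, ncol = 0,
                dimnames = list(c("rs1", "rs2"), character(0)))
    meta <- data.frame(snp_id = c("rs1", "rs2"),
                       risk_allele = c("A", "C"),
                       other_allele = c("G", "T"))
    ph <- data.frame(sample_id = character(0), status = character(0))
    co <- GrsCohort(d, meta, ph)
    dir <- withr::local_tempdir()
    writeCohort(co, dir, format = "tsv")
    back <- readCohort(dir, format = "tsv")
    expect_identical(dim(back), c(2L, 0L))
})

test_that("output is byte-stable under fixed sample and SNP order", {
    set.seed(7)
    co <- randomCohort(nSnp = 5, nCase = 20, nCtrl = 20)
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    writeCohort(co, d1)
    writeCohort(co, d2)
    for (f in c("genotypes.tsv", "phenotypes.tsv", "snps.tsv"))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
})

test_that("flipping the risk allele maps dosage d to 2 - d", {
    set.seed(3)
    co <- randomCohort(missingRate = 0.15)
    flipped <- flipRiskAllele(co)
    expect_identical(dosages(flipped), 2 - dosages(co))
    expect_identical(snpMeta(flipped)$risk_allele,
                     snpMeta(co)$other_allele)
    # flipping twice restores the original exactly
    expect_identical(dosages(flipRiskAllele(flipped)), dosages(co))
})

test_that("malformed inputs are rejected with informative errors", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("sample\trsA", "s1\t0"), path)
    expect_error(readGenotypes(path, "tsv"), "sample_id")

    writeLines(c("sample_id\trsA\trsA", "s1\t0\t1"), path)
    expect_error(readGenotypes(path, "tsv"), "duplicate SNP")

    writeLines(c("sample_id\trsA", "s1\t0", "s1\t1"), path)
    expect_error(readGenotypes(path, "tsv"), "duplicate sample")

    writeLines(c("sample_id\trsA", "s1\t3"), path)
    expect_error(readGenotypes(path, "tsv"), "dosage")

    dir <- withr::local_tempdir()
    meta <- data.frame(snp_id = "rsA", risk_allele = "A",
                       other_allele = "G")
    writeLines("1\trsA\t0\t0", file.path(dir, "x.map"))
    writeLines("f1 s1 0 0 0 1 A X", file.path(dir, "x.ped"))
    expect_error(readGenotypes(file.path(dir, "x.ped"), "pedmap",
                               meta = meta,
                               mapPath = file.path(dir, "x.map")),
                 "allele")
    writeLines("f1 s1 0 0 0 1 A", file.path(dir, "x.ped"))
    expect_error(readGenotypes(file.path(dir, "x.ped"), "pedmap",
                               meta = meta,
                               mapPath = file.path(dir, "x.map")),
                 "fields")
})

test_that("GrsCohort validity enforces the phenotype and allele rules", {
    d <- matrix(0, 1, 1, dimnames = list("rs1", "s1"))
    expect_error(GrsCohort(d, data.frame(risk_allele = "A",
                                         other_allele = "A"),
                           data.frame(status = "case")),
                 "differ")
    expect_error(GrsCohort(d, data.frame(risk_allele = "A",
                                         other_allele = "G"),
                           data.frame(status = "control",
                                      onset_class = "T1Ps")),
                 "onset_class")
    expect_error(GrsCohort(matrix(5, 1, 1,
                                  dimnames = list("rs1", "s1")),
                           data.frame(risk_allele = "A",
                                      other_allele = "G"),
                           data.frame(status = "case")),
                 "dosage")
})
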