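test_that("all data types round-trip through their file dialects", {
  d <- makeToyFixture(n = 8, nSnps = 6, nGenes = 4, seed = 5,
                      withCovariate = TRUE)
  dir <- withr::local_tempdir()

  writeDosageMatrix(d$dosages, file.path(dir, "g.tsv"))
  g2 <- readDosageMatrix(file.path(dir, "g.tsv"), mafMin = 0)
  expect_equal(g2@.Data, d$dosages@.Data)

  writeExpressionMatrix(d$expression, file.path(dir, "e.tsv"))
  e2 <- readExpressionMatrix(file.path(dir, "e.tsv"))
  expect_equal(e2@.Data, d$expression@.Data)

  writePhenotype(d$phenotype, file.path(dir, "p.tsv"))
  p2 <- readPhenotype(file.path(dir, "p.tsv"))
  expect_equal(phenotype(p2), phenotype(d$phenotype))
  expect_equal(covariates(p2), covariates(d$phenotype))

  writeEqtlMap(d$eqtlMap, file.path(dir, "q.tsv"))
  q2 <- readEqtlMap(file.path(dir, "q.tsv"))
  ord <- function(r) r[order(r$snp_id, r$gene_id), ]
  expect_equal(ord(eqtlRecords(q2)), ord(eqtlRecords(d$eqtlMap)),
               ignore_attr = TRUE)
})

test_that("loading restricts all sample-indexed objects to the shared samples", {
  dir <- withr::local_tempdir()
  # phenotype has 5 samples, genotype only 4 of them
  writeLines(c("snp_id\ta\tb\tc\td", "rs1\t0\t1\t2\t1", "rs2\t2\t1\t0\t1"),
             file.path(dir, "g.tsv"))
  writeLines(c("gene_id\te\td\tc\tb\ta", "g1\t1\t2\t3\t4\t5",
               "g2\t0.5\t1\t1.5\t2\t2.5"), file.path(dir, "e.tsv"))
  writeLines(c("sample_id\tphenotype", "e\t9", "d\t4", "c\t3", "b\t2", "a\t1"),
             file.path(dir, "p.tsv"))
  writeLines(c("snp_id\tgene_id\tpvalue", "rs1\tg1\t1e-6"),
             file.path(dir, "q.tsv"))
  suppressMessages({
    d <- loadTriangleData(file.path(dir, "g.tsv"), file.path(dir, "e.tsv"),
                          file.path(dir, "p.tsv"), file.path(dir, "q.tsv"),
                          mafMin = 0)
  })
  # phenotype file order is canonical; 'e' is dropped (absent from genotype)
  expect_identical(sampleIds(d$phenotype), c("d", "c", "b", "a"))
  expect_identical(rownames(d$dosages), sampleIds(d$phenotype))
  expect_identical(rownames(d$expression), sampleIds(d$phenotype))
  expect_equal(unname(phenotype(d$phenotype)), c(4, 3, 2, 1))
  expect_equal(unname(d$expression@.Data[, "g1"]), c(2, 3, 4, 5))
})

test_that("empty sample intersection and malformed cells are fatal with context", {
  dir <- withr::local_tempdir()
  writeLines(c("snp_id\ta\tb", "rs1\t0\t1"), file.path(dir, "g.tsv"))
  writeLines(c("gene_id\ta\tb", "g1\t1\t2"), file.path(dir, "e.tsv"))
  writeLines(c("sample_id\tphenotype", "x\t1", "y\t2"), file.path(dir, "p.tsv"))
  writeLines(c("snp_id\tgene_id\tpvalue", "rs1\tg1\t0.5"), file.path(dir, "q.tsv"))
  expect_error(
    suppressMessages(loadTriangleData(file.path(dir, "g.tsv"),
                                      file.path(dir, "e.tsv"),
                                      file.path(dir, "p.tsv"),
                                      file.path(dir, "q.tsv"), mafMin = 0)),
    "no shared samples")

  writeLines(c("snp_id\ta\tb", "rs1\t0\toops"), file.path(dir, "bad.tsv"))
  expect_error(readDosageMatrix(file.path(dir, "bad.tsv")), "row 1, column 3")
})

test_that("missing dosages are mean-imputed per SNP", {
  dir <- withr::local_tempdir()
  # hand computation: non-missing dosages 0 and 2, mean 1
  writeLines(c("snp_id\ts1\ts2\ts3", "rs1\t0\t2\tNA", "rs2\t0\t1\t2"),
             file.path(dir, "g.tsv"))
  g <- readDosageMatrix(file.path(dir, "g.tsv"), impute = "mean", mafMin = 0)
  expect_equal(g@.Data["s3", "rs1"], 1)
  gd <- readDosageMatrix(file.path(dir, "g.tsv"), impute = "drop", mafMin = 0)
  expect_identical(rownames(gd), c("s1", "s2"))
})

test_that("MAF floor and monomorphic SNPs are applied at genotype load", {
  dir <- withr::local_tempdir()
  tab <- c("snp_id\ts1\ts2\ts3\ts4\ts5\ts6\ts7\ts8\ts9\ts10",
           paste0("mono\t", paste(rep(2, 10), collapse = "\t")),
           paste0("rare\t1\t", paste(rep(0, 9), collapse = "\t")),
           paste0("ok\t", paste(rep(c(0, 1), 5), collapse = "\t")))
  writeLines(tab, file.path(dir, "g.tsv"))
  g <- readDosageMatrix(file.path(dir, "g.tsv"), mafMin = 0.06)
  expect_identical(colnames(g), "ok")
})

test_that("VCF genotypes load as ALT-allele dosages with missing-call imputation", {
  dir <- withr::local_tempdir()
  vcf <- c("##fileformat=VCFv4.2",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "S1", "S2", "S3", "S4", sep = "\t"),
           paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
                 "0/0", "0/1", "1/1", "0/0", sep = "\t"),
           paste("1", "200", "rs2", "A", "G", ".", "PASS", ".", "GT",
                 "0|1", "1|1", "./.", "0/0", sep = "\t"))
  writeLines(vcf, file.path(dir, "toy.vcf"))
  g <- readDosageMatrix(file.path(dir, "toy.vcf"), mafMin = 0)
  expect_identical(rownames(g), c("S1", "S2", "S3", "S4"))
  expect_equal(unname(g@.Data[, "rs1"]), c(0, 1, 2, 0))
  # ./. imputed to the mean of (1, 2, 0) = 1
  expect_equal(unname(g@.Data[, "rs2"]), c(1, 2, 1, 0))
})

test_that("FdrTable writing handles empty and non-empty tables at full precision", {
  dir <- withr::local_tempdir()
  empty <- efdrQvalues(numeric(0), c(0.5))
  pth <- file.path(dir, "empty.tsv")
  writeFdrTable(empty, pth)
  lines <- readLines(pth)
  expect_identical(lines[length(lines)],
                   "snp_id\tgenes\tp_obs\tnaive_q\tefdr\tq_efdr")
  expect_equal(nrow(fdrTable(readFdrTable(pth))), 0)

  obs <- c(rs1 = 0.01, rs2 = 0.2, rs3 = 0.6, rs4 = 0.9)
  sim <- c(0.05, 0.3, 0.55, 0.7, 0.95)
  ft <- efdrQvalues(obs, sim)
  writeFdrTable(ft, file.path(dir, "t.tsv"))
  back <- readFdrTable(file.path(dir, "t.tsv"))
  expect_equal(fdrTable(back), fdrTable(ft), tolerance = 1e-15)
  expect_equal(back@pi0, ft@pi0, tolerance = 1e-15)
  expect_equal(fdrTable(back)$efdr, c(0, 1/3, 2/3, 2/3), tolerance = 1e-15)
})

test_that("class validity rejects inconsistent objects", {
  m <- matrix(c(0, 1, 3), 3, 1, dimnames = list(letters[1:3], "rs1"))
  expect_error(DosageMatrix(m), "\\[0, 2\\]")
  expect_error(ExpressionMatrix(matrix(Inf, 1, 1,
                                       dimnames = list("a", "g"))), "finite")
  expect_error(EqtlMap(data.frame(snp_id = c("a", "a"), gene_id = c("g", "g"),
                                  pvalue = c(0.1, 0.2))), "duplicated")
  expect_error(PhenotypeVector(c(a = 1, b = 2),
                               matrix(0, 3, 1, dimnames = list(NULL, "c1"))),
               "covariate rows")
})
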