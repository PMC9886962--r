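test_that("VCF round trip is the identity on dosages, positions and ids", {
  ds <- small_sim(seed = 10, n_pops = 2, n_per_pop = 3, n_loci = 10,
                  missing_rate = 0.15)
  G <- ds$genotypes
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(G, path)
  G2 <- read_vcf(path)
  expect_equal(unname(G2$dosages), unname(G$dosages))
  expect_equal(G2$loci$pos, G$loci$pos)
  expect_equal(G2$loci$chrom, G$loci$chrom)
  expect_equal(G2$individuals$id, G$individuals$id)
})

test_that("GT coding handles het, phased and missing calls; bad GT errors", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    paste(c("chr1", "100", ".", "A", "G", ".", "PASS", ".", "GT",
            "0/1", "1|0", "./."), collapse = "\t"),
    paste(c("chr1", "200", ".", "C", "T", ".", "PASS", ".", "GT",
            "1/1", "0|0", "0/1"), collapse = "\t")
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  G <- read_vcf(path)
  expect_equal(unname(G$dosages[, 1]), c(1, 1, NA))
  expect_equal(unname(G$dosages[, 2]), c(2, 0, 1))
})

test_that("multi-allelic records error in strict mode and drop otherwise", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1"), collapse = "\t"),
    paste(c("chr1", "100", ".", "A", "G,T", ".", "PASS", ".", "GT", "0/1"),
          collapse = "\t"),
    paste(c("chr1", "200", ".", "C", "T", ".", "PASS", ".", "GT", "1/1"),
          collapse = "\t")
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  expect_error(read_vcf(path), "multi-allelic")
  expect_warning(G <- read_vcf(path, multiallelic = "drop"), "dropped")
  expect_equal(n_loci(G), 1)
})

test_that("dosage TSV round trips and rejects out-of-domain values", {
  ds <- small_sim(seed = 12, n_pops = 2, n_per_pop = 4, n_loci = 8,
                  missing_rate = 0.1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dosage_tsv(ds$genotypes, path)
  G2 <- read_dosage_tsv(path)
  expect_equal(unname(G2$dosages), unname(ds$genotypes$dosages))
  expect_equal(G2$individuals$population, ds$genotypes$individuals$population)

  bad <- readLines(path)
  bad[2] <- sub("\t2", "\t3", bad[2])
  if (!grepl("\t3", bad[2])) bad[2] <- sub("\t1", "\t3", bad[2])
  writeLines(bad, path)
  expect_error(read_dosage_tsv(path), "dosage")
})

test_that("env table drops incomplete sites with a warning", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("site\tzone\tpH\tK",
               "s1\tz1\t7.1\t300",
               "s2\tz1\t\t250",
               "s3\tz2\t7.9\t410"), path)
  expect_warning(E <- read_env_table(path), "s2")
  expect_equal(E$site, c("s1", "s3"))
  expect_equal(env_predictors <- setdiff(names(E), "site"), c("pH", "K"))
  expect_equal(attr(E, "metadata")$zone, c("z1", "z2"))
})

test_that("BED half-open intervals convert to 1-based inclusive", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t99\t200\tg1", path)
  ann <- read_annotation(path)
  expect_equal(ann$start, 100)
  expect_equal(ann$end, 200)
  expect_equal(ann$gene_id, "g1")
})

test_that("GFF3 gene features are read with ids and descriptions", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t500\t.\t+\t.\tID=MS.gene001;description=Cytochrome P450",
    "chr1\tsrc\texon\t100\t200\t.\t+\t.\tID=MS.gene001.e1",
    "chr2\tsrc\tgene\t900\t1200\t.\t-\t.\tID=MS.gene002;description=WD40 repeat"
  ), path)
  ann <- read_annotation(path)
  expect_equal(nrow(ann), 2)
  expect_equal(ann$gene_id, c("MS.gene001", "MS.gene002"))
  expect_match(ann$annotation[1], "Cytochrome P450")
  expect_equal(ann$start, c(100, 900))
})

test_that("phenotype table validates ids and numeric traits", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tdmy\tht", "g1\t12.5\t40", "g2\t9.1\t35"), path)
  ph <- read_phenotypes(path)
  expect_equal(ph$dmy, c(12.5, 9.1))
  writeLines(c("id\tdmy", "g1\t12.5", "g1\t9.1"), path)
  expect_error(read_phenotypes(path), "duplicated")
})

test_that("genotype_matrix validates its invariants", {
  expect_error(tiny_genotypes(matrix(c(0, 3), 1, 2)), "dosages")
  d <- matrix(0, 2, 2)
  expect_error(
    genotype_matrix(d, data.frame(chrom = "c", pos = 1:2, ref = "A", alt = "G"),
                    data.frame(id = c("a", "a"), population = "p", site = "s")),
    "unique")
})
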