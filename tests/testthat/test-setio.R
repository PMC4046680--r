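# I/O: genotype matrices, VCF, phenotypes, gene windows, GMT pathways.

write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

test_that("matrix-tsv genotypes parse and round-trip exactly", {
  path <- write_tsv_fixture(c("sample_id\trs1\trs2", "s1\t0\t2", "s2\t1\t1"))
  G <- read_genotypes(path, "matrix-tsv")
  expect_equal(G$values, matrix(c(0L, 1L, 2L, 1L), 2, 2), ignore_attr = TRUE)
  expect_equal(G$snp_ids, c("rs1", "rs2"))
  expect_equal(G$sample_ids, c("s1", "s2"))
  out <- tempfile(fileext = ".tsv")
  write_genotypes(G, out)
  G2 <- read_genotypes(out, "matrix-tsv")
  expect_identical(G2$values, G$values)
  # larger random round trip
  Gb <- genotype_matrix(rand_genotypes(13, 7, 5))
  write_genotypes(Gb, out)
  expect_identical(read_genotypes(out, "matrix-tsv")$values, Gb$values)
})

test_that("malformed genotype files raise errors naming the location", {
  path <- write_tsv_fixture(c("sample_id\trs1\trs2", "s1\t0\t2", "s2\t1"))
  expect_error(read_genotypes(path, "matrix-tsv"), "line 3")
  path2 <- write_tsv_fixture(c("sample_id\trs1", "s1\t3"))
  expect_error(read_genotypes(path2, "matrix-tsv", missing_policy = "fail"),
               "3")
})

test_that("missing genotype policies behave as documented", {
  lines <- c("sample_id\trs1\trs2", "s1\t0\t.", "s2\t1\t2", "s3\t1\t2")
  expect_error(read_genotypes(write_tsv_fixture(lines), missing_policy = "fail"),
               "missing|validation")
  expect_warning(
    Gd <- read_genotypes(write_tsv_fixture(lines), missing_policy = "drop-snp"),
    "dropping")
  expect_equal(Gd$snp_ids, "rs1")
  expect_warning(
    Gi <- read_genotypes(write_tsv_fixture(lines),
                         missing_policy = "mode-impute"),
    "imputed")
  expect_equal(Gi$values[1, 2], 2L)  # mode of observed values
})

test_that("VCF genotypes are read through the GT field with multi-allelic records skipped", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsA\tsB",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t1/0\t1/1",
    "1\t300\trs3\tG\tA,C\t.\tPASS\t.\tGT\t0/0\t0/1",
    "1\t400\trs4\tT\tC\t.\tPASS\t.\tGT\t1|1\t0|0")
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  expect_warning(G <- read_genotypes(path, "vcf"), "multi-allelic")
  expect_equal(G$snp_ids, c("rs1", "rs2", "rs4"))
  expect_equal(G$values[, "rs1"], c(sA = 0L, sB = 1L))
  expect_equal(G$values[, "rs2"], c(sA = 1L, sB = 2L))
  expect_equal(G$values[, "rs4"], c(sA = 2L, sB = 0L))
  expect_equal(G$snp_positions$pos, c(100L, 200L, 400L))
})

test_that("phenotypes validate and read from TSV", {
  path <- write_tsv_fixture(c("sample_id\tstatus", "s1\t1", "s2\t0"))
  y <- read_phenotype(path)
  expect_equal(unname(y), c(1L, 0L))
  expect_error(validate_phenotype(c(1, 1)), "control")
  expect_error(validate_phenotype(c(0, 2)), "0 or 1")
})

test_that("SNP-to-gene windows are inclusive at exactly +/- window_bp", {
  genes <- data.frame(gene_id = "g1", chrom = "1", start = 10000L,
                      end = 20000L, stringsAsFactors = FALSE)
  pos <- data.frame(chrom = "1",
                    pos = c(10000L - 5000L, 10000L - 5001L, 20000L + 5000L,
                            20000L + 5001L, 15000L))
  sets <- map_snps_to_genes(pos, genes, window_bp = 5000L)
  expect_equal(sets$g1$snp_indices, c(1L, 3L, 5L))
  # a SNP inside two overlapping genes belongs to both sets
  genes2 <- rbind(genes, data.frame(gene_id = "g2", chrom = "1",
                                    start = 14000L, end = 16000L))
  sets2 <- map_snps_to_genes(pos, genes2, window_bp = 0L)
  expect_true(5L %in% sets2$g1$snp_indices)
  expect_true(5L %in% sets2$g2$snp_indices)
  # nothing maps: empty list with a warning
  far <- data.frame(chrom = "2", pos = 1L)
  expect_warning(none <- map_snps_to_genes(far, genes), "no SNP")
  expect_length(none, 0)
})

test_that("gene sets grow monotonically with the window", {
  set.seed(8)
  genes <- data.frame(gene_id = paste0("g", 1:4), chrom = "1",
                      start = c(1000L, 40000L, 90000L, 150000L),
                      end = c(5000L, 60000L, 95000L, 160000L))
  pos <- data.frame(chrom = "1", pos = sort(sample.int(200000L, 60)))
  prev <- map_snps_to_genes(pos, genes, window_bp = 0L)
  for (w in c(2000L, 5000L, 20000L)) {
    cur <- map_snps_to_genes(pos, genes, window_bp = w)
    for (g in names(prev)) {
      expect_true(all(prev[[g]]$snp_indices %in% cur[[g]]$snp_indices))
    }
    prev <- cur
  }
})

test_that("BED-like gene intervals convert to 1-based inclusive coordinates", {
  path <- write_tsv_fixture(c("1\t999\t2000\tgeneA", "2\t0\t100\tgeneB"))
  genes <- read_gene_intervals(path)
  expect_equal(genes$start, c(1000L, 1L))
  expect_equal(genes$end, c(2000L, 100L))
  genes1 <- read_gene_intervals(path, zero_based = FALSE)
  expect_equal(genes1$start, c(999L, 0L))
})

test_that("GMT pathways parse, filter on size, and preserve order", {
  big <- paste(c("huge", "na", paste0("G", 1:251)), collapse = "\t")
  exact <- paste(c("edge", "na", paste0("H", 1:250)), collapse = "\t")
  lines <- c("pwB\tdesc\tTP53\tNOD2", big, exact, "pwA\tdesc\tIL18")
  path <- write_tsv_fixture(lines)
  pws <- read_gmt_pathways(path)
  expect_equal(names(pws), c("pwB", "edge", "pwA"))  # >250 genes removed
  expect_equal(pws$pwB, c("TP53", "NOD2"))
  expect_length(pws$edge, 250)
  expect_error(read_gmt_pathways(write_tsv_fixture("lonely")), "line 1")
  empty <- tempfile()
  writeLines(character(0), empty)
  expect_error(read_gmt_pathways(empty), "empty")
})

test_that("pathway SNP sets are deduplicated unions of gene sets", {
  gsets <- list(geneA = snp_set("geneA", c(1, 2)),
                geneB = snp_set("geneB", c(2, 3)),
                geneC = snp_set("geneC", 7))
  pws <- list(p1 = c("geneA", "geneB"), p2 = c("geneC"),
              p3 = c("missing_gene"))
  expect_warning(out <- pathway_snpsets(pws, gsets), "dropped")
  expect_equal(out$p1$snp_indices, c(1L, 2L, 3L))
  expect_equal(out$p2$snp_indices, 7L)
  expect_null(out$p3)
  # size bound: union never exceeds the sum of member sizes
  expect_lte(length(out$p1$snp_indices),
             length(gsets$geneA$snp_indices) + length(gsets$geneB$snp_indices))
})

test_that("snp_set and genotype_matrix enforce their invariants", {
  expect_error(snp_set("s", integer(0)), "empty")
  expect_error(snp_set("s", c(1, 1)), "duplicate")
  expect_error(snp_set("s", 5, d = 4), "range")
  expect_error(genotype_matrix(matrix(c(0, 3), 1, 2)), "0, 1 or 2")
  expect_error(genotype_matrix(matrix(0:1, 2, 1),
                               sample_ids = c("a", "a")), "unique")
})
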