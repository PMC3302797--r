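write_toy_tables <- function(dir, cells, snp_meta, acc_meta) {
  gpath <- file.path(dir, "geno.tsv")
  spath <- file.path(dir, "snps.tsv")
  apath <- file.path(dir, "accs.tsv")
  writeLines(cells, gpath)
  writeLines(snp_meta, spath)
  writeLines(acc_meta, apath)
  list(g = gpath, s = spath, a = apath)
}

std_snp_meta <- c(
  "snp_id\tchromosome\tposition_bp\tsource_panel",
  "s1\t1\t500\tkoshihikari",
  "s2\t1\t100\tkoshihikari",
  "s3\t2\t200\teiko",
  "s4\t1\t300\trikuu132"
)
std_acc_meta <- c(
  "accession_id\tgroup\twater_regime\tregistration_year\tregion",
  "a1\tgroup1\tirrigated\t\t",
  "a2\tgroup2\tirrigated\t1950\t",
  "a3\tgroup3\tirrigated\t1980\t"
)

test_that("genotype table loads sorted by map position with het coerced to missing", {
  d <- withr::local_tempdir()
  p <- write_toy_tables(d, c(
    "accession_id\ts1\ts2\ts3\ts4",
    "a1\tG\tT\tC\tA",
    "a2\tG\tT\tC\tG",
    "a3\tA\tH\tN\tG"
  ), std_snp_meta, std_acc_meta)
  x <- read_genotype_table(p$g, p$s, p$a)

  expect_identical(dim(x$calls), c(3L, 4L))
  # sorted (chromosome, position): s2 (1:100), s4 (1:300), s1 (1:500), s3 (2:200)
  expect_identical(x$snps$snp_id, c("s2", "s4", "s1", "s3"))
  expect_identical(colnames(x$calls), x$snps$snp_id)
  expect_identical(x$n_het_coerced, 1L)
  expect_true(is.na(x$calls["a3", "s2"]))  # the H cell
  expect_true(is.na(x$calls["a3", "s3"]))  # the N cell
  # first-seen symbol becomes allele A
  expect_identical(unname(x$calls[, "s1"]), c("A", "A", "B"))
})

test_that("loader rejects non-biallelic columns, unknown ids, tied positions", {
  d <- withr::local_tempdir()
  p <- write_toy_tables(d, c(
    "accession_id\ts1\ts2\ts3\ts4",
    "a1\tG\tT\tC\tA",
    "a2\tC\tT\tC\tG",
    "a3\tA\tT\tC\tG"
  ), std_snp_meta, std_acc_meta)
  expect_error(read_genotype_table(p$g, p$s, p$a), "non-biallelic.*s1")

  p2 <- write_toy_tables(d, c(
    "accession_id\ts1\ts2\ts3\ts4",
    "a1\tG\tT\tC\tA",
    "a9\tG\tT\tC\tG"
  ), std_snp_meta, std_acc_meta)
  expect_error(read_genotype_table(p2$g, p2$s, p2$a), "a9")

  tied <- std_snp_meta
  tied[3] <- "s2\t1\t500\tkoshihikari"  # same chr+pos as s1
  p3 <- write_toy_tables(d, c(
    "accession_id\ts1\ts2\ts3\ts4",
    "a1\tG\tT\tC\tA",
    "a2\tA\tC\tG\tG"
  ), tied, std_acc_meta)
  expect_error(read_genotype_table(p3$g, p3$s, p3$a), "tied SNP positions")
})

test_that("write/read round trip reproduces calls, order and metadata", {
  sim <- small_sim(7)
  d <- withr::local_tempdir()
  paths <- write_genotype_table(sim$panel, d)
  back <- read_genotype_table(paths["genotypes"], paths["snps"],
                              paths["accessions"])
  expect_identical(back$calls, sim$panel$calls)
  expect_identical(back$snps, sim$panel$snps)
  expect_identical(back$accessions, sim$panel$accessions)
  # after loading no call is heterozygous and every column is biallelic
  expect_true(all(back$calls %in% c("A", "B") | is.na(back$calls)))
})

write_toy_vcf <- function(path, body) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta1\ta2\ta3",
    body
  ), path)
  path
}

test_that("VCF import maps homozygous GT, drops hets and multi-allelic records", {
  d <- withr::local_tempdir()
  vcf <- write_toy_vcf(file.path(d, "x.vcf"), c(
    "1\t100\tv1\tG\tA\t.\tPASS\t.\tGT\t0/0\t1/1\t0/1",
    "1\t200\tv2\tT\tC\t.\tPASS\t.\tGT\t1|1\t0|0\t./.",
    "2\t300\tv3\tA\tC,G\t.\tPASS\t.\tGT\t0/0\t1/1\t2/2"
  ))
  apath <- file.path(d, "accs.tsv")
  writeLines(std_acc_meta, apath)
  expect_message(x <- read_vcf(vcf, apath), "1 multi-allelic")
  expect_identical(ncol(x$calls), 2L)  # triallelic v3 skipped
  expect_identical(unname(x$calls[c("a1", "a2", "a3"), "v1"]),
                   c("A", "B", NA))  # 0/1 is missing
  expect_true(is.na(x$calls["a3", "v2"]))  # ./. is missing
  expect_identical(x$n_het_coerced, 1L)
})

test_that("VCF import fails on empty bodies and disjoint sample sets", {
  d <- withr::local_tempdir()
  apath <- file.path(d, "accs.tsv")
  writeLines(std_acc_meta, apath)

  empty <- write_toy_vcf(file.path(d, "e.vcf"), character(0))
  expect_error(suppressWarnings(read_vcf(empty, apath)))

  other_meta <- c("accession_id\tgroup\twater_regime\tregistration_year\tregion",
                  "zz\tgroup1\tirrigated\t\t")
  apath2 <- file.path(d, "accs2.tsv")
  writeLines(other_meta, apath2)
  vcf <- write_toy_vcf(file.path(d, "x.vcf"),
                       "1\t100\tv1\tG\tA\t.\tPASS\t.\tGT\t0/0\t1/1\t0/0")
  expect_error(read_vcf(vcf, apath2), "no VCF samples")
})

test_that("BED export converts 1-based inclusive to 0-based half-open", {
  d <- withr::local_tempdir()
  path <- file.path(d, "iv.bed")
  write_bed(data.frame(chromosome = 1L, start_bp = 100L, end_bp = 200L,
                       label = "iv1"), path)
  expect_identical(readLines(path), "chr1\t99\t200\tiv1")

  write_bed(data.frame(chromosome = integer(), start_bp = integer(),
                       end_bp = integer()), path)
  expect_identical(length(readLines(path)), 0L)

  # a region like the longest reduced-diversity spans seen in practice
  write_bed(data.frame(chromosome = 11L, start_bp = 11600000L,
                       end_bp = 14558000L), path)
  f <- strsplit(readLines(path), "\t")[[1]]
  expect_identical(f[1], "chr11")
  expect_identical(as.integer(f[3]) - as.integer(f[2]), 2958001L)

  ann_path <- file.path(d, "ann.bed")
  writeLines("chr1\t99\t200\tqtl_a\tqtl", ann_path)
  ann <- read_annotations(ann_path)
  expect_identical(ann$start_bp, 100L)  # back to 1-based inclusive
  expect_identical(ann$end_bp, 200L)
})

test_that("Q-matrix and pedigree readers validate their invariants", {
  d <- withr::local_tempdir()
  qpath <- file.path(d, "q.tsv")
  writeLines(c("accession_id\tw\te\tc\tn",
               "a1\t0.7\t0.1\t0.1\t0.1",
               "a2\t0.5\t0.5\t0\t0"), qpath)
  q <- read_qmatrix(qpath)
  expect_equal(rowSums(q), c(a1 = 1, a2 = 1))

  writeLines(c("accession_id\tw\te\tc\tn",
               "a1\t0.7\t0.1\t0.1\t0.2"), qpath)
  expect_error(read_qmatrix(qpath), "sum to 1")

  ppath <- file.path(d, "ped.tsv")
  writeLines(c("child\tparent1\tparent2\trecurrent_parent",
               "c1\tf1\tf2\t",
               "c2\tc1\tf1\tf3"), ppath)
  expect_error(read_pedigree(ppath), "recurrent_parent must name")
})
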