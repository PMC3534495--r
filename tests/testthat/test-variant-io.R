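# VCF and gsMapper parsing, GFF3/GVF writing, interval conversion.

test_that("VCF SNVs and anchor-base indels convert to GFF3 conventions", {
  v <- read_vcf_variants(vcf_lines(
    "chr1\t100\t.\tA\tG\t.\t.\t.",
    "chr1\t100\t.\tAT\tA\t.\t.\t.",
    "chr1\t100\t.\tA\tAGG\t.\t.\t."))
  expect_identical(v$vtype, c("SNV", "deletion", "insertion"))
  expect_identical(v$start, c(100L, 101L, 100L))
  expect_identical(v$end, c(100L, 101L, 100L))
  expect_identical(v$ref_allele, c("A", "T", "-"))
  expect_identical(v$alt_allele, c("G", "-", "GG"))
})

test_that("multi-base anchor indels span the full deleted run", {
  v <- read_vcf_variants(vcf_lines("c1\t50\t.\tGACT\tG\t.\t.\t."))
  expect_identical(v$vtype, "deletion")
  expect_identical(c(v$start, v$end), c(51L, 53L))
  expect_identical(v$ref_allele, "ACT")
})

test_that("multi-allelic records yield one suffixed feature per ALT", {
  v <- read_vcf_variants(vcf_lines("c1\t10\trs7\tA\tG,C\t.\t.\t."))
  expect_identical(v$id, c("rs7_1", "rs7_2"))
  expect_identical(v$alt_allele, c("G", "C"))
})

test_that("non-ACGTN or complex alleles are skipped and counted", {
  expect_warning(
    v <- read_vcf_variants(vcf_lines(
      "c1\t10\t.\tA\tG\t.\t.\t.",
      "c1\t20\t.\tA\t<DEL>\t.\t.\t.",
      "c1\t30\t.\tAT\tGC\t.\t.\t.")),
    "skipped 2")
  expect_identical(nrow(v), 1L)
  expect_identical(attr(v, "n_skipped"), 2L)
})

test_that("structural VCF problems are errors naming the line", {
  expect_error(read_vcf_variants(vcf_lines("c1\t10\t.\tA")), "line 3")
  expect_error(read_vcf_variants(vcf_lines("c1\t1x0\t.\tA\tG\t.\t.\t.")),
               "non-integer POS")
})

test_that("gsMapper rows parse SNVs, insertions and deletions", {
  v <- read_gsmapper_variants(gsmapper_lines(
    ">contig00123 45 45 A G 30 95%",
    ">contig00123 60 60 - G 22 80%",
    ">contig00123 70 72 ACT - 18 77%"))
  expect_identical(v$vtype, c("SNV", "insertion", "deletion"))
  expect_identical(v$start, c(45L, 60L, 70L))
  expect_identical(v$end, c(45L, 60L, 72L))
  expect_identical(v$ref_allele, c("A", "-", "ACT"))
  expect_identical(v$alt_allele, c("G", "G", "-"))
  expect_identical(v$depth, c(30L, 22L, 18L))
  expect_identical(v$var_freq, c(95, 80, 77))
})

test_that("gsMapper dialect tolerates missing or extra trailing columns", {
  v <- read_gsmapper_variants(gsmapper_lines(
    ">c1 5 5 A T",
    ">c1 9 9 G C 12 88% extra stuff here"))
  expect_identical(nrow(v), 2L)
  expect_true(is.na(v$depth[1]))
  expect_identical(v$depth[2], 12L)
})

test_that("gsMapper structural problems are errors; empty input is empty", {
  expect_error(read_gsmapper_variants(">c1 xx 45 A G"), "non-numeric")
  expect_error(read_gsmapper_variants(">c1 45 45 A"), ">= 5 columns")
  v <- read_gsmapper_variants(gsmapper_lines())
  expect_identical(nrow(v), 0L)
})

test_that("GFF3 output carries GVF allele attributes and counts records", {
  v <- read_vcf_variants(vcf_lines(
    "c1\t100\t.\tA\tG\t.\t.\t.",
    "c1\t200\t.\tCT\tC\t.\t.\t.",
    "c1\t300\t.\tG\tGAAT\t.\t.\t."))
  path <- withr::local_tempfile(fileext = ".gff3")
  expect_identical(write_variant_gff3(v, path), 3L)
  lines <- readLines(path)
  expect_identical(lines[1], "##gff-version 3")
  rec <- strsplit(lines[2], "\t")[[1]]
  expect_identical(rec[c(4, 5)], c("100", "100"))
  expect_match(rec[9], "Reference_seq=A;Variant_seq=G")
})

test_that("invalid features are rejected by id at write time", {
  v <- tibble::tibble(seqid = "c1", source = "x", vtype = "SNV",
                      start = 5L, end = 6L, ref_allele = "A",
                      alt_allele = "G", id = "badsnv")
  expect_error(write_variant_gff3(v, withr::local_tempfile()), "badsnv")
})

test_that("VCF -> features -> GFF3 -> features is the identity", {
  v <- read_vcf_variants(vcf_lines(
    "c1\t100\t.\tA\tG\t.\t.\t.",
    "c1\t150\t.\tAT\tA\t.\t.\t.",
    "c1\t200\t.\tA\tAGG\t.\t.\t.",
    "c2\t10\t.\tGACT\tG\t.\t.\t."))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_variant_gff3(v, path)
  back <- read_variant_gff3(path)
  cols <- c("seqid", "vtype", "start", "end", "ref_allele", "alt_allele")
  expect_equal(as.data.frame(back[, cols]), as.data.frame(v[, cols]),
               ignore_attr = TRUE)
  expect_identical(back$id, v$id)
})

test_that("GFF3 and interval coordinates interconvert losslessly", {
  v <- tibble::tibble(
    seqid = "c1", source = "t",
    vtype = c("SNV", "deletion", "insertion"),
    start = c(10L, 20L, 100L), end = c(10L, 24L, 100L),
    ref_allele = c("A", "CCCCC", "-"), alt_allele = c("G", "-", "TT"),
    id = c("a", "b", "c"))
  iv <- gff3_to_interval(v)
  expect_identical(iv$start, c(9L, 19L, 100L))
  expect_identical(iv$end, c(10L, 24L, 100L))
  expect_identical(iv$end - iv$start, c(1L, 5L, 0L))
  back <- interval_to_gff3(iv)
  expect_identical(back$start, v$start)
  expect_identical(back$end, v$end)

  g <- interval_to_gff3(tibble::tibble(start = 0L, end = 5L))
  expect_identical(c(g$start, g$end), c(1L, 5L))
  expect_error(interval_to_gff3(tibble::tibble(start = -1L, end = 5L)),
               "negative")
})

test_that("parsers accept path, connection and text identically", {
  lines <- vcf_lines("c1\t100\t.\tA\tG\t.\t.\t.",
                     "c1\t150\t.\tC\tT\t.\t.\t.")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(lines, path)
  con <- file(path, open = "rt")
  withr::defer(try(close(con), silent = TRUE))
  v_text <- read_vcf_variants(lines)
  v_path <- read_vcf_variants(path)
  v_con <- read_vcf_variants(con)
  expect_identical(as.data.frame(v_text), as.data.frame(v_path))
  expect_identical(as.data.frame(v_text), as.data.frame(v_con))
})
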