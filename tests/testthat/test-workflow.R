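# Fixture generation with verified truth, the end-to-end workflow, and
# declarative table filtering.

test_that("fixtures are byte-identical under the same seed", {
  a <- generate_fixture(seed = 42, n_contigs = 2, contig_length = 1200,
                        n_variants = 10)
  b <- generate_fixture(seed = 42, n_contigs = 2, contig_length = 1200,
                        n_variants = 10)
  expect_identical(a$fasta, b$fasta)
  expect_identical(a$vcf, b$vcf)
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
  c <- generate_fixture(seed = 43, n_contigs = 2, contig_length = 1200,
                        n_variants = 10)
  expect_false(identical(a$fasta, c$fasta))
})

test_that("the planted-CAPS fraction is honoured exactly", {
  fx <- generate_fixture(seed = 9, n_contigs = 4, contig_length = 1800,
                         n_variants = 30, planted_caps_fraction = 0.4)
  expect_identical(nrow(fx$truth), 30L)
  expect_identical(sum(!is.na(fx$truth$enzyme)), 12L)
  expect_identical(sum(fx$truth$role == "neutral"), 18L)
  expect_true(all(fx$truth$expected[fx$truth$role == "neutral"] == ""))
})

test_that("detection reproduces the generator's digest-verified truth", {
  fx <- generate_fixture(seed = 13, n_contigs = 5, contig_length = 2200,
                         n_variants = 40, planted_caps_fraction = 0.5,
                         indel_fraction = 0.3)
  sc <- scan_variants(fx$ref, fx$variants)
  got <- dplyr::summarise(
    dplyr::group_by(tidy(sc), .data$variant_id),
    set = paste(paste0(.data$enzyme, ":", .data$status), collapse = ";"))
  cmp <- dplyr::left_join(fx$truth, got, by = c(id = "variant_id"))
  cmp$set[is.na(cmp$set)] <- ""
  expect_identical(cmp$set, cmp$expected)
})

test_that("VCF round trip preserves the planted variants", {
  fx <- generate_fixture(seed = 21, n_contigs = 2, contig_length = 1200,
                         n_variants = 10, indel_fraction = 0.5)
  v <- read_vcf_variants(fx$vcf)
  cols <- c("seqid", "vtype", "start", "end", "ref_allele", "alt_allele")
  expect_equal(as.data.frame(v[, cols]),
               as.data.frame(fx$variants[, cols]), ignore_attr = TRUE)
})

test_that("the full workflow writes all artifacts and is reproducible", {
  dir <- withr::local_tempdir()
  fx <- generate_fixture(seed = 42, n_contigs = 3, contig_length = 1800,
                         n_variants = 18, dir = file.path(dir, "fx"))
  out1 <- file.path(dir, "run1"); out2 <- file.path(dir, "run2")
  cfg <- workflow_config(reference = fx$paths$fasta,
                         variants = fx$paths$vcf, out_dir = out1)
  res <- run_caps_workflow(cfg)
  for (p in res$paths) {
    expect_true(file.exists(p))
    expect_gt(file.size(p), 0)
  }
  # provenance headers carry the seed
  expect_true(any(grepl("seed: 42", readLines(res$paths$candidates))))

  cfg2 <- workflow_config(reference = fx$paths$fasta,
                          variants = fx$paths$vcf, out_dir = out2)
  res2 <- run_caps_workflow(cfg2)
  expect_identical(readLines(res$paths$candidates),
                   readLines(res2$paths$candidates))
  expect_identical(readLines(res$paths$primers),
                   readLines(res2$paths$primers))

  # stage log lines reconcile with the tables
  log <- readLines(res$paths$log)
  expect_true(any(grepl(paste0("out=", nrow(res$variants), " features"),
                        log)))
  expect_true(any(grepl(paste0("candidates=", nrow(res$candidates)), log)))
  expect_true(any(grepl(paste0("pairs=", nrow(res$primers)),
                        log[grepl("stage design", log)])))
})

test_that("every designed pair targets a planted variant and flanks it", {
  dir <- withr::local_tempdir()
  fx <- generate_fixture(seed = 5, n_contigs = 3, contig_length = 1800,
                         n_variants = 18, dir = dir)
  res <- run_caps_workflow(workflow_config(
    reference = fx$paths$fasta, variants = fx$paths$vcf,
    out_dir = file.path(dir, "out")))
  expect_gt(nrow(res$primers), 0L)
  expect_true(all(res$primers$target_id %in% fx$variants$id))
  v <- fx$variants[match(res$primers$target_id, fx$variants$id), ]
  expect_true(all(res$primers$left_genomic_start +
                    res$primers$left_len - 1L < v$start))
  expect_true(all(res$primers$right_genomic_start -
                    res$primers$right_len + 1L > v$end))
  # and each is uniquely recovered by electronic PCR
  expect_true(all(glance(res$epcr)$specific))
})

test_that("a missing input path aborts before any output is written", {
  dir <- withr::local_tempdir()
  cfg <- workflow_config(reference = file.path(dir, "nope.fa"),
                         variants = file.path(dir, "nope.vcf"),
                         out_dir = file.path(dir, "out"))
  expect_error(run_caps_workflow(cfg), "nope.fa")
  expect_false(dir.exists(file.path(dir, "out")))
})

test_that("filter_table applies equality and range predicates in order", {
  tab <- tibble::tibble(enzyme = c("TaqI", "AluI", "TaqI"),
                        confounded = c(FALSE, FALSE, TRUE),
                        product_size = c(95L, 110L, 130L))
  expect_identical(filter_table(tab, enzyme = "TaqI")$product_size,
                   c(95L, 130L))
  expect_identical(nrow(filter_table(tab, confounded = FALSE)), 2L)
  expect_identical(filter_table(tab, product_size = c(90, 120))$enzyme,
                   c("TaqI", "AluI"))
  expect_identical(filter_table(tab), tab)
  expect_error(filter_table(tab, nope = 1), "valid columns")
})

test_that("HRM workflow designs only class I/II SNP assays", {
  dir <- withr::local_tempdir()
  fx <- generate_fixture(seed = 31, n_contigs = 3, contig_length = 1800,
                         n_variants = 18, dir = dir)
  res <- run_caps_workflow(workflow_config(
    reference = fx$paths$fasta, variants = fx$paths$vcf,
    out_dir = file.path(dir, "hrm"), marker_type = "HRM"))
  keep <- filter_hrm_targets(fx$variants)
  expect_true(all(res$primers$target_id %in% keep$id))
  expect_true(all(res$primers$product_size >= 60 &
                    res$primers$product_size <= 100))
})
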