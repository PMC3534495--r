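# Allele application, CAPS detection, SNP melting classes, HRM filtering.

snv <- function(pos, ref, alt, seqid = "c1", id = "v1") {
  tibble::tibble(seqid = seqid, source = "t", vtype = "SNV",
                 start = pos, end = pos, ref_allele = ref,
                 alt_allele = alt, id = id)
}

test_that("apply_variant edits SNVs, insertions and deletions in place", {
  expect_identical(apply_variant("GGGTCGAGGG", snv(5L, "C", "T")),
                   "GGGTTGAGGG")
  ins <- tibble::tibble(seqid = "c1", vtype = "insertion", start = 4L,
                        end = 4L, ref_allele = "-", alt_allele = "G",
                        id = "i1")
  expect_identical(apply_variant("GGTCAGG", ins), "GGTCGAGG")
  del <- tibble::tibble(seqid = "c1", vtype = "deletion", start = 5L,
                        end = 5L, ref_allele = "G", alt_allele = "-",
                        id = "d1")
  expect_identical(apply_variant("GGTCGAGG", del), "GGTCAGG")
})

test_that("apply_variant validates window containment and reference bases", {
  expect_error(apply_variant("ACGT", snv(9L, "A", "G")), "outside")
  expect_error(apply_variant("ACGT", snv(2L, "A", "G")),
               "reference mismatch")
})

test_that("a SNP destroying or creating a TaqI site is called with status", {
  p <- load_panel()
  lost <- detect_caps("GGGTCGAGGG", snv(5L, "C", "T"), p, flank = 5)
  expect_identical(lost$enzyme, "TaqI")
  expect_identical(lost$status, "lost")
  expect_identical(lost$ref_sites, "4")
  expect_identical(lost$alt_sites, "")

  gained <- detect_caps("GGGTTGAGGG", snv(5L, "T", "C"), p, flank = 5)
  expect_identical(gained$enzyme, "TaqI")
  expect_identical(gained$status, "gained")

  none <- detect_caps("GGGTTGAGGG", snv(1L, "G", "A"), p, flank = 5)
  expect_identical(nrow(none), 0L)
})

test_that("candidate status always reflects the site-count difference", {
  p <- load_panel()
  withr::with_seed(99, {
    for (rep in 1:50) {
      s <- random_dna(120)
      pos <- sample(30:90, 1)
      ref_b <- substr(s, pos, pos)
      alt_b <- sample(setdiff(c("A", "C", "G", "T"), ref_b), 1)
      cand <- detect_caps(s, snv(pos, ref_b, alt_b), p)
      if (nrow(cand)) {
        expect_true(all((cand$status == "gained") ==
                          (cand$n_alt_sites > cand$n_ref_sites)))
        expect_true(all(cand$n_alt_sites != cand$n_ref_sites))
      }
    }
  })
})

test_that("detection windows are clipped at contig ends and flagged", {
  p <- load_panel()
  res <- detect_caps("GTCGAGGGGG", snv(3L, "C", "T"), p, flank = 50)
  expect_identical(res$enzyme, "TaqI")
  expect_true(res$clipped)
})

test_that("flank shorter than the longest site is rejected", {
  expect_error(detect_caps("GGGTCGAGGG", snv(5L, "C", "T"), load_panel(),
                           flank = 2), "flank")
})

test_that("pure-shift indels yield no candidate, junction indels do", {
  p <- load_panel()
  # TCGA at 3-6; deleting an A in the downstream run only translates it
  s <- "GGTCGAGGAAAAGGGGGGGG"
  del <- tibble::tibble(seqid = "c1", vtype = "deletion", start = 10L,
                        end = 10L, ref_allele = "A", alt_allele = "-",
                        id = "d1")
  expect_identical(nrow(detect_caps(s, del, p)), 0L)
  # deleting one base of the site itself destroys it
  del_site <- tibble::tibble(seqid = "c1", vtype = "deletion", start = 4L,
                             end = 4L, ref_allele = "C", alt_allele = "-",
                             id = "d2")
  res <- detect_caps(s, del_site, p)
  expect_true("TaqI" %in% res$enzyme)
  expect_identical(res$status[res$enzyme == "TaqI"], "lost")
  # an insertion completing TC|A -> TCGA gains the site at the junction
  ins <- tibble::tibble(seqid = "c1", vtype = "insertion", start = 3L,
                        end = 3L, ref_allele = "-", alt_allele = "G",
                        id = "i1")
  res2 <- detect_caps("GTCAGGGGGG", ins, p)
  expect_identical(res2$status[res2$enzyme == "TaqI"], "gained")
})

test_that("another variant inside the window sets the confounded flag", {
  p <- load_panel()
  others <- dplyr::bind_rows(snv(5L, "C", "T", id = "v1"),
                             snv(12L, "G", "A", id = "v2"))
  res <- detect_caps("GGGTCGAGGGGGGGGG", others[1, ], p, flank = 10,
                     other_variants = others)
  expect_true(all(res$confounded))
  res2 <- detect_caps("GGGTCGAGGGGGGGGG", others[1, ], p, flank = 5,
                      other_variants = others[1, ])
  expect_false(any(res2$confounded))
})

test_that("snp_class maps all twelve ordered allele pairs", {
  expect_identical(snp_class(c("C", "T", "G", "A"), c("T", "C", "A", "G")),
                   rep("I", 4))
  expect_identical(snp_class(c("C", "A", "G", "T"), c("A", "C", "T", "G")),
                   rep("II", 4))
  expect_identical(snp_class(c("C", "G"), c("G", "C")), rep("III", 2))
  expect_identical(snp_class(c("A", "T"), c("T", "A")), rep("IV", 2))
  expect_error(snp_class("A", "A"), "distinct")
  expect_error(snp_class("A", "N"), "distinct")
})

test_that("snp_class is strand-symmetric", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bases <- c("A", "C", "G", "T")
  for (r in bases) for (a in setdiff(bases, r)) {
    expect_identical(snp_class(r, a), snp_class(comp[[r]], comp[[a]]))
  }
})

test_that("filter_hrm_targets keeps exactly class I/II SNVs", {
  v <- dplyr::bind_rows(
    snv(1L, "A", "G", id = "s1"), snv(2L, "A", "T", id = "s2"),
    snv(3L, "C", "G", id = "s3"), snv(4L, "C", "A", id = "s4"),
    tibble::tibble(seqid = "c1", source = "t", vtype = "insertion",
                   start = 5L, end = 5L, ref_allele = "-",
                   alt_allele = "GG", id = "i1"))
  out <- filter_hrm_targets(v)
  expect_identical(out$id, c("s1", "s4"))
  expect_identical(out$hrm_class, c("I", "II"))
  expect_identical(attr(out, "dropped_indels"), 1L)
  expect_identical(attr(out, "dropped_class"), 2L)
  expect_identical(nrow(filter_hrm_targets(v[5, ])), 0L)
  expect_identical(nrow(filter_hrm_targets(v[0, ])), 0L)
})

test_that("scan_variants tallies per enzyme, skips N alleles, keeps order", {
  p <- load_panel()
  ref <- c(c1 = "GGGTCGAGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGAGCTGGGG")
  v <- dplyr::bind_rows(
    snv(5L, "C", "T", id = "a"),        # TaqI lost
    snv(54L, "C", "T", id = "b"),       # AluI lost
    snv(20L, "G", "N", id = "n1"))      # skipped
  sc <- scan_variants(ref, v, p)
  g <- glance(sc)
  expect_identical(g$variants_seen, 3L)
  expect_identical(g$variants_skipped_n, 1L)
  expect_identical(g$TaqI, 1L)
  expect_identical(g$AluI, 1L)
  expect_identical(tidy(sc)$variant_id[1], "a")
  expect_error(scan_variants(ref, snv(5L, "C", "T", seqid = "nope"), p),
               "missing from reference")
})

test_that("scan_variants accepts a GFF3 path with identical results", {
  p <- load_panel()
  ref <- c(c1 = "GGGTCGAGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGAGCTGGGG")
  v <- dplyr::bind_rows(snv(5L, "C", "T", id = "a"),
                        snv(54L, "C", "T", id = "b"))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_variant_gff3(v, path)
  direct <- tidy(scan_variants(ref, v, p))
  from_file <- tidy(scan_variants(ref, path, p))
  expect_identical(as.data.frame(direct), as.data.frame(from_file))
})

test_that("candidate tables sort stably and round-trip through TSV", {
  p <- load_panel()
  ref <- c(c1 = "GGGTCGAGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGGAGCTGGGG")
  v <- dplyr::bind_rows(snv(54L, "C", "T", id = "b"),
                        snv(5L, "C", "T", id = "a"))
  tab <- candidates_to_table(scan_variants(ref, v, p))
  expect_true(all(diff(order(tab$seqid, tab$start, tab$enzyme)) > 0))
  expect_gte(ncol(tab), 9L)
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tab, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_identical(back$enzyme, tab$enzyme)
  expect_identical(as.integer(back$start), tab$start)
  expect_identical(as.logical(back$confounded), tab$confounded)
})
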