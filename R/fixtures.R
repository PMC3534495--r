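# Seeded synthetic fixtures: random transcriptome-like contigs with
# planted SNVs/indels and a digest-verified ground-truth table.
#
# Ground truth is verified at generation time by a regex-based digest
# (IUPAC codes expanded to character classes, overlapping matches counted
# with lookahead) — a mechanism deliberately different from the lookup-table
# scanner behind find_sites(), so the truth table is an independent oracle
# for the detection code.

.iupac_regex <- function(site) {
  chars <- strsplit(toupper(site), "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (is.null(set)) stop("invalid IUPAC symbol: ", ch, call. = FALSE)
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# Overlapping match count of an IUPAC site (both strands, palindrome
# collapsed) in a window, via PCRE lookahead.
.regex_site_count <- function(window, site) {
  cnt <- function(pat) {
    m <- gregexpr(paste0("(?=", .iupac_regex(pat), ")"), window,
                  perl = TRUE)[[1]]
    if (m[1] == -1L) 0L else length(m)
  }
  rc <- iupac_revcomp(site)
  if (rc == site) cnt(site) else cnt(site) + cnt(rc)
}

# Inline allele application (kept independent of apply_variant on purpose).
.edit_seq <- function(seq, vtype, p, q, ref_a, alt_a) {
  n <- nchar(seq)
  switch(vtype,
    SNV = paste0(substr(seq, 1L, p - 1L), alt_a, substr(seq, p + 1L, n)),
    deletion = paste0(substr(seq, 1L, p - 1L), substr(seq, q + 1L, n)),
    insertion = paste0(substr(seq, 1L, p), alt_a, substr(seq, p + 1L, n))
  )
}

# Expected (enzyme, status) set for one variant by brute-force digest of
# the +/- flank windows of both alleles.
.truth_expected <- function(contig, vtype, start, end, ref_a, alt_a, panel,
                            flank) {
  w1 <- max(1L, start - flank)
  w2 <- min(nchar(contig), end + flank)
  win <- substr(contig, w1, w2)
  altwin <- .edit_seq(win, vtype, start - w1 + 1L, end - w1 + 1L,
                      ref_a, alt_a)
  out <- list()
  for (i in seq_len(nrow(panel))) {
    cr <- .regex_site_count(win, panel$site[i])
    ca <- .regex_site_count(altwin, panel$site[i])
    if (cr != ca) {
      out[[length(out) + 1L]] <- list(
        enzyme = panel$name[i],
        status = if (ca > cr) "gained" else "lost")
    }
  }
  out
}

.expected_string <- function(exp) {
  if (!length(exp)) return("")
  paste(vapply(exp, function(e) paste0(e$enzyme, ":", e$status),
               character(1)), collapse = ";")
}

# Concrete realisation of a degenerate site (each code replaced by a
# random member of its base set).
.realise_site <- function(site) {
  chars <- strsplit(site, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (length(set) == 1L) set else sample(set, 1L)
  }, character(1)), collapse = "")
}

#' Generate a seeded synthetic reference + variant fixture with ground truth
#'
#' Builds random contigs of uniform base composition and plants
#' `n_variants` variants on them. A `planted_caps_fraction` share of the
#' variants is constructed to create (`gained`) or destroy (`lost`) a
#' recognition site of a randomly chosen panel enzyme, by embedding a
#' concrete site and flipping one of its bases; the remainder are placed
#' so that no panel enzyme's site count changes between alleles (a share
#' of those are 1-3 bp indels). Every planted variant's full expected
#' (enzyme, status) set is verified at generation time by an internal
#' regex-based brute-force digest and recorded in the truth table; retries
#' re-randomise a placement whose verification fails, and exhausting the
#' retry budget is an error. The same seed reproduces byte-identical
#' FASTA/VCF/truth outputs.
#'
#' Variants are spaced at least `min_spacing` bases apart so detection
#' windows do not overlap; `n_neighbours` optionally adds count-neutral
#' SNVs 15-45 bp from randomly chosen variants to exercise window
#' confounding and primer masking.
#'
#' @param seed Integer seed; all randomness flows through it.
#' @param n_contigs,contig_length Number and length of reference contigs.
#' @param n_variants Number of primary planted variants.
#' @param planted_caps_fraction Fraction of variants constructed as CAPS
#'   polymorphisms, in `[0, 1]`.
#' @param panel Enzyme panel (default [load_panel()]).
#' @param flank Detection window half-width used for truth verification.
#' @param indel_fraction Fraction of the *neutral* variants planted as
#'   indels rather than SNVs.
#' @param n_neighbours Count-neutral neighbour SNVs to add within 50 bp of
#'   randomly chosen variants (default 0).
#' @param min_spacing Minimum distance between primary variants.
#' @param dir If given, `ref.fa`, `variants.vcf` and `truth.tsv` are
#'   written there.
#' @return A list: `ref` (named character vector), `variants`
#'   (variant-feature tibble including neighbours), `truth` (one row per
#'   planted variant incl. neighbours: role, expected enzyme/status,
#'   full expected set, HRM class, neighbour ids), `fasta` and `vcf`
#'   (text lines), and file `paths` when `dir` is given.
#' @export
generate_fixture <- function(seed = 42L, n_contigs = 6L,
                             contig_length = 2400L, n_variants = 60L,
                             planted_caps_fraction = 0.5,
                             panel = load_panel(), flank = 50L,
                             indel_fraction = 0.2, n_neighbours = 0L,
                             min_spacing = 150L, dir = NULL) {
  stopifnot(planted_caps_fraction >= 0, planted_caps_fraction <= 1)
  withr::with_seed(as.integer(seed), {
    margin <- 170L
    per_contig <- (contig_length - 2L * margin) %/% min_spacing + 1L
    if (per_contig * n_contigs < n_variants) {
      stop("contigs too small for ", n_variants, " variants at spacing ",
           min_spacing, call. = FALSE)
    }
    contig_names <- sprintf("contig%03d", seq_len(n_contigs))
    ref <- stats::setNames(vapply(seq_len(n_contigs), function(i)
      paste(sample(c("A", "C", "G", "T"), contig_length, replace = TRUE),
            collapse = ""), character(1)), contig_names)

    # slot positions, round-robin across contigs, jittered on a grid
    slots <- list()
    k <- 0L
    for (j in seq_len(per_contig)) {
      for (ci in seq_len(n_contigs)) {
        if (k >= n_variants) break
        k <- k + 1L
        pos <- margin + (j - 1L) * min_spacing +
          sample.int(min_spacing - 110L, 1L)
        slots[[k]] <- list(seqid = contig_names[ci], pos = pos)
      }
    }
    n_caps <- round(planted_caps_fraction * n_variants)
    roles <- sample(c(rep("caps", n_caps),
                      rep("neutral", n_variants - n_caps)))

    truth_rows <- vector("list", n_variants)
    for (k in seq_len(n_variants)) {
      s <- slots[[k]]
      res <- if (roles[k] == "caps") {
        .plant_caps_variant(ref[[s$seqid]], s$pos, panel, flank)
      } else {
        .plant_neutral_variant(ref[[s$seqid]], s$pos, panel, flank,
                               indel = stats::runif(1) < indel_fraction)
      }
      ref[[s$seqid]] <- res$contig
      truth_rows[[k]] <- tibble::tibble(
        id = sprintf("var%04d", k), seqid = s$seqid, role = roles[k],
        vtype = res$vtype, start = res$start, end = res$end,
        ref_allele = res$ref_a, alt_allele = res$alt_a,
        enzyme = res$enzyme, status = res$status, expected = res$expected,
        hrm_class = if (res$vtype == "SNV")
          snp_class(res$ref_a, res$alt_a) else NA_character_,
        neighbour_ids = ""
      )
    }
    truth <- dplyr::bind_rows(truth_rows)

    # neighbours: count-neutral SNVs near randomly chosen primary variants
    if (n_neighbours > 0L) {
      anchors <- sample(seq_len(n_variants), n_neighbours,
                        replace = n_neighbours > n_variants)
      for (j in seq_len(n_neighbours)) {
        a <- truth[anchors[j], ]
        offset <- sample(15:45, 1L) * sample(c(-1L, 1L), 1L)
        pos <- a$start + offset
        res <- .plant_neutral_variant(ref[[a$seqid]], pos, panel, flank,
                                      indel = FALSE)
        ref[[a$seqid]] <- res$contig
        nid <- sprintf("nbr%04d", j)
        truth <- dplyr::bind_rows(truth, tibble::tibble(
          id = nid, seqid = a$seqid, role = "neighbour",
          vtype = res$vtype, start = res$start, end = res$end,
          ref_allele = res$ref_a, alt_allele = res$alt_a,
          enzyme = res$enzyme, status = res$status, expected = res$expected,
          hrm_class = snp_class(res$ref_a, res$alt_a),
          neighbour_ids = a$id))
        truth$neighbour_ids[truth$id == a$id] <- paste0(
          truth$neighbour_ids[truth$id == a$id],
          ifelse(nzchar(truth$neighbour_ids[truth$id == a$id]), ",", ""), nid)
      }
    }
    truth <- dplyr::arrange(truth, .data$seqid, .data$start, .data$id)

    variants <- tibble::tibble(
      seqid = truth$seqid, source = "fixture", vtype = truth$vtype,
      start = truth$start, end = truth$end,
      ref_allele = truth$ref_allele, alt_allele = truth$alt_allele,
      id = truth$id)

    fasta <- unlist(lapply(contig_names, function(nm) {
      s <- ref[[nm]]
      starts <- seq(1L, nchar(s), by = 60L)
      c(paste0(">", nm), substring(s, starts, pmin(starts + 59L, nchar(s))))
    }))
    vcf <- .features_to_vcf(variants, ref)

    paths <- NULL
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      paths <- list(fasta = file.path(dir, "ref.fa"),
                    vcf = file.path(dir, "variants.vcf"),
                    truth = file.path(dir, "truth.tsv"))
      writeLines(fasta, paths$fasta)
      writeLines(vcf, paths$vcf)
      readr::write_tsv(truth, paths$truth, progress = FALSE)
    }
    list(ref = ref, variants = variants, truth = truth,
         fasta = fasta, vcf = vcf, paths = paths, seed = as.integer(seed))
  })
}

# Plant a CAPS variant at ~pos: embed a concrete enzyme site and flip one
# of its bases; `lost` breaks the site in the alternate allele, `gained`
# breaks it in the reference so the variant restores it. Verified by
# regex digest; re-randomised on failure.
.plant_caps_variant <- function(contig, pos, panel, flank, max_try = 40L) {
  for (try in seq_len(max_try)) {
    ei <- sample.int(nrow(panel), 1L)
    site <- .realise_site(panel$site[ei])
    m <- nchar(site)
    mode <- sample(c("lost", "gained"), 1L)
    j <- sample.int(m, 1L)
    site_base <- substr(site, j, j)
    other <- sample(setdiff(c("A", "C", "G", "T"), site_base), 1L)
    edit_at <- pos + j - 1L

    work <- paste0(substr(contig, 1L, pos - 1L), site,
                   substr(contig, pos + m, nchar(contig)))
    if (mode == "lost") {
      ref_a <- site_base; alt_a <- other
    } else {
      work <- paste0(substr(work, 1L, edit_at - 1L), other,
                     substr(work, edit_at + 1L, nchar(work)))
      ref_a <- other; alt_a <- site_base
    }
    exp <- .truth_expected(work, "SNV", edit_at, edit_at, ref_a, alt_a,
                           panel, flank)
    hit <- purrr::detect(exp, ~ .x$enzyme == panel$name[ei] &&
                           .x$status == mode)
    if (!is.null(hit)) {
      return(list(contig = work, vtype = "SNV", start = edit_at,
                  end = edit_at, ref_a = ref_a, alt_a = alt_a,
                  enzyme = panel$name[ei], status = mode,
                  expected = .expected_string(exp)))
    }
  }
  stop("could not plant a CAPS variant after ", max_try, " attempts",
       call. = FALSE)
}

# Plant a variant whose alleles digest identically for every panel enzyme.
.plant_neutral_variant <- function(contig, pos, panel, flank, indel = FALSE,
                                   max_try = 60L) {
  for (try in seq_len(max_try)) {
    p <- pos + sample.int(21L, 1L) - 11L
    if (indel) {
      len <- sample.int(3L, 1L)
      if (stats::runif(1) < 0.5) {
        vtype <- "insertion"
        ref_a <- "-"
        alt_a <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                       collapse = "")
        start <- p; end <- p
      } else {
        vtype <- "deletion"
        ref_a <- substr(contig, p, p + len - 1L)
        alt_a <- "-"
        start <- p; end <- p + len - 1L
      }
    } else {
      vtype <- "SNV"
      ref_a <- substr(contig, p, p)
      alt_a <- sample(setdiff(c("A", "C", "G", "T"), ref_a), 1L)
      start <- p; end <- p
    }
    exp <- .truth_expected(contig, vtype, start, end, ref_a, alt_a, panel,
                           flank)
    if (!length(exp)) {
      return(list(contig = contig, vtype = vtype, start = start, end = end,
                  ref_a = ref_a, alt_a = alt_a,
                  enzyme = NA_character_, status = NA_character_,
                  expected = ""))
    }
  }
  stop("could not place a digest-neutral variant after ", max_try,
       " attempts", call. = FALSE)
}

# Variant features -> VCF body (anchor-base convention for indels).
.features_to_vcf <- function(variants, ref) {
  header <- c("##fileformat=VCFv4.2",
              "##source=capsmark-fixture",
              paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"))
  body <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    contig <- ref[[v$seqid]]
    switch(v$vtype,
      SNV = sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                    v$seqid, v$start, v$id, v$ref_allele, v$alt_allele),
      insertion = {
        anchor <- substr(contig, v$start, v$start)
        sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.", v$seqid, v$start, v$id,
                anchor, paste0(anchor, v$alt_allele))
      },
      deletion = {
        anchor <- substr(contig, v$start - 1L, v$start - 1L)
        sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.", v$seqid, v$start - 1L, v$id,
                paste0(anchor, v$ref_allele), anchor)
      })
  }, character(1))
  c(header, body)
}
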