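# CAPS polymorphism detection: apply a variant to a reference window,
# digest both alleles in silico, and report enzymes whose site counts
# differ between alleles.

#' Apply a variant to a sequence window
#'
#' Edits a reference window string according to one variant feature:
#' SNVs substitute a single base, deletions remove the deleted span,
#' insertions add the inserted bases immediately 3' of the anchor base.
#' The reference allele is checked against the window and a mismatch is an
#' error (it means coordinates or the reference are wrong).
#'
#' @param window A DNA string.
#' @param variant A one-row variant-feature tibble (or named list).
#' @param window_offset 1-based genomic position of the first window base.
#' @return The alternate-allele window string; length changes by the
#'   alt-minus-ref allele length difference.
#' @examples
#' apply_variant("GGGTCGAGGG",
#'   list(vtype = "SNV", start = 5, end = 5, ref_allele = "C",
#'        alt_allele = "T"), 1)
#' @export
apply_variant <- function(window, variant, window_offset = 1L) {
  v <- as.list(variant)
  p <- v$start - window_offset + 1L
  q <- v$end - window_offset + 1L
  n <- nchar(window)
  if (p < 1L || q > n) {
    stop("variant '", v$id %||% "?", "' lies outside the window", call. = FALSE)
  }
  switch(v$vtype,
    SNV = {
      have <- substr(window, p, p)
      if (have != v$ref_allele) {
        stop("reference mismatch at ", v$start, ": window has '", have,
             "', variant says '", v$ref_allele, "'", call. = FALSE)
      }
      paste0(substr(window, 1L, p - 1L), v$alt_allele,
             substr(window, p + 1L, n))
    },
    deletion = {
      have <- substr(window, p, q)
      if (have != v$ref_allele) {
        stop("reference mismatch at ", v$start, "-", v$end, ": window has '",
             have, "', variant says '", v$ref_allele, "'", call. = FALSE)
      }
      paste0(substr(window, 1L, p - 1L), substr(window, q + 1L, n))
    },
    insertion = {
      paste0(substr(window, 1L, p), v$alt_allele, substr(window, p + 1L, n))
    },
    stop("unknown vtype '", v$vtype, "'", call. = FALSE)
  )
}

#' Detect CAPS candidates for one variant
#'
#' Extracts a window of `flank` bases either side of the variant (clipped
#' at contig ends and flagged), builds the alternate-allele window with
#' [apply_variant()], and for every panel enzyme compares the *number* of
#' recognition sites between the two windows. A count difference means the
#' two alleles digest differently: the enzyme is a CAPS candidate, with
#' status `gained` (alternate allele has more sites) or `lost`. Comparing
#' counts rather than positions makes length-changing indels safe: an
#' indel that merely translates downstream sites yields no candidate.
#'
#' Other variants supplied in `other_variants` are *not* applied to the
#' alternate window (phase between nearby site-level calls is unknown);
#' a candidate whose window contains another variant is flagged
#' `confounded` instead.
#'
#' @param ref_seq The contig sequence (DNA string).
#' @param variant A one-row variant-feature tibble (or named list).
#' @param panel An [load_panel()] enzyme panel.
#' @param flank Bases of context either side of the variant; must be at
#'   least the longest site length minus one. Default 50.
#' @param other_variants Optional variant tibble used only to set the
#'   `confounded` flag.
#' @return A tibble with one row per candidate enzyme: variant identity
#'   and coordinates, `enzyme`, `status`, site counts and window-local
#'   site positions (comma-joined), `confounded`, `clipped`.
#' @examples
#' p <- load_panel()
#' detect_caps("GGGTCGAGGG",
#'   list(id = "v1", seqid = "c1", vtype = "SNV", start = 5, end = 5,
#'        ref_allele = "C", alt_allele = "T"), p, flank = 5)
#' @export
detect_caps <- function(ref_seq, variant, panel = load_panel(), flank = 50L,
                        other_variants = NULL) {
  v <- as.list(variant)
  max_site <- max(nchar(panel$site))
  if (flank < max_site - 1L) {
    stop("flank must be >= longest site length - 1 (", max_site - 1L, ")",
         call. = FALSE)
  }
  n <- nchar(ref_seq)
  if (v$start < 1L || v$end > n) {
    stop("variant '", v$id %||% "?", "' outside contig bounds", call. = FALSE)
  }
  w1 <- max(1L, v$start - as.integer(flank))
  w2 <- min(n, v$end + as.integer(flank))
  clipped <- (w1 > v$start - flank) || (w2 < v$end + flank)
  window <- substr(ref_seq, w1, w2)
  altwin <- apply_variant(window, v, window_offset = w1)

  confounded <- FALSE
  if (!is.null(other_variants) && nrow(other_variants)) {
    ov <- other_variants[other_variants$id != (v$id %||% ""), , drop = FALSE]
    ov <- ov[ov$seqid == v$seqid, , drop = FALSE]
    confounded <- any(ov$end >= w1 & ov$start <= w2)
  }

  ref_codes <- .seq_codes(window)
  alt_codes <- .seq_codes(altwin)
  rows <- vector("list", nrow(panel))
  for (i in seq_len(nrow(panel))) {
    site <- panel$site[i]
    rc <- iupac_revcomp(site)
    rs <- .scan_iupac(ref_codes, site)
    as_ <- .scan_iupac(alt_codes, site)
    if (!panel$palindromic[i]) {
      rs <- sort(c(rs, .scan_iupac(ref_codes, rc)))
      as_ <- sort(c(as_, .scan_iupac(alt_codes, rc)))
    }
    if (length(rs) == length(as_)) next
    rows[[i]] <- tibble::tibble(
      variant_id = v$id %||% NA_character_,
      seqid = v$seqid %||% NA_character_,
      start = as.integer(v$start), end = as.integer(v$end),
      vtype = v$vtype,
      enzyme = panel$name[i],
      status = if (length(as_) > length(rs)) "gained" else "lost",
      n_ref_sites = length(rs), n_alt_sites = length(as_),
      ref_sites = paste(rs, collapse = ","),
      alt_sites = paste(as_, collapse = ","),
      confounded = confounded,
      clipped = clipped
    )
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) out <- .empty_caps_tbl()
  out
}

.empty_caps_tbl <- function() {
  tibble::tibble(
    variant_id = character(), seqid = character(),
    start = integer(), end = integer(), vtype = character(),
    enzyme = character(), status = character(),
    n_ref_sites = integer(), n_alt_sites = integer(),
    ref_sites = character(), alt_sites = character(),
    confounded = logical(), clipped = logical()
  )
}

#' Scan a variant set for CAPS candidates
#'
#' Runs [detect_caps()] over every variant, contig by contig, and returns
#' all candidates in input order together with run counters. Variants may
#' be given as a tibble or as a path to a GFF3/GVF or VCF file, in which
#' case the file is streamed through the corresponding reader. Variants
#' whose alleles contain N are skipped and counted (conservative-N
#' matching would report spurious losses for them).
#'
#' @param ref Reference sequences: a named character vector, a
#'   `Biostrings::DNAStringSet`, or a FASTA file path.
#' @param variants A variant-feature tibble, or a path to a `.gff3`/`.gvf`
#'   or `.vcf` file.
#' @param panel An enzyme panel; default [load_panel()].
#' @param flank Window half-width in bases (default 50).
#' @return A tibble of class `caps_scan` of candidates, with counters
#'   available through [glance()]: variants seen, variants skipped,
#'   candidates emitted, and per-enzyme tallies.
#' @export
scan_variants <- function(ref, variants, panel = load_panel(), flank = 50L) {
  ref <- .as_ref_seqs(ref)
  if (is.character(variants) && length(variants) == 1L &&
      file.exists(variants)) {
    variants <- if (grepl("\\.vcf$", variants, ignore.case = TRUE)) {
      read_vcf_variants(variants)
    } else {
      read_variant_gff3(variants)
    }
  }
  missing <- setdiff(unique(variants$seqid), names(ref))
  if (length(missing)) {
    stop("contig(s) missing from reference: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  seen <- 0L; skipped_n <- 0L
  out <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    seen <- seen + 1L
    alle <- paste0(v$ref_allele, v$alt_allele)
    if (grepl("N", alle, fixed = TRUE)) {
      skipped_n <- skipped_n + 1L
      next
    }
    out[[i]] <- detect_caps(ref[[v$seqid]], v, panel, flank,
                            other_variants = variants)
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) res <- .empty_caps_tbl()
  tally <- stats::setNames(integer(nrow(panel)), panel$name)
  if (nrow(res)) {
    tb <- table(res$enzyme)
    tally[names(tb)] <- as.integer(tb)
  }
  structure(res,
            class = c("caps_scan", class(res)),
            variants_seen = seen,
            variants_skipped_n = skipped_n,
            candidates = nrow(res),
            enzyme_tally = tally)
}

.as_ref_seqs <- function(ref) {
  if (inherits(ref, "DNAStringSet")) {
    out <- as.character(ref)
    names(out) <- sub("\\s.*$", "", names(out))
    return(toupper(out))
  }
  if (is.character(ref) && length(ref) == 1L && is.null(names(ref)) &&
      file.exists(ref)) {
    x <- Biostrings::readDNAStringSet(ref)
    return(.as_ref_seqs(x))
  }
  if (is.character(ref) && !is.null(names(ref))) return(toupper(ref))
  stop("reference must be a named character vector, DNAStringSet or FASTA path",
       call. = FALSE)
}

#' @export
tidy.caps_scan <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "caps_scan")
  for (a in c("variants_seen", "variants_skipped_n", "candidates",
              "enzyme_tally")) attr(out, a) <- NULL
  tibble::as_tibble(out)
}

#' @export
glance.caps_scan <- function(x, ...) {
  tally <- attr(x, "enzyme_tally")
  dplyr::bind_cols(
    tibble::tibble(
      variants_seen = attr(x, "variants_seen"),
      variants_skipped_n = attr(x, "variants_skipped_n"),
      candidates = attr(x, "candidates")
    ),
    tibble::as_tibble(as.list(tally))
  )
}

#' Melting class of a SNP
#'
#' HRM genotyping resolves alleles by amplicon melting temperature, which
#' depends on the substitution type. The standard classes by unordered
#' allele pair: I = C/T or G/A, II = C/A or G/T, III = C/G, IV = A/T.
#' Classes I and II give usable melt shifts in small amplicons; III and IV
#' shift little and make poor HRM targets. The class is strand-symmetric.
#'
#' @param ref_allele,alt_allele Single bases in A/C/G/T (vectorised).
#' @return A character vector over `"I"`, `"II"`, `"III"`, `"IV"`.
#' @examples
#' snp_class("C", "T")  # "I"
#' snp_class("G", "T")  # "II"
#' @export
snp_class <- function(ref_allele, alt_allele) {
  key <- paste0(pmin(toupper(ref_allele), toupper(alt_allele)),
                pmax(toupper(ref_allele), toupper(alt_allele)))
  map <- c(CT = "I", AG = "I", AC = "II", GT = "II", CG = "III", AT = "IV")
  out <- unname(map[key])
  if (anyNA(out)) {
    stop("snp_class needs two distinct single bases in A/C/G/T", call. = FALSE)
  }
  out
}

#' Filter variants to HRM-suitable SNPs
#'
#' Keeps only SNVs of melting class I or II; indels and class III/IV SNVs
#' are dropped. The numbers dropped are recorded in attributes
#' `dropped_indels` and `dropped_class` on the result.
#'
#' @param variants A variant-feature tibble.
#' @return The retained rows, input order preserved, with an added
#'   `hrm_class` column.
#' @export
filter_hrm_targets <- function(variants) {
  is_snv <- variants$vtype == "SNV"
  snvs <- variants[is_snv, , drop = FALSE]
  cls <- if (nrow(snvs)) snp_class(snvs$ref_allele, snvs$alt_allele) else
    character(0)
  keep <- cls %in% c("I", "II")
  out <- snvs[keep, , drop = FALSE]
  out$hrm_class <- cls[keep]
  attr(out, "dropped_indels") <- sum(!is_snv)
  attr(out, "dropped_class") <- sum(!keep)
  out
}

#' Tabulate CAPS candidates for line-oriented filtering
#'
#' Returns the candidate table with a stable column order, sorted by
#' (seqid, start, enzyme), ready to write as TSV and slice with standard
#' text tools or [filter_table()].
#'
#' @param candidates A candidate tibble from [detect_caps()] /
#'   [scan_variants()].
#' @return A plain tibble sorted by (seqid, start, enzyme).
#' @export
candidates_to_table <- function(candidates) {
  cols <- c("variant_id", "seqid", "start", "end", "vtype", "enzyme",
            "status", "n_ref_sites", "n_alt_sites", "ref_sites",
            "alt_sites", "confounded", "clipped")
  out <- tibble::as_tibble(candidates)[, cols]
  class(out) <- class(tibble::tibble())
  dplyr::arrange(out, .data$seqid, .data$start, .data$enzyme)
}
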