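# Electronic PCR: ungapped primer matching with 3'-end anchoring,
# amplicon prediction from convergent matches, gapped primer mapping, and
# a parser for primersearch-style amplimer reports.

# Mismatch profile of `pcodes` slid along `scodes`; NA (non-ACGT) in the
# sequence counts as a mismatch at every offset.
.mm_profile <- function(scodes, pcodes, positions = seq_along(pcodes)) {
  n <- length(scodes); m <- length(pcodes)
  k <- n - m + 1L
  if (k < 1L) return(integer(0))
  mm <- integer(k)
  for (j in positions) {
    v <- scodes[j:(j + k - 1L)]
    neq <- v != pcodes[j]
    neq[is.na(neq)] <- TRUE
    mm <- mm + as.integer(neq)
  }
  mm
}

#' Match a primer against a sequence (ungapped, 3'-anchored)
#'
#' Reports every ungapped alignment of the primer on the top strand, and
#' of its reverse complement on the bottom strand, with at most
#' `max_mismatch` mismatches overall and *zero* mismatches in the
#' 3'-terminal `three_prime_exact` bases — mismatches at the extending 3'
#' end abolish priming, so they disqualify a hit regardless of the total.
#' On the bottom strand the primer's 3' end faces the *start* of the
#' matched top-strand window.
#'
#' @param primer Primer sequence, 5' to 3'.
#' @param seq Template DNA string.
#' @param max_mismatch Maximum total mismatches (default 0).
#' @param three_prime_exact Bases at the 3' end required to match exactly
#'   (default 3).
#' @return A tibble with `start` (1-based top-strand window start),
#'   `strand`, `mismatches`, sorted by position.
#' @export
match_primer <- function(primer, seq, max_mismatch = 0L,
                         three_prime_exact = 3L) {
  m <- nchar(primer)
  stopifnot(m >= three_prime_exact)
  scodes <- .seq_codes(seq)
  pc <- .seq_codes(primer)
  rcc <- .seq_codes(dna_revcomp(primer))
  hits <- list()

  mm_f <- .mm_profile(scodes, pc)
  if (length(mm_f)) {
    tail_pos <- seq.int(m - three_prime_exact + 1L, m)
    mm3 <- if (three_prime_exact > 0L)
      .mm_profile(scodes, pc, tail_pos) else integer(length(mm_f))
    keep <- mm_f <= max_mismatch & mm3 == 0L
    if (any(keep)) hits$fwd <- tibble::tibble(
      start = which(keep), strand = "+", mismatches = mm_f[keep])
  }
  mm_r <- .mm_profile(scodes, rcc)
  if (length(mm_r)) {
    head_pos <- seq_len(three_prime_exact)   # 3' end of the rc primer
    mm3 <- if (three_prime_exact > 0L)
      .mm_profile(scodes, rcc, head_pos) else integer(length(mm_r))
    keep <- mm_r <= max_mismatch & mm3 == 0L
    if (any(keep)) hits$rev <- tibble::tibble(
      start = which(keep), strand = "-", mismatches = mm_r[keep])
  }
  out <- dplyr::bind_rows(hits)
  if (!nrow(out)) {
    return(tibble::tibble(start = integer(), strand = character(),
                          mismatches = integer()))
  }
  dplyr::arrange(out, .data$start, .data$strand)
}

#' Electronic PCR of primer pairs against reference sequences
#'
#' For every pair and reference sequence, finds all convergent
#' combinations of a forward-strand match of one primer with a
#' reverse-strand match of the other (either orientation), with the 3'
#' ends facing each other and a product no longer than `max_product`.
#' Pairs hitting zero loci (failed assay) or more than one locus
#' (non-specific assay) are flagged in the per-pair summary, available
#' through [glance()].
#'
#' @param pairs A tibble with `pair_id`, `left_seq`, `right_seq` (e.g.
#'   from [design_primers()]).
#' @param ref Named character vector, `DNAStringSet`, or FASTA path.
#' @param max_mismatch,three_prime_exact Passed to [match_primer()].
#' @param max_product Longest reportable product (default 2000 bp).
#' @return A tibble of class `epcr_result`: `pair_id`, `seqid`,
#'   `fwd_start`, `rev_start` (top-strand start of the reverse-primer
#'   window), `product_length`, `mm_fwd`, `mm_rev`, `orientation`
#'   (`"forward"` = left primer on the top strand). Attribute `summary`
#'   (via [glance()]) tallies hits per pair with a `specific` flag.
#' @export
epcr <- function(pairs, ref, max_mismatch = 0L, three_prime_exact = 3L,
                 max_product = 2000L) {
  ref <- .as_ref_seqs(ref)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    pid <- pairs$pair_id[i]
    lseq <- pairs$left_seq[i]; rseq <- pairs$right_seq[i]
    for (sq in names(ref)) {
      lm <- match_primer(lseq, ref[[sq]], max_mismatch, three_prime_exact)
      rm_ <- match_primer(rseq, ref[[sq]], max_mismatch, three_prime_exact)
      rows[[length(rows) + 1L]] <- .pair_hits(
        pid, sq, lm, rm_, nchar(lseq), nchar(rseq), max_product, "forward")
      rows[[length(rows) + 1L]] <- .pair_hits(
        pid, sq, rm_, lm, nchar(rseq), nchar(lseq), max_product, "reverse")
    }
  }
  hits <- dplyr::bind_rows(rows)
  if (!nrow(hits)) {
    hits <- tibble::tibble(
      pair_id = character(), seqid = character(), fwd_start = integer(),
      rev_start = integer(), product_length = integer(),
      mm_fwd = integer(), mm_rev = integer(), orientation = character())
  }
  counts <- table(factor(hits$pair_id, levels = unique(pairs$pair_id)))
  summary <- tibble::tibble(
    pair_id = names(counts),
    n_hits = as.integer(counts),
    specific = as.integer(counts) == 1L
  )
  structure(hits, class = c("epcr_result", class(hits)), summary = summary)
}

# Convergent combinations: fwd primer (+) at f, rev primer (-) window at r.
.pair_hits <- function(pid, sq, fwd, rev, len_f, len_r, max_product,
                       orientation) {
  fwd <- fwd[fwd$strand == "+", , drop = FALSE]
  rev <- rev[rev$strand == "-", , drop = FALSE]
  if (!nrow(fwd) || !nrow(rev)) return(NULL)
  combos <- tidyr::crossing(
    f = seq_len(nrow(fwd)), r = seq_len(nrow(rev)))
  f_start <- fwd$start[combos$f]
  r_start <- rev$start[combos$r]
  product <- r_start + len_r - 1L - f_start + 1L
  ok <- r_start >= f_start & product <= max_product &
    product >= pmax(len_f, len_r)
  if (!any(ok)) return(NULL)
  tibble::tibble(
    pair_id = pid, seqid = sq,
    fwd_start = f_start[ok], rev_start = r_start[ok],
    product_length = as.integer(product[ok]),
    mm_fwd = fwd$mismatches[combos$f][ok],
    mm_rev = rev$mismatches[combos$r][ok],
    orientation = orientation
  )
}

#' @export
tidy.epcr_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "epcr_result")
  attr(out, "summary") <- NULL
  tibble::as_tibble(out)
}

#' @export
glance.epcr_result <- function(x, ...) {
  attr(x, "summary")
}

#' Map individual primers onto sequences with gapped matching
#'
#' Approximate (edit-distance) mapping of single primers, tolerating
#' substitutions *and* indels up to `max_edits` total — the looser search
#' used to ask "where could this oligo anneal at all", as distinct from
#' the ungapped, 3'-anchored matching that models productive priming in
#' [epcr()]. Alignment is delegated to `Biostrings::matchPattern()` with
#' indels enabled.
#'
#' @param primers A tibble with `primer_id` and `seq` columns, or a named
#'   character vector of primer sequences.
#' @param ref Named character vector, `DNAStringSet`, or FASTA path.
#' @param max_edits Maximum total edit operations (default 2).
#' @return A tibble: `primer_id`, `seqid`, `start`, `end`, `strand`,
#'   `edits` (Levenshtein distance between primer and matched span).
#' @export
map_primers <- function(primers, ref, max_edits = 2L) {
  if (is.character(primers)) {
    primers <- tibble::tibble(
      primer_id = names(primers) %||% paste0("primer", seq_along(primers)),
      seq = unname(primers))
  }
  ref <- .as_ref_seqs(ref)
  rows <- list()
  for (i in seq_len(nrow(primers))) {
    for (sq in names(ref)) {
      subject <- Biostrings::DNAString(ref[[sq]])
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") primers$seq[i] else
          dna_revcomp(primers$seq[i])
        m <- Biostrings::matchPattern(pat, subject,
                                      max.mismatch = max_edits,
                                      with.indels = TRUE)
        if (!length(m)) next
        spans <- as.character(m)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          primer_id = primers$primer_id[i], seqid = sq,
          start = BiocGenerics::start(m), end = BiocGenerics::end(m),
          strand = strand,
          edits = as.integer(utils::adist(pat, spans))
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    return(tibble::tibble(primer_id = character(), seqid = character(),
                          start = integer(), end = integer(),
                          strand = character(), edits = integer()))
  }
  out[out$edits <= max_edits, , drop = FALSE]
}

#' Parse a primersearch-style amplimer report
#'
#' Reads the block dialect written by EMBOSS primersearch: a
#' `Primer name <id>` line opens each pair's section, each predicted
#' product is an `Amplimer N` block holding a `Sequence:` line, one
#' forward-strand and one reverse-strand `hits ... with N mismatches`
#' line, and an `Amplimer length: N bp` line. The reverse-strand position
#' is printed in brackets as a distance from the 3' end of the target
#' sequence and is returned as parsed (`rev_offset3`), since the report
#' does not carry the sequence length.
#'
#' @param input A file path, `"-"`, an open connection, or text lines.
#' @return A tibble, one row per amplimer: `pair_id`, `seqid`,
#'   `fwd_start`, `rev_offset3`, `mm_fwd`, `mm_rev`, `product_length`.
#' @export
parse_amplimer_report <- function(input) {
  src <- .open_lines(input)
  if (src$close) on.exit(close(src$con), add = TRUE)
  if (!isOpen(src$con)) open(src$con, open = "rt")
  lines <- readLines(src$con, warn = FALSE)

  rows <- list()
  pair <- NA_character_
  blk <- NULL
  blk_index <- 0L
  finish <- function() {
    if (is.null(blk)) return(invisible())
    need <- c("seqid", "fwd_start", "rev_offset3", "product_length")
    if (!all(need %in% names(blk))) {
      stop("malformed amplimer block ", blk_index, ": missing ",
           paste(setdiff(need, names(blk)), collapse = ", "), call. = FALSE)
    }
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      pair_id = pair, seqid = blk$seqid,
      fwd_start = blk$fwd_start, rev_offset3 = blk$rev_offset3,
      mm_fwd = blk$mm_fwd %||% NA_integer_,
      mm_rev = blk$mm_rev %||% NA_integer_,
      product_length = blk$product_length)
    blk <<- NULL
  }
  for (ln in lines) {
    t <- trimws(ln)
    if (grepl("^Primer name ", t)) {
      finish()
      pair <- sub("^Primer name\\s+", "", t)
    } else if (grepl("^Amplimer\\s+\\d+$", t)) {
      finish()
      blk_index <- blk_index + 1L
      blk <- list()
    } else if (!is.null(blk) && grepl("^Sequence:", t)) {
      blk$seqid <- trimws(sub("^Sequence:\\s*", "", t))
    } else if (!is.null(blk) &&
               grepl("hits forward strand at \\d+ with \\d+ mismatch", t)) {
      blk$fwd_start <- as.integer(
        sub(".*hits forward strand at (\\d+) with.*", "\\1", t))
      blk$mm_fwd <- as.integer(
        sub(".*with (\\d+) mismatch.*", "\\1", t))
    } else if (!is.null(blk) &&
               grepl("hits reverse strand at \\[\\d+\\] with \\d+ mismatch",
                     t)) {
      blk$rev_offset3 <- as.integer(
        sub(".*hits reverse strand at \\[(\\d+)\\] with.*", "\\1", t))
      blk$mm_rev <- as.integer(sub(".*with (\\d+) mismatch.*", "\\1", t))
    } else if (!is.null(blk) && grepl("^Amplimer length:", t)) {
      blk$product_length <- as.integer(
        sub("^Amplimer length:\\s*(\\d+)\\s*bp.*", "\\1", t))
    }
  }
  finish()
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble::tibble(pair_id = character(), seqid = character(),
                          fwd_start = integer(), rev_offset3 = integer(),
                          mm_fwd = integer(), mm_rev = integer(),
                          product_length = integer())
  }
  out
}
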