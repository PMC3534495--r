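# Variant-masked flanking primer design.
#
# Templates are reference windows centred on a target variant with every
# *other* (non-target) variant position replaced by N, so primers cannot
# anneal over segregating sites and assays amplify uniformly across
# genotypes. The design engine enumerates candidate oligos under
# length/Tm/GC constraints, scores them with a primer3-style additive
# penalty, and pairs them under marker-type-specific product-size ranges.

#' Primer design configuration
#'
#' Amplicon-size ranges per marker type default to 90-120 bp for CAPS
#' (small products digest and resolve cleanly on high-percentage agarose)
#' and 60-100 bp for indel and HRM markers (short amplicons maximise the
#' allele melt shift and indel length resolution). Oligo constraints are
#' conventional PCR defaults.
#'
#' @param product_size Named list of `c(min, max)` product sizes per
#'   marker type.
#' @param primer_length `c(min, max)` primer length in bases.
#' @param primer_opt_length Optimum primer length.
#' @param tm_range `c(min, max)` acceptable melting temperature, Celsius.
#' @param tm_opt Optimum melting temperature.
#' @param gc_range `c(min, max)` acceptable GC percentage.
#' @param max_poly_run Longest tolerated mononucleotide run.
#' @param max_pairs Maximum primer pairs returned per target.
#' @param mask_char Mask character for non-target variant positions.
#' @return A list of class `design_config`.
#' @export
design_config <- function(product_size = list(CAPS = c(90L, 120L),
                                              indel = c(60L, 100L),
                                              HRM = c(60L, 100L)),
                          primer_length = c(18L, 30L),
                          primer_opt_length = 21L,
                          tm_range = c(52, 65),
                          tm_opt = 59,
                          gc_range = c(20, 80),
                          max_poly_run = 4L,
                          max_pairs = 5L,
                          mask_char = "N") {
  for (r in product_size) {
    stopifnot(length(r) == 2L, r[1] <= r[2], r[1] > 0)
  }
  stopifnot(primer_length[1] <= primer_length[2],
            tm_range[1] <= tm_range[2], gc_range[1] <= gc_range[2])
  structure(list(product_size = product_size,
                 primer_length = as.integer(primer_length),
                 primer_opt_length = as.integer(primer_opt_length),
                 tm_range = tm_range, tm_opt = tm_opt,
                 gc_range = gc_range,
                 max_poly_run = as.integer(max_poly_run),
                 max_pairs = as.integer(max_pairs),
                 mask_char = mask_char),
            class = "design_config")
}

# --- oligo thermodynamics -------------------------------------------------

# Nearest-neighbour enthalpy (kcal/mol) and entropy (cal/mol/K),
# SantaLucia (1998) unified parameters, with duplex-initiation terms per
# terminal base and a monovalent-salt entropy correction.
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Oligo melting temperature (nearest-neighbour model)
#'
#' Two-state nearest-neighbour Tm with unified stacking parameters,
#' terminal initiation terms, entropy corrected for monovalent salt
#' (0.368 x (n-1) x ln[Na+]), at a given total oligo concentration.
#'
#' @param seq Character vector of oligo sequences (ACGT).
#' @param oligo_conc Total oligo strand concentration, mol/L (default
#'   50 nM, the usual PCR assumption).
#' @param na_conc Monovalent cation concentration, mol/L (default 50 mM).
#' @return Melting temperatures in degrees Celsius.
#' @export
oligo_tm <- function(seq, oligo_conc = 5e-8, na_conc = 5e-2) {
  vapply(toupper(seq), function(s) {
    m <- nchar(s)
    if (m < 2L) return(NA_real_)
    steps <- substring(s, 1:(m - 1L), 2:m)
    dh <- sum(.NN_DH[steps])
    ds <- sum(.NN_DS[steps])
    if (is.na(dh)) return(NA_real_)
    for (termbase in c(substr(s, 1L, 1L), substr(s, m, m))) {
      if (termbase %in% c("G", "C")) {
        dh <- dh + 0.1; ds <- ds - 2.8
      } else {
        dh <- dh + 2.3; ds <- ds + 4.1
      }
    }
    ds <- ds + 0.368 * (m - 1L) * log(na_conc)
    1000 * dh / (ds + 1.987 * log(oligo_conc / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

.gc_percent <- function(seq) {
  vapply(toupper(seq), function(s) {
    n <- nchar(s)
    100 * (n - nchar(gsub("[GC]", "", s))) / n
  }, numeric(1), USE.NAMES = FALSE)
}

.max_poly_run <- function(seq) {
  vapply(toupper(seq), function(s) {
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
    max(r$lengths)
  }, numeric(1), USE.NAMES = FALSE)
}

# --- templates ------------------------------------------------------------

#' Build a masked design template around a target variant
#'
#' Extracts a window around the target wide enough for the largest
#' product plus both primers, then replaces every base covered by a
#' *neighbour* (non-target) variant with the mask character. Neighbour
#' insertions, being zero-length, mask their anchor base. Target bases are
#' never masked; a neighbour overlapping the target is an error, because
#' the target is then ambiguous.
#'
#' @param ref_seq The contig sequence.
#' @param target A one-row variant-feature tibble or named list.
#' @param neighbours Variant tibble of non-target variants (the target
#'   itself, matched by `id`, is ignored if present).
#' @param config A [design_config()].
#' @param marker_type `"CAPS"`, `"indel"` or `"HRM"`.
#' @return A list of class `design_template`: `seqid`, `sequence`,
#'   `offset` (1-based genomic position of window base 1), `target_start`
#'   / `target_end` (window-local), `masked` (window-local positions),
#'   `marker_type`, `target_id`.
#' @export
build_template <- function(ref_seq, target, neighbours = NULL,
                           config = design_config(),
                           marker_type = c("CAPS", "indel", "HRM")) {
  marker_type <- match.arg(marker_type)
  v <- as.list(target)
  n <- nchar(ref_seq)
  half <- config$product_size[[marker_type]][2] + config$primer_length[2]
  w1 <- max(1L, v$start - half)
  w2 <- min(n, v$end + half)
  seq <- substr(ref_seq, w1, w2)

  # window-local target span; insertions target the two junction bases
  t1 <- v$start - w1 + 1L
  t2 <- v$end - w1 + 1L
  if (v$vtype == "insertion") t2 <- min(nchar(seq), t1 + 1L)

  masked <- integer(0)
  if (!is.null(neighbours) && nrow(neighbours)) {
    nb <- neighbours[neighbours$seqid == v$seqid, , drop = FALSE]
    if (!is.null(v$id) && "id" %in% names(nb)) {
      nb <- nb[nb$id != v$id, , drop = FALSE]
    }
    nb <- nb[nb$end >= w1 & nb$start <= w2, , drop = FALSE]
    if (nrow(nb)) {
      if (any(nb$end >= v$start & nb$start <= v$end)) {
        stop("target '", v$id %||% "?", "' overlaps a neighbour variant: ",
             "ambiguous target", call. = FALSE)
      }
      masked <- sort(unique(unlist(purrr::map2(
        pmax(nb$start, w1) - w1 + 1L, pmin(nb$end, w2) - w1 + 1L,
        function(a, b) a:b
      ))))
      chars <- strsplit(seq, "", fixed = TRUE)[[1]]
      chars[masked] <- config$mask_char
      seq <- paste(chars, collapse = "")
    }
  }
  structure(list(seqid = v$seqid %||% NA_character_, sequence = seq,
                 offset = w1, target_start = t1, target_end = t2,
                 masked = masked, marker_type = marker_type,
                 target_id = v$id %||% NA_character_),
            class = "design_template")
}

# --- design ---------------------------------------------------------------

.empty_pairs_tbl <- function(reason = NULL) {
  out <- tibble::tibble(
    pair_id = character(), target_id = character(), marker_type = character(),
    left_seq = character(), right_seq = character(),
    left_start = integer(), left_len = integer(),
    right_start = integer(), right_len = integer(),
    product_size = integer(), tm_left = numeric(), tm_right = numeric(),
    penalty = numeric()
  )
  class(out) <- c("primer_pairs", class(out))
  attr(out, "failure_reason") <- reason
  out
}

# Enumerate acceptable oligos whose window-local span is [start, start+len-1]
# inside [lo, hi]; `rc` selects the right (reverse-strand) primer.
.enumerate_oligos <- function(seq, lo, hi, masked, config, rc) {
  cand <- list()
  if (hi - lo + 1L < config$primer_length[1]) return(NULL)
  mask_set <- masked
  for (len in seq(config$primer_length[1], config$primer_length[2])) {
    if (hi - len + 1L < lo) next
    starts <- seq.int(lo, hi - len + 1L)
    subs <- substring(seq, starts, starts + len - 1L)
    ok <- !grepl("[^ACGT]", subs)
    if (length(mask_set)) {
      hit <- vapply(starts, function(s)
        any(mask_set >= s & mask_set <= s + len - 1L), logical(1))
      ok <- ok & !hit
    }
    if (!any(ok)) next
    starts <- starts[ok]; subs <- subs[ok]
    oligo <- if (rc) dna_revcomp(subs) else subs
    gc <- .gc_percent(oligo)
    run <- .max_poly_run(oligo)
    keep <- gc >= config$gc_range[1] & gc <= config$gc_range[2] &
      run <= config$max_poly_run
    if (!any(keep)) next
    starts <- starts[keep]; oligo <- oligo[keep]
    tm <- oligo_tm(oligo)
    keep2 <- !is.na(tm) & tm >= config$tm_range[1] & tm <= config$tm_range[2]
    if (!any(keep2)) next
    cand[[length(cand) + 1L]] <- tibble::tibble(
      start = starts[keep2], len = len, seq = oligo[keep2], tm = tm[keep2],
      penalty = abs(tm[keep2] - config$tm_opt) +
        0.5 * abs(len - config$primer_opt_length)
    )
  }
  if (!length(cand)) return(NULL)
  dplyr::bind_rows(cand)
}

#' Design flanking primer pairs on a masked template
#'
#' Enumerates left primers entirely 5' of the target span and right
#' primers entirely 3' of it, rejecting any oligo that touches a masked
#' position or a non-ACGT base, is outside the length/Tm/GC windows, or
#' carries a long mononucleotide run. Candidates are paired under the
#' marker type's product-size range; pairs are scored by the sum of the
#' two oligo penalties (Tm and length deviation from optimum) plus the
#' pair Tm difference, and returned sorted by ascending penalty with ties
#' broken by leftmost left-primer start. Every returned pair is
#' revalidated against the pair invariants (product arithmetic, size
#' range, target containment, mask avoidance).
#'
#' @param template A [build_template()] result.
#' @param config A [design_config()].
#' @return A tibble of at most `config$max_pairs` pairs with window-local
#'   coordinates (`left_start` = 5' base of the left primer;
#'   `right_start` = 5' base of the right primer, i.e. the rightmost
#'   template base of the product; `product_size = right_start -
#'   left_start + 1`). When empty, attribute `failure_reason` holds a
#'   machine-readable reason (`"flanks too short"`, `"no acceptable
#'   pair"`).
#' @export
design_primers <- function(template, config = design_config()) {
  stopifnot(inherits(template, "design_template"))
  psz <- config$product_size[[template$marker_type]]
  seq <- template$sequence
  n <- nchar(seq)
  t1 <- template$target_start; t2 <- template$target_end
  min_len <- config$primer_length[1]

  # quick feasibility: smallest product that still flanks the target
  if (t1 - 1L < min_len || n - t2 < min_len ||
      (t1 - 1L) + (n - t2) + (t2 - t1 + 1L) < psz[1]) {
    return(.empty_pairs_tbl("flanks too short"))
  }

  left <- .enumerate_oligos(seq, 1L, t1 - 1L, template$masked, config,
                            rc = FALSE)
  right <- .enumerate_oligos(seq, t2 + 1L, n, template$masked, config,
                             rc = TRUE)
  if (is.null(left) || is.null(right)) {
    return(.empty_pairs_tbl("no acceptable pair"))
  }
  # keep the best candidates per side to bound the cross join
  left <- dplyr::slice_min(left, .data$penalty, n = 60L, with_ties = FALSE)
  right <- dplyr::slice_min(right, .data$penalty, n = 60L, with_ties = FALSE)

  pairs <- tidyr::crossing(
    dplyr::rename_with(left, ~ paste0("l_", .x)),
    dplyr::rename_with(right, ~ paste0("r_", .x))
  )
  pairs$right_start <- pairs$r_start + pairs$r_len - 1L
  pairs$product_size <- pairs$right_start - pairs$l_start + 1L
  pairs <- pairs[pairs$product_size >= psz[1] & pairs$product_size <= psz[2], ]
  if (!nrow(pairs)) return(.empty_pairs_tbl("no acceptable pair"))

  pairs$penalty <- pairs$l_penalty + pairs$r_penalty +
    abs(pairs$l_tm - pairs$r_tm)
  pairs <- dplyr::arrange(pairs, .data$penalty, .data$l_start,
                          .data$right_start)
  pairs <- utils::head(pairs, config$max_pairs)

  out <- tibble::tibble(
    pair_id = paste0(template$target_id %||% "target", "_",
                     seq_len(nrow(pairs))),
    target_id = template$target_id %||% NA_character_,
    marker_type = template$marker_type,
    left_seq = pairs$l_seq, right_seq = pairs$r_seq,
    left_start = as.integer(pairs$l_start), left_len = as.integer(pairs$l_len),
    right_start = as.integer(pairs$right_start),
    right_len = as.integer(pairs$r_len),
    product_size = as.integer(pairs$product_size),
    tm_left = pairs$l_tm, tm_right = pairs$r_tm,
    penalty = pairs$penalty
  )
  class(out) <- c("primer_pairs", class(out))
  .revalidate_pairs(out, template, psz)
}

# Defensive boundary: drop (with a warning) any pair violating the pair
# invariants, whatever produced it.
.revalidate_pairs <- function(pairs, template, psz) {
  if (!nrow(pairs)) return(pairs)
  l_end <- pairs$left_start + pairs$left_len - 1L
  r_lo <- pairs$right_start - pairs$right_len + 1L
  ok <- pairs$product_size == pairs$right_start - pairs$left_start + 1L &
    pairs$product_size >= psz[1] & pairs$product_size <= psz[2] &
    l_end < template$target_start & r_lo > template$target_end
  if (length(template$masked)) {
    ok <- ok & !vapply(seq_len(nrow(pairs)), function(i) {
      any((template$masked >= pairs$left_start[i] &
             template$masked <= l_end[i]) |
          (template$masked >= r_lo[i] &
             template$masked <= pairs$right_start[i]))
    }, logical(1))
  }
  if (any(!ok)) {
    warning("dropped ", sum(!ok), " pair(s) failing revalidation",
            call. = FALSE)
  }
  out <- pairs[ok, , drop = FALSE]
  if (!nrow(out)) attr(out, "failure_reason") <- "no acceptable pair"
  out
}

#' Lift designed pairs to contig coordinates as a reportable table
#'
#' @param pairs A [design_primers()] tibble (possibly several targets'
#'   worth, bound together).
#' @param templates A single `design_template` or a named list of them
#'   keyed by `target_id`, used to lift window-local coordinates.
#' @param enzyme Optional character vector (recycled) naming the CAPS
#'   enzyme assayed by each pair.
#' @return A tibble, one row per pair, with genomic 1-based coordinates
#'   `left_genomic_start` and `right_genomic_start` (the 5' base of each
#'   primer on the contig).
#' @export
primer_table <- function(pairs, templates, enzyme = NA_character_) {
  if (inherits(templates, "design_template")) {
    templates <- stats::setNames(list(templates), templates$target_id)
  }
  if (!nrow(pairs)) {
    return(dplyr::bind_cols(pairs,
      tibble::tibble(seqid = character(0), enzyme = character(0),
                     left_genomic_start = integer(0),
                     right_genomic_start = integer(0))))
  }
  off <- vapply(pairs$target_id, function(id) templates[[id]]$offset,
                integer(1))
  seqid <- vapply(pairs$target_id, function(id) templates[[id]]$seqid,
                  character(1))
  out <- pairs
  out$seqid <- unname(seqid)
  out$enzyme <- rep_len(enzyme, nrow(out))
  out$left_genomic_start <- as.integer(unname(off) + out$left_start - 1L)
  out$right_genomic_start <- as.integer(unname(off) + out$right_start - 1L)
  out
}
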