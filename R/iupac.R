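# IUPAC nucleotide alphabet: base sets and complements shared by the
# enzyme scanner, the variant parsers and the primer engine.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

#' Reverse complement of an IUPAC-degenerate pattern
#'
#' Complements every symbol under the IUPAC complement table (R<->Y, K<->M,
#' B<->V, D<->H; S, W and N are self-complementary) and reverses the string.
#' A recognition site is palindromic exactly when it equals its own IUPAC
#' reverse complement.
#'
#' @param pattern A character vector of IUPAC nucleotide strings.
#' @return A character vector of the same length.
#' @examples
#' iupac_revcomp("GANTC")  # "GANTC" (palindromic)
#' iupac_revcomp("GGATC")
#' @export
iupac_revcomp <- function(pattern) {
  stopifnot(is.character(pattern))
  vapply(pattern, function(p) {
    if (!nzchar(p)) return("")
    chars <- strsplit(toupper(p), "", fixed = TRUE)[[1]]
    comp <- IUPAC_COMPLEMENT[chars]
    if (anyNA(comp)) {
      bad <- unique(chars[is.na(comp)])
      stop("invalid IUPAC symbol(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    paste(rev(unname(comp)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Reverse complement of a plain DNA sequence
#'
#' For sequences over A, C, G, T, N (case-insensitive; N maps to N).
#'
#' @param seq A character vector of DNA strings.
#' @return A character vector of reverse complements, uppercase.
#' @export
dna_revcomp <- function(seq) {
  stopifnot(is.character(seq))
  vapply(seq, function(s) {
    if (!nzchar(s)) return("")
    chars <- rev(strsplit(toupper(s), "", fixed = TRUE)[[1]])
    paste(chartr("ACGTN", "TGCAN", chars), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Integer-code a DNA string: A=1 C=2 G=3 T=4, anything else (incl. N) NA.
# The scanner treats NA as matching no pattern symbol (conservative-N rule).
.seq_codes <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
}

# Per-position allowed-base masks (logical[4]) for an IUPAC pattern.
.pattern_masks <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  lapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (is.null(set)) stop("invalid IUPAC symbol: ", ch, call. = FALSE)
    c("A", "C", "G", "T") %in% set
  })
}

# 1-based start positions where `pattern` matches `codes` (from .seq_codes).
# Overlapping matches all reported; windows containing non-ACGT never match.
.scan_iupac <- function(codes, pattern) {
  masks <- .pattern_masks(pattern)
  m <- length(masks)
  n <- length(codes)
  if (n < m || m == 0L) return(integer(0))
  k <- n - m + 1L
  ok <- rep(TRUE, k)
  for (j in seq_len(m)) {
    v <- codes[j:(j + k - 1L)]
    allow <- masks[[j]][v]
    allow[is.na(allow)] <- FALSE
    ok <- ok & allow
  }
  which(ok)
}

.valid_dna <- function(x) grepl("^[ACGTN]+$", toupper(x))
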