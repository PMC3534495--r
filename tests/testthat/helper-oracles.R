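# Independent oracles for site scanning and primer matching. These are
# deliberately implemented with different mechanisms from the package
# (PCRE regex with lookahead; position-by-position string comparison) so
# that agreement is a real cross-check.

IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

oracle_regex <- function(site) {
  chars <- strsplit(site, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    set <- IUPAC_ORACLE[[ch]]
    if (nchar(set) == 1L) set else paste0("[", set, "]")
  }, character(1)), collapse = "")
}

oracle_revcomp_iupac <- function(site) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  chars <- strsplit(site, "", fixed = TRUE)[[1]]
  paste(rev(comp[chars]), collapse = "")
}

# Overlapping top-strand match positions of an IUPAC pattern (regex route).
oracle_match_positions <- function(seq, site) {
  m <- gregexpr(paste0("(?=", oracle_regex(site), ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

# Double-stranded site count with the palindrome collapse.
oracle_site_count <- function(seq, site) {
  rc <- oracle_revcomp_iupac(site)
  n <- length(oracle_match_positions(seq, site))
  if (rc != site) n <- n + length(oracle_match_positions(seq, rc))
  n
}

# Brute-force CAPS oracle: digest both alleles across the panel, compare
# counts, report enzyme/status differences as "Enzyme:status" strings.
oracle_caps <- function(ref_window, alt_window, panel) {
  out <- character(0)
  for (i in seq_len(nrow(panel))) {
    cr <- oracle_site_count(ref_window, panel$site[i])
    ca <- oracle_site_count(alt_window, panel$site[i])
    if (cr != ca) {
      out <- c(out, paste0(panel$name[i], ":",
                           if (ca > cr) "gained" else "lost"))
    }
  }
  out
}

# Exhaustive ungapped primer-match oracle (both strands, 3'-anchored).
oracle_match_primer <- function(primer, seq, max_mismatch, k3) {
  m <- nchar(primer)
  n <- nchar(seq)
  pr <- strsplit(primer, "", fixed = TRUE)[[1]]
  rc <- strsplit(dna_revcomp(primer), "", fixed = TRUE)[[1]]
  sq <- strsplit(seq, "", fixed = TRUE)[[1]]
  rows <- list()
  for (i in seq_len(max(0L, n - m + 1L))) {
    win <- sq[i:(i + m - 1L)]
    mmf <- sum(win != pr | !(win %in% c("A", "C", "G", "T")))
    if (mmf <= max_mismatch &&
        all(win[(m - k3 + 1L):m] == pr[(m - k3 + 1L):m])) {
      rows[[length(rows) + 1L]] <- data.frame(start = i, strand = "+",
                                              mismatches = mmf)
    }
    mmr <- sum(win != rc | !(win %in% c("A", "C", "G", "T")))
    if (mmr <= max_mismatch && all(win[1:k3] == rc[1:k3])) {
      rows[[length(rows) + 1L]] <- data.frame(start = i, strand = "-",
                                              mismatches = mmr)
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), strand = character(),
                      mismatches = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), , drop = FALSE]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
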