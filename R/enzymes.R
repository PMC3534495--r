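# Restriction enzymes with IUPAC-degenerate recognition sites, and
# double-stranded site scanning.

#' Load a restriction-enzyme panel
#'
#' With no arguments, returns the bundled default panel of six enzymes whose
#' sites survive well in PCR buffers and are the workhorses of CAPS
#' genotyping: TaqI, AluI, RsaI, DpnII, HinfI and HaeIII. Recognition
#' sequences and cut offsets follow REBASE and ship as a plain TSV in
#' `inst/extdata/restriction_enzymes.tsv`, so a custom panel is just another
#' TSV (columns `name`, `site`, optional `cut_offset`).
#'
#' @param config `NULL` for the default panel, a path to a TSV file, or a
#'   data frame with columns `name`, `site` and optionally `cut_offset`
#'   (0-based cut position within the site on the top strand).
#' @return A tibble of class `enzyme_panel` with columns `name`, `site`,
#'   `cut_offset` and the derived `palindromic` (site equals its IUPAC
#'   reverse complement).
#' @examples
#' load_panel()
#' load_panel(data.frame(name = "EcoRI", site = "GAATTC", cut_offset = 1))
#' @export
load_panel <- function(config = NULL) {
  if (is.null(config)) {
    config <- system.file("extdata", "restriction_enzymes.tsv",
                          package = "capsmark", mustWork = TRUE)
  }
  tab <- if (is.character(config)) {
    readr::read_tsv(config, col_types = readr::cols(
      name = readr::col_character(),
      site = readr::col_character(),
      .default = readr::col_integer()
    ), progress = FALSE)
  } else {
    tibble::as_tibble(config)
  }
  if (!all(c("name", "site") %in% names(tab))) {
    stop("enzyme table needs columns 'name' and 'site'", call. = FALSE)
  }
  if (!("cut_offset" %in% names(tab))) tab$cut_offset <- NA_integer_
  tab$site <- toupper(tab$site)

  dup <- tab$name[duplicated(tab$name)]
  if (length(dup)) {
    stop("duplicate enzyme name(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(tab))) {
    chars <- strsplit(tab$site[i], "", fixed = TRUE)[[1]]
    bad <- setdiff(chars, names(IUPAC_SETS))
    if (length(bad)) {
      stop("enzyme ", tab$name[i], ": invalid IUPAC character(s) ",
           paste(unique(bad), collapse = ", "), " in site ", tab$site[i],
           call. = FALSE)
    }
    if (nchar(tab$site[i]) < 3L) {
      stop("enzyme ", tab$name[i], ": site shorter than 3 bases", call. = FALSE)
    }
  }
  out <- tibble::tibble(
    name = tab$name,
    site = tab$site,
    cut_offset = as.integer(tab$cut_offset),
    palindromic = tab$site == iupac_revcomp(tab$site)
  )
  class(out) <- c("enzyme_panel", class(out))
  out
}

#' Find restriction sites on both strands
#'
#' Scans a DNA sequence for matches to an enzyme's IUPAC-degenerate
#' recognition site. Top-strand matches are reported on `+`; windows
#' matching the reverse complement of the site are reported on `-`, both
#' with the 1-based start of the matched window on the top strand. For
#' palindromic enzymes the two strand hits at a locus are one physical site
#' and are collapsed to a single `+` record. Overlapping matches are all
#' reported. An `N` (or any non-ACGT symbol) in the sequence matches no
#' pattern symbol, so ambiguous reference bases never produce sites.
#'
#' @param seq A single DNA string over A, C, G, T, N.
#' @param enzyme One row of an [load_panel()] panel (or any list/row with
#'   `site`, and optionally `name`), or a bare IUPAC site string.
#' @return A tibble with columns `position` (integer, 1-based top-strand
#'   start) and `strand` (`"+"`/`"-"`), sorted by position.
#' @examples
#' find_sites("GGGTCGAGGG", "TCGA")     # one TaqI site at 4
#' find_sites("AAGACTCAA", "GANTC")     # GACTC matches the degenerate site
#' @export
find_sites <- function(seq, enzyme) {
  site <- if (is.character(enzyme) && length(enzyme) == 1L) enzyme else enzyme$site
  site <- toupper(site)
  codes <- .seq_codes(seq)
  fwd <- .scan_iupac(codes, site)
  rcs <- iupac_revcomp(site)
  if (site == rcs) {
    return(tibble::tibble(position = as.integer(fwd),
                          strand = rep("+", length(fwd))))
  }
  rev <- .scan_iupac(codes, rcs)
  out <- tibble::tibble(
    position = as.integer(c(fwd, rev)),
    strand = c(rep("+", length(fwd)), rep("-", length(rev)))
  )
  dplyr::arrange(out, .data$position, .data$strand)
}

# Site count only; shares semantics with find_sites but skips tibble
# construction on the hot path of CAPS scanning.
.count_sites <- function(codes, site, palindromic, rc_site) {
  n <- length(.scan_iupac(codes, site))
  if (!palindromic) n <- n + length(.scan_iupac(codes, rc_site))
  n
}
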