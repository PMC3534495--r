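# Variant IO: VCF and Roche gsMapper 454HCDiffs/454AllDiffs readers, a
# GFF3/GVF writer-reader pair, and coordinate interconversion with the
# 0-based half-open interval convention.
#
# The variant-feature model (one row per tibble):
#   seqid       reference sequence name
#   source      provenance free text ("vcf", "gsMapper", ...)
#   vtype       "SNV", "insertion" or "deletion"
#   start, end  1-based inclusive GFF3 coordinates; SNV: start == end;
#               deletion: the deleted bases; insertion: zero-length
#               convention, start == end == the base 5' of the insertion
#   ref_allele  bases over ACGTN, or "-" for insertions
#   alt_allele  bases over ACGTN, or "-" for deletions
#   id          unique feature identifier

# --- line streaming -------------------------------------------------------

# Turn `input` into a connection: an open connection is used as-is, "-" is
# stdin, an existing file path is opened, anything else is treated as text
# (a vector of lines, or strings containing newlines).
.open_lines <- function(input) {
  if (inherits(input, "connection")) {
    return(list(con = input, close = FALSE))
  }
  stopifnot(is.character(input))
  if (length(input) == 1L && input == "-") {
    return(list(con = file("stdin"), close = TRUE))
  }
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input)) {
    return(list(con = file(input, open = "rt"), close = TRUE))
  }
  txt <- paste(input, collapse = "\n")
  list(con = textConnection(txt), close = TRUE)
}

# Single-pass driver: feeds `fun(line, line_number)` one line at a time
# without ever holding the whole file.
.stream_lines <- function(input, fun, chunk_size = 4096L) {
  src <- .open_lines(input)
  if (src$close) on.exit(close(src$con), add = TRUE)
  if (!isOpen(src$con)) {
    open(src$con, open = "rt")
  }
  lineno <- 0L
  repeat {
    lines <- readLines(src$con, n = chunk_size, warn = FALSE)
    if (!length(lines)) break
    for (ln in lines) {
      lineno <- lineno + 1L
      fun(ln, lineno)
    }
  }
  invisible(lineno)
}

.new_variant_collector <- function() {
  rows <- list()
  list(
    add = function(row) rows[[length(rows) + 1L]] <<- row,
    result = function() {
      if (!length(rows)) {
        return(tibble::tibble(
          seqid = character(), source = character(), vtype = character(),
          start = integer(), end = integer(),
          ref_allele = character(), alt_allele = character(), id = character()
        ))
      }
      dplyr::bind_rows(rows)
    }
  )
}

# --- VCF ------------------------------------------------------------------

#' Read variant calls from VCF into variant features
#'
#' Streams a VCF site by site (header and FORMAT/sample columns are
#' ignored) and emits one variant feature per ALT allele, converted to the
#' GFF3/GVF coordinate convention: the shared leading anchor base of an
#' indel record is trimmed, deletions sit on the deleted bases, and
#' insertions become zero-length features anchored on the base 5' of the
#' inserted sequence. Multi-allelic records yield one feature per ALT with
#' `_1`, `_2`, ... id suffixes.
#'
#' Records whose REF or ALT contains symbols outside A/C/G/T/N (or whose
#' shape fits neither an SNV nor a pure anchor-base indel) are skipped and
#' counted; the count is reported as a warning and in the `n_skipped`
#' attribute. Structural problems (wrong column count, non-integer POS)
#' are errors naming the offending line.
#'
#' @param input A file path, `"-"` for stdin, an open connection, or VCF
#'   text (a character vector of lines).
#' @return A tibble of variant features (see package docs for columns),
#'   with attribute `n_skipped`.
#' @examples
#' v <- read_vcf_variants(c("##fileformat=VCFv4.2",
#'   "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
#'   "chr1\t100\t.\tA\tG\t.\t.\t."))
#' @export
read_vcf_variants <- function(input) {
  coll <- .new_variant_collector()
  skipped <- 0L
  .stream_lines(input, function(ln, lineno) {
    if (!nzchar(ln) || startsWith(ln, "#")) return(invisible())
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L) {
      stop("VCF parse error at line ", lineno, ": expected >= 8 tab-separated",
           " columns, got ", length(f), call. = FALSE)
    }
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos) || f[2] != as.character(pos)) {
      stop("VCF parse error at line ", lineno, ": non-integer POS '", f[2],
           "'", call. = FALSE)
    }
    ref <- toupper(f[4])
    alts <- strsplit(toupper(f[5]), ",", fixed = TRUE)[[1]]
    base_id <- if (f[3] %in% c(".", "")) paste0(f[1], "_", pos) else f[3]
    multi <- length(alts) > 1L
    for (k in seq_along(alts)) {
      alt <- alts[k]
      id <- if (multi) paste0(base_id, "_", k) else base_id
      feat <- .vcf_allele_to_feature(f[1], pos, ref, alt, id)
      if (is.null(feat)) skipped <<- skipped + 1L else coll$add(feat)
    }
  })
  out <- coll$result()
  if (skipped > 0L) {
    warning("skipped ", skipped, " VCF allele record(s) with non-ACGTN or ",
            "complex alleles", call. = FALSE)
  }
  attr(out, "n_skipped") <- skipped
  out
}

# One VCF (POS, REF, ALT) allele -> feature row, or NULL to skip.
.vcf_allele_to_feature <- function(seqid, pos, ref, alt, id) {
  if (!.valid_dna(ref) || !.valid_dna(alt)) return(NULL)
  if (ref == alt) return(NULL)
  if (nchar(ref) == 1L && nchar(alt) == 1L) {
    return(tibble::tibble(seqid = seqid, source = "vcf", vtype = "SNV",
                          start = pos, end = pos,
                          ref_allele = ref, alt_allele = alt, id = id))
  }
  # indel with shared leading anchor base
  if (substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    if (nchar(alt) == 1L && nchar(ref) > 1L) {        # deletion
      del <- substr(ref, 2L, nchar(ref))
      return(tibble::tibble(seqid = seqid, source = "vcf", vtype = "deletion",
                            start = pos + 1L, end = pos + nchar(ref) - 1L,
                            ref_allele = del, alt_allele = "-", id = id))
    }
    if (nchar(ref) == 1L && nchar(alt) > 1L) {        # insertion
      ins <- substr(alt, 2L, nchar(alt))
      return(tibble::tibble(seqid = seqid, source = "vcf", vtype = "insertion",
                            start = pos, end = pos,
                            ref_allele = "-", alt_allele = ins, id = id))
    }
  }
  NULL  # complex substitution: no representation in this model
}

# --- gsMapper 454HCDiffs / 454AllDiffs ------------------------------------

#' Read Roche gsMapper 454HCDiffs/454AllDiffs variant tables
#'
#' Parses the tabular dialect written by gsMapper: a comment/header block,
#' then one row per variant starting with `>`, with whitespace-separated
#' columns (reference accession, start, end, reference bases, variant
#' bases, then version-dependent depth/frequency columns). `-` in the
#' reference column signals an insertion, `-` in the variant column a
#' deletion. Trailing columns beyond the first five are tolerated; when
#' the first two look like a read depth and a percent frequency they are
#' carried into `depth` and `var_freq`.
#'
#' @param input A file path, `"-"`, an open connection, or text lines.
#' @return A tibble of variant features with extra columns `depth` and
#'   `var_freq` (NA when absent), and attribute `n_skipped`.
#' @export
read_gsmapper_variants <- function(input) {
  coll <- .new_variant_collector()
  skipped <- 0L
  .stream_lines(input, function(ln, lineno) {
    if (!startsWith(ln, ">")) return(invisible())
    f <- strsplit(sub("^>", "", trimws(ln)), "[ \t]+")[[1]]
    if (length(f) < 5L) {
      stop("gsMapper parse error at line ", lineno,
           ": expected >= 5 columns after '>', got ", length(f), call. = FALSE)
    }
    if (toupper(f[2]) == "START") return(invisible())  # column header row
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      stop("gsMapper parse error at line ", lineno,
           ": non-numeric start/end ('", f[2], "', '", f[3], "')",
           call. = FALSE)
    }
    ref <- toupper(f[4]); alt <- toupper(f[5])
    depth <- NA_integer_; freq <- NA_real_
    if (length(f) >= 6L) depth <- suppressWarnings(as.integer(f[6]))
    if (length(f) >= 7L) {
      freq <- suppressWarnings(as.numeric(sub("%$", "", f[7])))
    }
    id <- paste0(f[1], "_", start)
    feat <- NULL
    if (ref == "-" && .valid_dna(alt)) {
      feat <- tibble::tibble(seqid = f[1], source = "gsMapper",
                             vtype = "insertion", start = start, end = start,
                             ref_allele = "-", alt_allele = alt, id = id)
    } else if (alt == "-" && .valid_dna(ref)) {
      feat <- tibble::tibble(seqid = f[1], source = "gsMapper",
                             vtype = "deletion", start = start, end = end,
                             ref_allele = ref, alt_allele = "-", id = id)
    } else if (nchar(ref) == 1L && nchar(alt) == 1L &&
               .valid_dna(ref) && .valid_dna(alt) && ref != alt) {
      feat <- tibble::tibble(seqid = f[1], source = "gsMapper", vtype = "SNV",
                             start = start, end = start,
                             ref_allele = ref, alt_allele = alt, id = id)
    }
    if (is.null(feat)) {
      skipped <<- skipped + 1L
    } else {
      feat$depth <- depth
      feat$var_freq <- freq
      coll$add(feat)
    }
  })
  out <- coll$result()
  if (!("depth" %in% names(out))) {
    out$depth <- integer(0); out$var_freq <- numeric(0)
  }
  if (skipped > 0L) {
    warning("skipped ", skipped, " gsMapper row(s) that fit no variant class",
            call. = FALSE)
  }
  attr(out, "n_skipped") <- skipped
  out
}

# --- validation -----------------------------------------------------------

#' Validate variant features against the model invariants
#'
#' Checks, per row: coordinate ordering; SNVs are single-base with
#' start == end; insertions are zero-length with `ref_allele == "-"`;
#' deletion span equals the deleted allele length; ref and alt differ.
#'
#' @param variants A variant-feature tibble.
#' @return The input, invisibly; errors name the offending feature id.
#' @export
validate_variants <- function(variants) {
  req <- c("seqid", "vtype", "start", "end", "ref_allele", "alt_allele", "id")
  miss <- setdiff(req, names(variants))
  if (length(miss)) {
    stop("variant table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    bad <- function(msg) stop("invalid variant '", v$id, "': ", msg,
                              call. = FALSE)
    if (v$start < 1L || v$end < v$start) bad("bad coordinates")
    if (identical(v$ref_allele, v$alt_allele)) bad("ref equals alt")
    switch(v$vtype,
      SNV = {
        if (v$start != v$end) bad("SNV with start != end")
        if (nchar(v$ref_allele) != 1L || nchar(v$alt_allele) != 1L)
          bad("SNV alleles must be single bases")
      },
      insertion = {
        if (v$start != v$end) bad("insertion must be zero-length (start == end)")
        if (v$ref_allele != "-") bad("insertion ref allele must be '-'")
        if (!nzchar(v$alt_allele) || v$alt_allele == "-")
          bad("insertion alt allele empty")
      },
      deletion = {
        if (v$alt_allele != "-") bad("deletion alt allele must be '-'")
        if (v$end - v$start + 1L != nchar(v$ref_allele))
          bad("deletion span does not match allele length")
      },
      bad(paste0("unknown vtype '", v$vtype, "'"))
    )
  }
  invisible(variants)
}

# --- GFF3 / GVF -----------------------------------------------------------

#' Write variant features as GFF3 with GVF allele attributes
#'
#' Emits a `##gff-version 3` pragma then one 9-column record per feature,
#' 1-based inclusive, with alleles in GVF-style `Reference_seq=` /
#' `Variant_seq=` attributes. Output order equals input order.
#'
#' @param variants A variant-feature tibble (validated before writing;
#'   invariant violations are errors naming the feature id).
#' @param path Output file path or connection; `"-"` writes to stdout.
#' @param comments Optional character vector written as `#` comment lines
#'   after the version pragma (used for provenance headers).
#' @return The number of records written.
#' @export
write_variant_gff3 <- function(variants, path, comments = NULL) {
  validate_variants(variants)
  src <- if ("source" %in% names(variants)) variants$source else
    rep("capsmark", nrow(variants))
  lines <- c("##gff-version 3",
    if (length(comments)) paste0("# ", comments),
    if (nrow(variants)) paste(
      variants$seqid, src, variants$vtype,
      variants$start, variants$end, ".", ".", ".",
      paste0("ID=", variants$id,
             ";Reference_seq=", variants$ref_allele,
             ";Variant_seq=", variants$alt_allele),
      sep = "\t"))
  if (inherits(path, "connection")) {
    writeLines(lines, path)
  } else if (identical(path, "-")) {
    writeLines(lines)
  } else {
    writeLines(lines, path)
  }
  nrow(variants)
}

#' Read GFF3/GVF variant features written by [write_variant_gff3()]
#'
#' @param input A file path, `"-"`, an open connection, or text lines.
#' @return A variant-feature tibble.
#' @export
read_variant_gff3 <- function(input) {
  coll <- .new_variant_collector()
  .stream_lines(input, function(ln, lineno) {
    if (!nzchar(ln) || startsWith(ln, "#")) return(invisible())
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L) {
      stop("GFF3 parse error at line ", lineno, ": expected 9 columns, got ",
           length(f), call. = FALSE)
    }
    attrs <- .parse_gff3_attrs(f[9])
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end)) {
      stop("GFF3 parse error at line ", lineno, ": non-integer coordinates",
           call. = FALSE)
    }
    coll$add(tibble::tibble(
      seqid = f[1], source = f[2], vtype = f[3],
      start = start, end = end,
      ref_allele = attrs[["Reference_seq"]] %||% NA_character_,
      alt_allele = attrs[["Variant_seq"]] %||% NA_character_,
      id = attrs[["ID"]] %||% paste0(f[1], "_", f[4])
    ))
  })
  coll$result()
}

.parse_gff3_attrs <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  out <- lapply(kv, function(x) if (length(x) >= 2L) x[2] else NA_character_)
  names(out) <- vapply(kv, `[`, character(1), 1L)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- interval conversion --------------------------------------------------

#' Convert variant features to 0-based half-open interval records
#'
#' Maps GFF3 1-based inclusive coordinates to the Galaxy/BED interval
#' convention (0-based start, exclusive end), preserving length. Zero-length
#' insertion features map to zero-length intervals with `start == end` at
#' the 1-based anchor coordinate, so that the round trip through
#' [interval_to_gff3()] is the identity.
#'
#' @param variants A variant-feature tibble (needs `vtype` to recognise
#'   zero-length insertions).
#' @return A tibble with `seqid`, `start` (0-based), `end` (exclusive),
#'   `name`, `strand` (always `"."`), `zero_length`.
#' @export
gff3_to_interval <- function(variants) {
  if (any(variants$start < 1L | variants$end < 1L)) {
    stop("negative or zero GFF3 coordinates", call. = FALSE)
  }
  zl <- variants$vtype == "insertion"
  tibble::tibble(
    seqid = variants$seqid,
    start = as.integer(ifelse(zl, variants$start, variants$start - 1L)),
    end = as.integer(variants$end),
    name = variants$id,
    strand = ".",
    zero_length = zl
  )
}

#' Convert 0-based half-open interval records back to GFF3 coordinates
#'
#' Zero-length intervals (`start == end`) become zero-length GFF3 features
#' with `start == end` at the interval coordinate (the insertion
#' convention); ordinary intervals map to `(start + 1, end)`.
#'
#' @param intervals A tibble with 0-based `start` and exclusive `end`
#'   (negative coordinates are errors), plus optional `seqid`/`name`.
#' @return A tibble with 1-based inclusive `start`/`end` and `zero_length`.
#' @export
interval_to_gff3 <- function(intervals) {
  if (any(intervals$start < 0L | intervals$end < 0L)) {
    stop("negative interval coordinates", call. = FALSE)
  }
  if (any(intervals$end < intervals$start)) {
    stop("interval end precedes start", call. = FALSE)
  }
  zl <- intervals$start == intervals$end
  out <- tibble::tibble(
    start = as.integer(ifelse(zl, intervals$start, intervals$start + 1L)),
    end = as.integer(ifelse(zl, intervals$start, intervals$end)),
    zero_length = zl
  )
  if ("seqid" %in% names(intervals)) out <- dplyr::bind_cols(
    tibble::tibble(seqid = intervals$seqid), out)
  if ("name" %in% names(intervals)) out$name <- intervals$name
  out
}
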