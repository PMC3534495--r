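# End-to-end marker-design workflow: convert -> detect -> filter ->
# design -> electronic PCR, with flat TSV/GFF3 artifacts carrying
# provenance headers, plus generic table filtering.

#' Workflow configuration
#'
#' Bundles the paths and parameters of one [run_caps_workflow()] run. Two
#' entry points share all downstream stages: variant calls may come as
#' VCF (Illumina-style pipelines) or as gsMapper 454HCDiffs/454AllDiffs
#' tables (454 pipelines); `variant_format = "auto"` decides by file
#' extension (`.vcf` / `.txt` vs `.gff3`/`.gvf`).
#'
#' @param reference FASTA path of the reference contigs.
#' @param variants Path to the variant calls.
#' @param out_dir Output directory (created at run time).
#' @param variant_format `"auto"`, `"vcf"`, `"gsmapper"` or `"gff3"`.
#' @param panel Optional enzyme panel TSV path or data frame; default the
#'   bundled six-enzyme panel.
#' @param flank Detection window half-width (default 50).
#' @param marker_type `"CAPS"`, `"indel"` or `"HRM"`.
#' @param design A [design_config()].
#' @param max_mismatch,three_prime_exact,max_product Electronic-PCR
#'   thresholds, see [epcr()].
#' @param seed Integer seed recorded in output provenance (default 42).
#' @return A list of class `run_config`.
#' @export
workflow_config <- function(reference, variants, out_dir,
                            variant_format = c("auto", "vcf", "gsmapper",
                                               "gff3"),
                            panel = NULL, flank = 50L,
                            marker_type = c("CAPS", "indel", "HRM"),
                            design = design_config(),
                            max_mismatch = 0L, three_prime_exact = 3L,
                            max_product = 2000L, seed = 42L) {
  structure(list(reference = reference, variants = variants,
                 out_dir = out_dir,
                 variant_format = match.arg(variant_format),
                 panel = panel, flank = as.integer(flank),
                 marker_type = match.arg(marker_type), design = design,
                 max_mismatch = as.integer(max_mismatch),
                 three_prime_exact = as.integer(three_prime_exact),
                 max_product = as.integer(max_product),
                 seed = as.integer(seed)),
            class = "run_config")
}

.provenance <- function(config, stage, inputs) {
  c(paste0("capsmark ", as.character(utils::packageVersion("capsmark"))),
    paste0("stage: ", stage),
    paste0("seed: ", config$seed),
    paste0("reference: ", config$reference),
    paste0("variants: ", config$variants),
    paste0("flank: ", config$flank),
    paste0("marker_type: ", config$marker_type),
    paste0("inputs: ", inputs))
}

.write_tsv_provenance <- function(tbl, path, prov) {
  body <- sub("\n$", "", readr::format_tsv(tbl))
  writeLines(c(paste0("# ", prov), strsplit(body, "\n", fixed = TRUE)[[1]]),
             path)
  invisible(path)
}

#' Run the full marker-design workflow
#'
#' Executes the five stages in order — convert the variant calls to
#' GFF3/GVF features, detect CAPS candidates against the enzyme panel,
#' filter targets for the requested marker type (HRM keeps class I/II
#' SNVs; indel keeps indels; CAPS keeps variants with at least one
#' candidate enzyme), design masked flanking primer pairs, and validate
#' them by electronic PCR against the reference — writing one flat
#' artifact per stage into `out_dir`, each with a provenance header
#' (package version, seed, inputs, parameters). A failing stage aborts
#' with the stage name; re-running the same configuration reproduces
#' byte-identical candidate and primer tables.
#'
#' @param config A [workflow_config()].
#' @return Invisibly, a list with the artifact `paths` (`variants_gff3`,
#'   `candidates`, `primers`, `epcr`, `log`), the stage tibbles, and the
#'   per-stage record counts.
#' @export
run_caps_workflow <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$reference, config$variants)) {
    if (!file.exists(p)) stop("input path does not exist: ", p, call. = FALSE)
  }
  panel <- load_panel(config$panel)
  ref <- .as_ref_seqs(config$reference)
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir,
                                              recursive = TRUE)
  paths <- list(
    variants_gff3 = file.path(config$out_dir, "variants.gff3"),
    candidates = file.path(config$out_dir, "candidates.tsv"),
    primers = file.path(config$out_dir, "primers.tsv"),
    epcr = file.path(config$out_dir, "epcr.tsv"),
    log = file.path(config$out_dir, "run.log"))
  log_lines <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("workflow stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # convert
  fmt <- config$variant_format
  if (fmt == "auto") {
    fmt <- if (grepl("\\.vcf$", config$variants, ignore.case = TRUE)) "vcf"
      else if (grepl("\\.(gff3?|gvf)$", config$variants,
                     ignore.case = TRUE)) "gff3"
      else "gsmapper"
  }
  variants <- stage("convert", switch(fmt,
    vcf = read_vcf_variants(config$variants),
    gsmapper = read_gsmapper_variants(config$variants),
    gff3 = read_variant_gff3(config$variants)))
  stage("convert", write_variant_gff3(
    variants, paths$variants_gff3,
    comments = .provenance(config, "convert", fmt)))
  log_lines <- c(log_lines, sprintf(
    "stage convert: format=%s in=%s out=%d features", fmt, config$variants,
    nrow(variants)))

  # detect
  scan <- stage("detect",
                scan_variants(ref, variants, panel, config$flank))
  cand <- candidates_to_table(scan)
  .write_tsv_provenance(cand, paths$candidates,
                        .provenance(config, "detect", "variants.gff3"))
  g <- glance(scan)
  log_lines <- c(log_lines, sprintf(
    "stage detect: variants=%d skipped_n=%d candidates=%d",
    g$variants_seen, g$variants_skipped_n, g$candidates))

  # filter: choose design targets for the marker type
  targets <- stage("filter", switch(config$marker_type,
    CAPS = variants[variants$id %in% cand$variant_id, , drop = FALSE],
    indel = variants[variants$vtype %in% c("insertion", "deletion"), ,
                     drop = FALSE],
    HRM = filter_hrm_targets(variants)))
  log_lines <- c(log_lines, sprintf(
    "stage filter: marker_type=%s targets=%d of %d variants",
    config$marker_type, nrow(targets), nrow(variants)))

  # design
  primers <- stage("design", {
    out <- vector("list", nrow(targets))
    for (i in seq_len(nrow(targets))) {
      tgt <- targets[i, ]
      tpl <- build_template(ref[[tgt$seqid]], tgt, neighbours = variants,
                            config = config$design,
                            marker_type = config$marker_type)
      pp <- design_primers(tpl, config$design)
      if (nrow(pp)) {
        enz <- if (config$marker_type == "CAPS") {
          paste(sort(unique(cand$enzyme[cand$variant_id == tgt$id])),
                collapse = ";")
        } else NA_character_
        out[[i]] <- primer_table(pp, tpl, enzyme = enz)
      }
    }
    dplyr::bind_rows(out)
  })
  if (!nrow(primers)) {
    primers <- primer_table(.empty_pairs_tbl(), list())
  }
  .write_tsv_provenance(primers, paths$primers,
                        .provenance(config, "design", "candidates.tsv"))
  log_lines <- c(log_lines, sprintf(
    "stage design: targets=%d pairs=%d", nrow(targets), nrow(primers)))

  # electronic PCR validation
  hits <- stage("epcr", epcr(primers, ref,
                             max_mismatch = config$max_mismatch,
                             three_prime_exact = config$three_prime_exact,
                             max_product = config$max_product))
  .write_tsv_provenance(tidy(hits), paths$epcr,
                        .provenance(config, "epcr", "primers.tsv"))
  spec_tab <- glance(hits)
  log_lines <- c(log_lines, sprintf(
    "stage epcr: pairs=%d hits=%d specific=%d nonspecific=%d nohit=%d",
    nrow(spec_tab), nrow(hits), sum(spec_tab$specific),
    sum(spec_tab$n_hits > 1L), sum(spec_tab$n_hits == 0L)))

  writeLines(c(paste0("# ", .provenance(config, "run", "all")), log_lines),
             paths$log)
  invisible(list(paths = paths, variants = variants, candidates = cand,
                 targets = targets, primers = primers, epcr = hits,
                 log = log_lines))
}

#' Filter a stage table by named-column predicates
#'
#' Row-wise filtering of candidate/primer tables with a declarative spec:
#' a scalar means equality, a length-2 numeric vector means an inclusive
#' range. Row order is preserved; an empty spec is the identity.
#'
#' @param rows A tibble (e.g. candidates or primers).
#' @param ... Named predicates, e.g. `enzyme = "TaqI"`,
#'   `confounded = FALSE`, `product_size = c(90, 120)`.
#' @return The retained rows, original order.
#' @examples
#' \dontrun{filter_table(cand, enzyme = "TaqI", confounded = FALSE)}
#' @export
filter_table <- function(rows, ...) {
  spec <- list(...)
  if (!length(spec)) return(rows)
  bad <- setdiff(names(spec), names(rows))
  if (length(bad) || is.null(names(spec)) || any(names(spec) == "")) {
    stop("unknown column(s): ", paste(bad, collapse = ", "),
         "; valid columns: ", paste(names(rows), collapse = ", "),
         call. = FALSE)
  }
  keep <- rep(TRUE, nrow(rows))
  for (col in names(spec)) {
    v <- spec[[col]]
    keep <- keep & if (is.numeric(v) && length(v) == 2L) {
      rows[[col]] >= v[1] & rows[[col]] <= v[2]
    } else {
      rows[[col]] == v
    }
  }
  rows[keep & !is.na(keep), , drop = FALSE]
}
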