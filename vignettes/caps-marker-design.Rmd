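---
title: "Designing CAPS, indel and HRM markers from sequence variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing CAPS, indel and HRM markers from sequence variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Genotyping labs working on under-resourced species — the motivating case
is bulb onion, a crop with a 10–20 Gbp unsequenced genome where variant
discovery happens on transcriptome contigs a few hundred bases long —
need to convert bulk variant calls into assays runnable with a
thermocycler, a gel rig, or a melt-curve instrument. Three marker
classes fit that constraint, and `capsmark` designs all three:

* **CAPS**: a variant that changes the digestibility of a small PCR
  product. The computable core is deciding, for each (variant, enzyme)
  pair, whether the two alleles carry different numbers of recognition
  sites near the variant.
* **Indel**: a short length polymorphism; design reduces to tight
  flanking primers so the allele size difference is resolvable.
* **HRM**: SNPs genotyped by amplicon melting. Only substitution classes
  I (C/T, G/A) and II (C/A, G/T) shift the melt curve enough to score
  reliably in small amplicons; class III (C/G) and IV (A/T) swaps are
  near-isothermal and are filtered out before design.

### CAPS detection

For variant $v$ on contig $S$ with 1-based inclusive coordinates
$[s, e]$, the detector extracts $W = S[s-f \,..\, e+f]$ with flank
$f$ (default 50 bp), builds the alternate window $W'$ by applying the
allele edit, and for each panel enzyme counts double-stranded matches of
the IUPAC-degenerate recognition site in $W$ and $W'$. A candidate is
emitted iff the counts differ; the status is *gained* when the alternate
allele carries more sites.

Three deliberate semantics:

* **Counts, not positions.** For SNVs, count and position comparison
  coincide. For indels they do not: a 2 bp deletion downstream of a TaqI
  site translates the site without changing digestibility, and a
  positional comparison would flag it as a (false) polymorphism. Count
  comparison is silent exactly when both alleles digest identically.
* **Conservative N.** A sequence `N` (or any non-ACGT symbol) matches no
  pattern symbol, including pattern `N`. Ambiguity codes in NGS
  references would otherwise manufacture phantom site losses.
* **One variant at a time.** Other variants inside the window are *not*
  applied to the alternate window — phase between nearby site-level
  calls is unknown — but their presence sets a `confounded` flag so
  downstream filtering can drop or deprioritise those candidates.
  Windows clipped at contig ends are processed and flagged `clipped`
  rather than skipped, because transcriptome contigs are short and
  skipping would silently lose targets.

The default panel (TaqI, AluI, RsaI, DpnII, HinfI, HaeIII) covers the
enzymes that digest reliably in PCR buffer without cleanup, which is
what makes CAPS a one-tube-plus-gel assay. Recognition sequences follow
REBASE and ship as `inst/extdata/restriction_enzymes.tsv`; user panels
are the same three-column TSV. The flank default of 50 bp comfortably
exceeds the longest bundled site minus one (the theoretical minimum for
a site to overlap the edit) and catches junction sites created by
multi-base indels.

### Masked primer design

`build_template()` cuts a window around the target wide enough for the
largest allowed product plus a primer at either end, and replaces every
*other* known variant position with `N`. Masking matters because a
primer sitting on a segregating site amplifies genotypes unevenly and
can silently drop alleles. The engine then:

1. enumerates left primers wholly 5' of the target and right primers
   wholly 3' of it, rejecting oligos that touch a masked position or
   non-ACGT base, fall outside the length (18–30 nt, optimum 21), Tm
   (52–65 °C, optimum 59) or GC (20–80 %) windows, or contain a
   mononucleotide run longer than 4;
2. pairs them under the marker type's product-size range — CAPS
   90–120 bp, indel and HRM 60–100 bp, all overridable in
   `design_config()`;
3. scores each pair as
   $\mathrm{penalty} = \sum_{\text{oligo}} \left(|T_m - T_m^{opt}| +
   0.5\,|\ell - \ell^{opt}|\right) + |T_m^{left} - T_m^{right}|$
   and returns the best `max_pairs` (default 5) sorted by ascending
   penalty, ties broken by leftmost left-primer start — a total order,
   so identical inputs always return identical pairs;
4. revalidates every returned pair against the pair invariants (product
   arithmetic, size range, target strictly inside the product, masks
   untouched) and drops violators with a warning — a defensive boundary
   so downstream stages never see a malformed pair.

Melting temperatures use the two-state nearest-neighbour model with the
SantaLucia (1998) unified stacking parameters, terminal initiation
terms, the monovalent-salt entropy correction
$\Delta S' = \Delta S + 0.368\,(n-1)\ln[\mathrm{Na}^+]$ at 50 mM, and
$T_m = \Delta H / (\Delta S' + R \ln(C_T/4))$ at $C_T = 50$ nM. The
$C_T/4$ convention runs ~1.9 °C below implementations that use
$\ln C_T$; the Tm *range* defaults were chosen with that in mind. The
engine is authored in-package (enumeration plus NN thermodynamics is
small and fully testable) and deliberately does not model hairpins,
self-dimers or cross-dimers — at 60–120 bp products with penalty-ranked
candidates this is rarely limiting, but it is a known simplification.

The amplicon-size defaults are small on purpose: CAPS digests resolve
cleanly on high-percentage agarose when the uncut product is ~100 bp,
and HRM melt shifts scale inversely with amplicon size. They are
config values, not assumptions baked into the code.

### Electronic PCR

`epcr()` models productive priming as *ungapped* alignment with at most
`max_mismatch` mismatches (default 0) and zero mismatches in the
3'-terminal `three_prime_exact` bases (default 3) — polymerase
extension, not hybridisation, is the gatekeeper, and 3' mismatches
abolish it while internal ones often do not. Indel-tolerant matching is
deliberately confined to `map_primers()` (Biostrings-backed, total
edits ≤ 2 by default), the "where could this oligo anneal at all"
question. Convergent forward/reverse match combinations within
`max_product` (default 2000 bp) become predicted amplicons; per-pair
hit counts drive the specificity screen (0 hits = failed assay, >1 =
multi-locus). `parse_amplimer_report()` additionally reads the
primersearch-style amplimer block dialect, so externally produced ePCR
reports can enter the same tables; its reverse-strand coordinate is
kept as the parsed 3'-offset because the report does not carry sequence
lengths.

## The synthetic fixture generator

`generate_fixture()` emulates the discovery setting the package is
built for: a few kilobase-scale contigs (defaults: 6 × 2.4 kb, uniform
base composition), 60 planted variants, half of them constructed to
create or destroy one panel enzyme's site (embed a concrete site
realisation, flip one of its bases), the rest verified to leave every
panel enzyme's digest unchanged; a slice of the neutral variants are
1–3 bp indels. Every planted variant's full expected (enzyme, status)
set is verified at generation time by a regex-based brute-force digest
— code independent of the scanner used by detection, so the truth table
is a genuine oracle rather than a restatement of the implementation.
Variants are spaced ≥ 150 bp so detection windows are independent;
`n_neighbours` plants additional digest-neutral SNVs 15–45 bp from
chosen targets to exercise confounding flags and primer masking.

What the generator does *not* emulate — and therefore what passing
tests do not show about real data: non-uniform base composition and
repeats (real transcriptomes contain paralogues that make primers
multi-locus; the specificity screen exists precisely because synthetic
uniqueness is optimistic), sequencing and assembly error in the
reference, miscalled variants, and polyploid/heterozygous dosage. The
wet-lab failure modes of real markers (null alleles, star activity,
incomplete digestion) are outside any in-silico model.

Test and verification problem sizes are the package's own choices:
1000 random 200 bp SNV windows for the oracle-equivalence check, 200
constructed indel cases, 500 cases per strand-symmetry screen, and a
112-target neighbour-rich fixture for the primer-contract and
self-recovery checks. At these sizes every screen has run with zero
discrepancies.

## Format conventions and degenerate inputs

* VCF indels are anchor-trimmed: `AT→A` at POS 100 becomes a deletion of
  the `T` at 101; `A→AGG` becomes a zero-length insertion anchored at
  100 (inserted bases lie 3' of the anchor). This is the GFF3/GVF
  convention and makes allele application unambiguous. Records that are
  neither SNV nor pure anchor indel (complex substitutions, symbolic
  alleles) have no representation in the feature model and are skipped
  with a counter — permissive for content, strict (fail with a line
  number) for structure.
* Alleles are carried as GVF-style `Reference_seq`/`Variant_seq`
  attributes, so the GFF3 output round-trips field-exactly.
* Interval (0-based half-open) conversion maps zero-length insertions to
  zero-length intervals at the anchor coordinate, the one choice that
  makes the round trip the identity (the Galaxy interval format has no
  insertion encoding of its own).
* The gsMapper 454HCDiffs/454AllDiffs dialect is parsed from its `>`
  rows using the first five fields, tolerating version-dependent
  trailing columns (the first two are carried as depth and frequency
  when numeric) and a literal column-header row. The exact column set
  varies by mapper version and is not formally specified anywhere, so
  the parser is deliberately tolerant.
* Streaming: the readers consume connections line by line and never
  slurp a file before parsing; `scan_variants()` accepts a file path
  and processes features against one contig at a time, so memory scales
  with the candidate table, not the input.

## Reproducibility

All randomness in the fixture generator and workflow flows through a
single integer seed (default 42), which is recorded in every artifact's
provenance header; artifacts contain no timestamps, so identical
configurations produce byte-identical candidate and primer tables. The
design engine and detector are deterministic by construction.

## Known limitations

* No dCAPS design: SNPs that condition no restriction polymorphism are
  reported as non-candidates, not rescued with engineered-mismatch
  primers.
* No fragment-resolution scoring: candidates report site counts and
  positions, not predicted gel patterns; enzymes with optional cut
  offsets carry them for downstream use only.
* No melt-curve prediction for HRM beyond the class I/II filter, and no
  multiplex compatibility scoring.
* Primer thermodynamics omit secondary-structure terms (above), and the
  electronic PCR is exact-matching by default — raising `max_mismatch`
  trades sensitivity for a quadratic growth in convergent combinations.
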