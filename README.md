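# capsmark

Bulk PCR-based marker design from next-generation sequence variants, in R.

Deep sequencing finds thousands of SNPs and indels in any organism, but
turning them into assays a small lab can actually run — PCR, a restriction
digest, an agarose gel, or a melt curve — is the bottleneck, especially
for non-model species with no genome and only transcriptome contigs to
work from. `capsmark` closes that gap for three low-technology marker
classes:

* **CAPS** (cleaved amplified polymorphic sequences, a.k.a. PCR-RFLP):
  a variant creates or destroys a restriction site, so the amplified
  alleles digest differently.
* **Indel** markers: a short length polymorphism resolved directly on a
  gel from a small amplicon.
* **HRM** (high-resolution melting) markers: class I/II SNPs genotyped
  closed-tube by the melt shift of a small amplicon.

The pipeline is tabular end to end — variant features, CAPS candidates,
primer pairs and predicted amplicons are tibbles that chain with the
pipe and write as flat GFF3/TSV files.

## The core computation

For a variant with reference allele *r* and alternate allele *a* on
contig *S*, take the window `W = S[start − f .. end + f]` (flank
`f = 50` bp by default) and build the alternate window `W'` by applying
the allele edit. For each enzyme *E* with IUPAC-degenerate recognition
site *p*, count recognition sites on both strands,

    n(W, E)  = |{i : W[i..i+|p|−1] ∈ expand(p)}| + (non-palindromic: same for revcomp(p))

and call *(variant, E)* a **CAPS candidate** iff `n(W, E) ≠ n(W', E)`,
with status *gained* when the alternate allele has more sites. Comparing
*counts* rather than site positions makes length-changing indels safe: an
indel that merely translates downstream sites is not a polymorphism and
yields no candidate. A sequence `N` matches no pattern symbol, so
ambiguous reference bases never produce candidates.

Around each target, primer design masks every *other* known variant
position with `N` and excludes those positions from primer placement, so
assays amplify uniformly across genotypes. Candidate oligos are
enumerated under length/Tm/GC constraints (nearest-neighbour Tm,
SantaLucia unified parameters), scored with an additive penalty, and
paired under marker-specific amplicon sizes: **90–120 bp for CAPS,
60–100 bp for indel and HRM**. Designed pairs are validated by
electronic PCR: ungapped, 3'-anchored matching of both primers on both
strands, convergent combinations reported as predicted amplicons, and
pairs hitting zero or multiple loci flagged.

The default enzyme panel is the six digest workhorses that perform well
in PCR buffers: TaqI, AluI, RsaI, DpnII, HinfI, HaeIII (REBASE sites,
bundled as a TSV; any panel can be supplied the same way).

## Worked example

Everything below runs on a seeded synthetic fixture, so it reproduces
exactly; substitute your own FASTA and VCF/454HCDiffs files for real
data.

```r
library(capsmark)

fx    <- generate_fixture(seed = 42, n_contigs = 3,
                          contig_length = 1800, n_variants = 18)
panel <- load_panel()
scan  <- scan_variants(fx$ref, fx$variants, panel, flank = 50)
glance(scan)
#> # A tibble: 1 × 9
#>   variants_seen variants_skipped_n candidates  TaqI  AluI  RsaI DpnII HinfI
#>           <int>              <int>      <int> <int> <int> <int> <int> <int>
#> 1            18                  0         10     2     1     2     3     1

candidates_to_table(scan)[1:5, c("variant_id", "seqid", "start", "vtype",
                                 "enzyme", "status", "confounded")]
#>   variant_id seqid     start vtype enzyme status confounded
#> 1 var0001    contig001   171 SNV   TaqI   lost   FALSE
#> 2 var0007    contig001   489 SNV   AluI   gained FALSE
#> 3 var0010    contig001   656 SNV   DpnII  lost   FALSE
#> 4 var0002    contig002   196 SNV   DpnII  gained FALSE
#> 5 var0002    contig002   196 SNV   HinfI  lost   FALSE
```

18 planted variants yield 10 enzyme/variant candidates; `var0001` is a
SNP whose alternate allele *loses* a TaqI site, so the two alleles of a
~100 bp amplicon around it separate on a gel after a TaqI digest.
`var0002` conditions two enzymes at once. Design masked flanking primers
for the first candidate and validate them:

```r
tgt <- fx$variants[fx$variants$id == "var0001", ]
tpl <- build_template(fx$ref[[tgt$seqid]], tgt, neighbours = fx$variants)
pp  <- design_primers(tpl)
pp[, c("pair_id", "product_size", "tm_left", "tm_right", "penalty")]
#>   pair_id   product_size tm_left tm_right penalty
#> 1 var0001_1          111    54.7     55.1    4.36
#> 2 var0001_2          102    57.4     58.4    4.57
#> ...

glance(epcr(primer_table(pp, tpl, enzyme = "TaqI"), fx$ref))
#>   pair_id   n_hits specific
#> 1 var0001_1      1 TRUE
#> 2 var0001_2      1 TRUE
#> ...
```

All pairs sit in the 90–120 bp CAPS range, flank the SNP without
touching any masked neighbour position, and each amplifies exactly one
locus in the reference (`specific = TRUE`), at exactly its designed
product size. `run_caps_workflow()` chains all of this (convert →
detect → filter → design → ePCR) from file paths to provenance-headed
artifacts, and `exec/capsmark` exposes each stage as a shell subcommand
(`vcf2gff`, `gsmapper2gff`, `find-caps`, `design-primers`, `epcr`,
`map-primers`, `simulate`, `run`).

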