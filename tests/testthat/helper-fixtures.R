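# Small in-code text fixtures for the parsers.

vcf_lines <- function(...) {
  c("##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    ...)
}

gsmapper_lines <- function(...) {
  c(">Reference  Start  End  Ref  Var  Total  Var  Freq",
    "",
    ...)
}

# Minimal primersearch-style amplimer report.
amplimer_report <- function() {
  c("Primer name pairA",
    "Amplimer 1",
    "\tSequence: contig00123  ",
    "\tonion transcript contig",
    "\tAAGCTTGCATGCCTGCAGGT hits forward strand at 21 with 0 mismatches",
    "\tTTGGCCAATTCGGCACGAGG hits reverse strand at [35] with 0 mismatches",
    "\tAmplimer length: 104 bp",
    "",
    "Primer name pairB",
    "Amplimer 1",
    "\tSequence: contig00456",
    "\tanother contig",
    "\tACGTACGTACGTACGTACGT hits forward strand at 5 with 1 mismatches",
    "\tTGCATGCATGCATGCATGCA hits reverse strand at [12] with 0 mismatches",
    "\tAmplimer length: 88 bp")
}
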