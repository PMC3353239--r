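## Shared sequence constants (loaded before the modules that use them).

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

## The standard genetic code as a named character vector codon -> amino acid
## ("*" for stop).
GENETIC_CODE_1 <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

## the 61 sense codons
SENSE_CODONS <- local({
  all <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  sort(all[!all %in% STOP_CODONS])
})
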