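# Shared constants (this file loads before the module files).

DNA_BASES <- c("A", "C", "G", "T")

# All 64 trinucleotides in lexicographic order.
ALL_TRINUCS <- do.call(paste0, expand.grid(DNA_BASES, DNA_BASES, DNA_BASES,
                                           stringsAsFactors = FALSE)[, 3:1])
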