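# Shared alphabet constants (file sorts first so every other source file
# can use them at load time).

# Gap character recognised in aligned rows.
GAP_CHAR <- "-"

# Unambiguous nucleotide states used by the alignment statistics.
NUC_STATES <- c("A", "C", "G", "T")

STOP_CODONS <- c("TAA", "TAG", "TGA")
ALL_CODONS <- as.vector(outer(as.vector(outer(NUC_STATES, NUC_STATES,
                                              paste0)),
                              NUC_STATES, paste0))
NONSTOP_CODONS <- ALL_CODONS[!ALL_CODONS %in% STOP_CODONS]
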