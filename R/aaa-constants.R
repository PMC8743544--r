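# Shared sequence constants; this file must collate before all others.

# Bacterial/archaeal genetic code (translation table 11), codon -> residue.
.codon_table_11 <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0
  )))
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"
  ), "")[[1]]
  stats::setNames(aas, codons)
})

.start_codons <- c("ATG", "GTG", "TTG")
.stop_codons <- c("TAA", "TAG", "TGA")

# 20 standard residues plus the ambiguity/rare letters accepted in digests
.aa_alphabet <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y",
  "X", "B", "Z", "J", "U", "O"
)
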