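# Standard genetic code and the 61 sense-codon alphabet, in the conventional
# TCAG ordering (first codon position varies slowest).

NUC <- c("T", "C", "A", "G")

CODON64 <- as.vector(t(outer(
  as.vector(t(outer(NUC, NUC, paste0))), NUC, paste0)))
# outer() nesting above yields position-1-slowest TCAG order:
# TTT TTC TTA TTG TCT ... GGG

GENETIC_CODE_STD <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

STOP_CODONS <- names(GENETIC_CODE_STD)[GENETIC_CODE_STD == "*"]
CODON61 <- CODON64[!CODON64 %in% STOP_CODONS]
CODON61_AA <- unname(GENETIC_CODE_STD[CODON61])

# codon index (1..61) -> 3 nucleotide indices (1..4, TCAG), as a 61 x 3 matrix
CODON61_NUC <- t(vapply(strsplit(CODON61, ""),
                        function(s) match(s, NUC), integer(3)))

# Is the single-nucleotide difference between two codons a transition?
is_transition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
}
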