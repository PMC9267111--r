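# Standard genetic code tables used throughout the package.
# Built once at install time from Biostrings::GENETIC_CODE.

GENETIC_CODE_TBL <- Biostrings::GENETIC_CODE

#' @noRd
STOP_CODONS <- sort(names(GENETIC_CODE_TBL)[GENETIC_CODE_TBL == "*"])

# The 61 sense codons in fixed alphabetical order; this order is the
# documented column order of every codon-count and RSCU table.
SENSE_CODONS <- sort(names(GENETIC_CODE_TBL)[GENETIC_CODE_TBL != "*"])

CODON_AA <- GENETIC_CODE_TBL[SENSE_CODONS]

# Synonymous families keyed by one-letter amino acid; Met and Trp are
# single-codon families and carry no synonymous information.
SYN_FAMILIES <- split(SENSE_CODONS, CODON_AA)
FAMILY_SIZE <- vapply(SYN_FAMILIES, length, integer(1))

# 59 codons entering RSCU and RSCU-PCA: sense codons minus ATG and TGG.
RSCU_CODONS <- setdiff(SENSE_CODONS, c("ATG", "TGG"))

# Codons of amino acids with >= 2 synonymous codons (GC3s denominator set).
SYNONYMOUS_CODONS <- RSCU_CODONS

# Isoleucine codons: excluded (with stops) from GC3 in the neutrality plot.
ILE_CODONS <- SYN_FAMILIES[["I"]]

# PR2 third-position pools: the five four-codon families plus the
# four-codon subsets of the six-fold families (Arg CG*, Leu CT*, Ser TC*).
PR2_CODONS <- sort(c(
  SYN_FAMILIES[["A"]], SYN_FAMILIES[["G"]], SYN_FAMILIES[["P"]],
  SYN_FAMILIES[["T"]], SYN_FAMILIES[["V"]],
  paste0("CG", c("A", "C", "G", "T")),
  paste0("CT", c("A", "C", "G", "T")),
  paste0("TC", c("A", "C", "G", "T"))
))

# ENc degeneracy classes (CodonW convention: six-fold families kept whole).
ENC_CLASSES <- list(
  `2` = names(FAMILY_SIZE)[FAMILY_SIZE == 2],
  `3` = names(FAMILY_SIZE)[FAMILY_SIZE == 3],
  `4` = names(FAMILY_SIZE)[FAMILY_SIZE == 4],
  `6` = names(FAMILY_SIZE)[FAMILY_SIZE == 6]
)

DINUCLEOTIDES <- sort(as.vector(outer(c("A", "C", "G", "T"),
                                      c("A", "C", "G", "T"), paste0)))

# split a validated CDS string into codons (frame 0)
split_codons <- function(sequence) {
  n <- nchar(sequence)
  substring(sequence, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}

third_base <- function(codons) substr(codons, 3L, 3L)
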