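# Independent oracles and fixture builders shared across tests.

SENSE <- mycocub:::SENSE_CODONS
STOPS <- mycocub:::STOP_CODONS
FAMS <- mycocub:::SYN_FAMILIES

# assemble a CDS from sense codons (start/stop added)
make_cds <- function(codons, stop = "TAA") {
  paste0("ATG", paste(codons, collapse = ""), stop)
}

# random codon count table; counts drawn from `range` so every family is
# observed (no missing-family fallback path in either implementation)
random_count_table <- function(range = 2:60) {
  counts <- sample(range, length(SENSE), replace = TRUE)
  names(counts) <- SENSE
  counts
}

# Independent ENc oracle. Written from the "homozygosity = probability that
# two codons drawn without replacement from a family are identical" view:
# F = sum_i C(n_i, 2) / C(n, 2), averaged per degeneracy class, then
# ENc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6 (capped at 61). Valid for tables
# where every family has n >= 2 and F > 0.
naive_enc <- function(counts) {
  fam_f <- sapply(FAMS[lengths(FAMS) >= 2], function(codons) {
    n <- sum(counts[codons])
    sum(choose(counts[codons], 2)) / choose(n, 2)
  })
  deg <- lengths(FAMS)[names(fam_f)]
  fbar <- tapply(fam_f, deg, mean)
  min(61, 2 + 9 / fbar[["2"]] + 1 / fbar[["3"]] + 5 / fbar[["4"]] +
        3 / fbar[["6"]])
}

# brute-force dinucleotide odds ratios by explicit window enumeration
naive_rho <- function(sequence) {
  b <- strsplit(sequence, "")[[1]]
  L <- length(b)
  out <- numeric(0)
  for (x in c("A", "C", "G", "T")) for (y in c("A", "C", "G", "T")) {
    fxy <- 0
    for (i in seq_len(L - 1)) if (b[i] == x && b[i + 1] == y)
      fxy <- fxy + 1
    fx <- sum(b == x) / L
    fy <- sum(b == y) / L
    out[paste0(x, y)] <- (fxy / (L - 1)) / (fx * fy)
  }
  out
}

# exhaustive hypergeometric upper tail: enumerate all C(N, n) selections
# of `n` genes from a background of `N` of which the first `K` carry the
# term; returns P(X >= k)
enum_hyper_p <- function(k, K, N, n) {
  sel <- utils::combn(N, n)
  hits <- colSums(sel <= K)
  mean(hits >= k)
}

# closed-form OLS slope/intercept via the normal equations
normal_eq_ols <- function(x, y) {
  n <- length(x)
  slope <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small default study used by several end-to-end tests (kept light)
tiny_study <- function(seed = 1, n_host = 60, n_virus = 5,
                       similar_fraction = 0.1) {
  vm <- make_codon_model(0.30, 1, seed = 11)
  hm <- make_codon_model(0.55, 1, seed = 12)
  generate_study(study_design(n_host, n_virus, similar_fraction,
                              c(150, 250), seed = seed), vm, hm)
}
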