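#' Count sense codons of one or more CDS
#'
#' Tallies frame-0 codons; the terminal stop codon is dropped. Stop codons
#' are never keyed: an internal stop raises an error (validation should have
#' rejected the sequence).
#'
#' @param x a single CDS string, a character vector of CDS (pooled), or a
#'   `cds_set` (pooled over all rows).
#' @return named integer vector over the 61 sense codons (fixed alphabetical
#'   order) with attribute `total`; class `codon_counts`.
#' @export
count_codons <- function(x) {
  seqs <- if (is.data.frame(x)) x$sequence else as.character(x)
  codons <- unlist(lapply(seqs, function(s)
    drop_terminal_stop(split_codons(s))), use.names = FALSE)
  if (any(codons %in% STOP_CODONS))
    stop("internal stop codon encountered; run validate_cds first")
  counts <- table(factor(codons, levels = SENSE_CODONS))
  out <- as.integer(counts)
  names(out) <- SENSE_CODONS
  structure(out, total = sum(out), class = "codon_counts")
}

#' Per-sequence codon count matrix
#'
#' @param x a `cds_set`.
#' @return integer matrix, one row per sequence (rownames = ids), 61 sense
#'   codon columns in fixed alphabetical order.
#' @export
codon_count_matrix <- function(x) {
  m <- t(vapply(x$sequence, function(s) unclass(count_codons(s)),
                integer(length(SENSE_CODONS))))
  rownames(m) <- x$id
  colnames(m) <- SENSE_CODONS
  m
}

#' Relative synonymous codon usage
#'
#' For codon *j* of an amino acid with degeneracy *k*,
#' `RSCU = x_j / (sum(x) / k)`: the observed count relative to the count
#' expected under uniform usage within the family. ATG, TGG and the stop
#' codons are excluded, leaving 59 values. Codons are classed as
#' over-represented when RSCU > 1.6 and under-represented when RSCU < 0.6;
#' families with zero total get value 0 and class `"absent"` (distinct from
#' a genuine 0 inside an observed family).
#'
#' @param counts a `codon_counts` vector from [count_codons()] (or any named
#'   numeric vector keyed by codon).
#' @param over,under class thresholds (defaults 1.6 / 0.6).
#' @return list with `values` (named numeric over the 59 codons) and
#'   `classes` (named character: `"over"`, `"normal"`, `"under"`,
#'   `"absent"`); class `rscu`.
#' @export
rscu <- function(counts, over = 1.6, under = 0.6) {
  x <- counts[RSCU_CODONS]
  x[is.na(x)] <- 0
  names(x) <- RSCU_CODONS
  aa <- CODON_AA[RSCU_CODONS]
  fam_tot <- tapply(x, aa, sum)[aa]
  k <- FAMILY_SIZE[aa]
  values <- as.vector(ifelse(fam_tot > 0, x / (fam_tot / k), 0))
  classes <- as.vector(ifelse(fam_tot == 0, "absent",
             ifelse(values > over, "over",
             ifelse(values < under, "under", "normal"))))
  names(values) <- names(classes) <- RSCU_CODONS
  structure(list(values = values, classes = classes), class = "rscu")
}

#' Per-sequence RSCU matrix
#'
#' The 59-column numeric matrix consumed by [rscu_pca()]; absent families
#' contribute 0 (auditable via [rscu()] classes on individual rows).
#'
#' @param x a `cds_set` or a codon count matrix from [codon_count_matrix()].
#' @return numeric matrix, rows = sequences, columns = the 59 RSCU codons in
#'   fixed alphabetical order.
#' @export
rscu_matrix <- function(x) {
  cm <- if (is.matrix(x)) x else codon_count_matrix(x)
  m <- t(apply(cm, 1L, function(row) rscu(row)$values))
  colnames(m) <- RSCU_CODONS
  m
}

#' Wright's effective number of codons (ENc)
#'
#' The Wright (1990) estimator. Per synonymous family the codon
#' homozygosity is `F = (n * sum(p^2) - 1) / (n - 1)` with `n` the family
#' count total and `p` the within-family codon proportions. Families with
#' `n <= 1` or `F = 0` are treated as missing and replaced by the mean F of
#' the observed families in the same degeneracy class; if the 3-fold class
#' (Ile) is entirely unobservable its mean is estimated as the average of
#' the 2-fold and 4-fold class means (Wright's fallback, as in CodonW).
#' `ENc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, capped at 61.
#'
#' @param counts a `codon_counts` vector ([count_codons()]) or named numeric
#'   vector keyed by codon.
#' @return list with `enc` (capped to \[20, 61\], `NA` if undefined), `raw`
#'   (uncapped), and `class_means` (mean F per degeneracy class);
#'   class `enc`.
#' @export
enc <- function(counts) {
  x <- counts[SENSE_CODONS]
  x[is.na(x)] <- 0
  f_hat <- vapply(SYN_FAMILIES[FAMILY_SIZE >= 2], function(codons) {
    n <- sum(x[codons])
    if (n <= 1) return(NA_real_)
    p <- x[codons] / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    if (f == 0) NA_real_ else f
  }, numeric(1))
  class_mean <- vapply(ENC_CLASSES, function(aas) {
    v <- f_hat[aas]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  if (is.na(class_mean[["3"]]) &&
      !is.na(class_mean[["2"]]) && !is.na(class_mean[["4"]]))
    class_mean[["3"]] <- (class_mean[["2"]] + class_mean[["4"]]) / 2
  if (anyNA(class_mean))
    return(structure(list(enc = NA_real_, raw = NA_real_,
                          class_means = class_mean), class = "enc"))
  raw <- 2 + 9 / class_mean[["2"]] + 1 / class_mean[["3"]] +
    5 / class_mean[["4"]] + 3 / class_mean[["6"]]
  structure(list(enc = min(raw, 61), raw = raw, class_means = class_mean),
            class = "enc")
}

#' Expected ENc under pure GC3s compositional constraint
#'
#' `ENc_expected(s) = 2 + s + 29 / (s^2 + (1 - s)^2)`, the theoretical
#' curve for codon usage driven only by third-position GC content.
#'
#' @param s GC3s as a fraction in \[0, 1\] (vectorised).
#' @return expected ENc value(s).
#' @export
expected_enc <- function(s) {
  if (any(is.na(s)) || any(s < 0 | s > 1))
    stop("GC3s fraction must lie in [0, 1]")
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' Per-sequence ENc table
#'
#' @param x a `cds_set`.
#' @return data.frame with columns `id`, `enc`, `enc_raw`.
#' @export
enc_table <- function(x) {
  cm <- codon_count_matrix(x)
  vals <- apply(cm, 1L, function(row) {
    e <- enc(row)
    c(e$enc, e$raw)
  })
  data.frame(id = x$id, enc = vals[1L, ], enc_raw = vals[2L, ],
             row.names = NULL)
}
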