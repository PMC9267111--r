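#' Nucleotide composition of a CDS
#'
#' Base percentages over the full coding sequence, stop codon included.
#'
#' @param sequence a single CDS string (validated), or a `cds_set`
#'   (then one row per sequence is returned).
#' @return For a single string, a named numeric vector
#'   `a_pct, c_pct, g_pct, t_pct, gc_pct` (percent of total length).
#'   For a `cds_set`, a data.frame with an `id` column and those fields.
#' @export
nucleotide_composition <- function(sequence) {
  if (is.data.frame(sequence)) {
    m <- t(vapply(sequence$sequence, nucleotide_composition, numeric(5)))
    return(data.frame(id = sequence$id, m, row.names = NULL))
  }
  if (!nzchar(sequence)) stop("empty sequence")
  bases <- strsplit(sequence, "")[[1L]]
  n <- length(bases)
  counts <- vapply(c("A", "C", "G", "T"), function(b) sum(bases == b),
                   numeric(1))
  pct <- 100 * counts / n
  c(a_pct = pct[["A"]], c_pct = pct[["C"]], g_pct = pct[["G"]],
    t_pct = pct[["T"]], gc_pct = pct[["C"]] + pct[["G"]])
}

#' Positional GC content for the neutrality plot
#'
#' GC fraction at each codon position with the neutrality-plot exclusions:
#' ATG and TGG codons (and the terminal stop codon) are dropped from GC1,
#' GC2 and GC3; additionally the isoleucine codons (ATT, ATC, ATA) are
#' dropped from GC3 only (stop codons would also be dropped there, but a
#' validated CDS has none internally). GC12 is the mean of GC1 and GC2.
#'
#' @param sequence a single validated CDS string, or a `cds_set`.
#' @return named numeric vector `gc1, gc2, gc3, gc12` in percent (`NA` when
#'   no codons remain after exclusions), or a data.frame for a `cds_set`.
#' @export
positional_gc <- function(sequence) {
  if (is.data.frame(sequence)) {
    m <- t(vapply(sequence$sequence, positional_gc, numeric(4)))
    return(data.frame(id = sequence$id, m, row.names = NULL))
  }
  codons <- drop_terminal_stop(split_codons(sequence))
  keep12 <- !codons %in% c("ATG", "TGG", STOP_CODONS)
  keep3 <- keep12 & !codons %in% ILE_CODONS
  gc_at <- function(codons, pos) {
    if (length(codons) == 0L) return(NA_real_)
    100 * mean(substr(codons, pos, pos) %in% c("G", "C"))
  }
  gc1 <- gc_at(codons[keep12], 1L)
  gc2 <- gc_at(codons[keep12], 2L)
  gc3 <- gc_at(codons[keep3], 3L)
  c(gc1 = gc1, gc2 = gc2, gc3 = gc3, gc12 = (gc1 + gc2) / 2)
}

#' Synonymous third-position GC content (GC3s)
#'
#' Fraction of G or C at the third position of codons belonging to amino
#' acids with two or more synonymous codons — the CodonW convention: Met,
#' Trp and stop codons are excluded, isoleucine is included (unlike the
#' GC3 of [positional_gc()]).
#'
#' @param sequence a single validated CDS string, or a `cds_set`.
#' @return GC3s in percent (`NA` if no synonymous codon is present), or a
#'   data.frame (`id`, `gc3s`) for a `cds_set`.
#' @export
gc3s <- function(sequence) {
  if (is.data.frame(sequence)) {
    return(data.frame(id = sequence$id,
                      gc3s = vapply(sequence$sequence, gc3s, numeric(1)),
                      row.names = NULL))
  }
  codons <- drop_terminal_stop(split_codons(sequence))
  syn <- codons[codons %in% SYNONYMOUS_CODONS]
  if (length(syn) == 0L) return(NA_real_)
  100 * mean(third_base(syn) %in% c("G", "C"))
}

#' Full composition profile table
#'
#' One row per sequence with base percentages, positional GC and GC3s.
#'
#' @param x a `cds_set`.
#' @return data.frame with columns `id`, `a_pct`, `c_pct`, `g_pct`, `t_pct`,
#'   `gc_pct`, `gc1`, `gc2`, `gc3`, `gc12`, `gc3s`.
#' @export
composition_profile <- function(x) {
  out <- nucleotide_composition(x)
  out <- cbind(out, positional_gc(x)[, -1L, drop = FALSE])
  out$gc3s <- gc3s(x)$gc3s
  out
}

drop_terminal_stop <- function(codons) {
  n <- length(codons)
  if (n > 0L && codons[[n]] %in% STOP_CODONS) codons[-n] else codons
}
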