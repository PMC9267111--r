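#' Read a gene-to-term annotation map
#'
#' @param path two-column TSV (`gene`, `term`), optionally a third column
#'   of term names; header optional (detected by whether the first field of
#'   the first line is literally `gene`).
#' @return list with `gene2terms` (named list gene -> character vector of
#'   terms) and `term_names` (named character, possibly empty); class
#'   `annotation_map`.
#' @export
read_annotation_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  header <- identical(strsplit(first, "\t")[[1L]][1L], "gene")
  tab <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  if (!header) names(tab)[1:2] <- c("gene", "term")
  annotation_map(tab$gene, tab$term,
                 term_names = if (ncol(tab) >= 3L)
                   stats::setNames(tab[[3L]], tab$term) else character(0))
}

#' Build an annotation map from gene/term pairs
#'
#' @param gene,term character vectors of equal length (one row per
#'   gene-term link).
#' @param term_names optional named character vector of term descriptions.
#' @return an `annotation_map`; the background is the set of annotated
#'   genes.
#' @export
annotation_map <- function(gene, term, term_names = character(0)) {
  stopifnot(length(gene) == length(term))
  g2t <- lapply(split(as.character(term), as.character(gene)), unique)
  structure(list(gene2terms = g2t,
                 term_names = term_names[!duplicated(names(term_names))]),
            class = "annotation_map")
}

#' Hypergeometric term enrichment of a gene selection
#'
#' Upper-tail (over-representation) hypergeometric test per term:
#' with `N` annotated background genes, `K` of them carrying the term, and
#' `n` selected annotated genes of which `k` carry the term,
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Selected genes absent
#' from the background are dropped with a warning; no multiple-testing
#' correction is applied by default (`adjust = "none"`), matching a raw
#' p < 0.01 significance threshold. Benjamini-Hochberg is available via
#' `adjust = "BH"` (significance is then on the adjusted p).
#'
#' @param selected character vector of selected gene ids.
#' @param annotation an `annotation_map`.
#' @param alpha significance threshold (strict `p < alpha`; default 0.01).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame sorted by p: `term, name, k, n, K, N, p, p_adj,
#'   significant`.
#' @export
enrich <- function(selected, annotation, alpha = 0.01,
                   adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(annotation, "annotation_map"))
  background <- names(annotation$gene2terms)
  N <- length(background)
  sel <- unique(as.character(selected))
  dropped <- setdiff(sel, background)
  if (length(dropped) > 0L)
    warning(length(dropped), " selected gene(s) not in the annotated ",
            "background were dropped")
  sel <- intersect(sel, background)
  if (length(sel) == 0L) stop("no selected gene is annotated")
  n <- length(sel)
  term_of_bg <- annotation$gene2terms
  K_tab <- table(unlist(term_of_bg, use.names = FALSE))
  k_tab <- table(unlist(term_of_bg[sel], use.names = FALSE))
  terms <- names(K_tab)
  k <- as.integer(k_tab[terms])
  k[is.na(k)] <- 0L
  K <- as.integer(K_tab)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  p_adj <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  nm <- annotation$term_names[terms]
  out <- data.frame(term = terms,
                    name = ifelse(is.na(nm), "", nm),
                    k = k, n = n, K = K, N = N, p = p, p_adj = p_adj,
                    significant = p_adj < alpha,
                    row.names = NULL)
  out[order(out$p, out$term), , drop = FALSE]
}

#' Compare two enriched-term sets
#'
#' @param a,b character vectors of term ids.
#' @return list `shared`, `only_a`, `only_b` (each sorted, unique).
#' @export
compare_term_sets <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  list(shared = sort(intersect(a, b)),
       only_a = sort(setdiff(a, b)),
       only_b = sort(setdiff(b, a)))
}
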