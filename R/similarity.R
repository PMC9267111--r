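#' Joint virus-host PCA of RSCU vectors
#'
#' Principal component analysis of the stacked (host genes + viruses)
#' 59-column RSCU matrix: column mean-centering, no variance scaling
#' (`prcomp` defaults). The joint construction matters — host scores from a
#' joint fit differ from a host-only fit, and the fixed scaling convention
#' is what gives the 0.3-unit per-virus radius its meaning. The sign of
#' each axis is fixed so that its largest-magnitude loading is positive,
#' making score tables reproducible across runs and libraries.
#'
#' @param host_rscu,virus_rscu numeric matrices with the same 59-codon
#'   column order (see [rscu_matrix()]); rownames are ids. `virus_rscu` may
#'   be NULL if `host_rscu` already contains everything.
#' @param virus_ids ids marking virus rows; defaults to the rownames of
#'   `virus_rscu`.
#' @return list with `scores` (data.frame `id`, `origin`, `PC1..PC4`),
#'   `variance_explained` (fractions per axis, all axes), `loadings`
#'   (59 x k matrix); class `rscu_pca`.
#' @export
rscu_pca <- function(host_rscu, virus_rscu = NULL, virus_ids = NULL) {
  stacked <- rbind(host_rscu, virus_rscu)
  if (nrow(stacked) < 2L) stop("need at least 2 rows for PCA")
  if (is.null(rownames(stacked)))
    rownames(stacked) <- paste0("row", seq_len(nrow(stacked)))
  if (is.null(virus_ids))
    virus_ids <- if (is.null(virus_rscu)) character(0) else
      rownames(stacked)[seq.int(nrow(host_rscu) + 1L, nrow(stacked))]
  fit <- stats::prcomp(stacked, center = TRUE, scale. = FALSE)
  # fix axis signs: largest-|loading| positive on every axis
  flip <- vapply(seq_len(ncol(fit$rotation)), function(j) {
    l <- fit$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  fit$rotation <- sweep(fit$rotation, 2L, flip, `*`)
  fit$x <- sweep(fit$x, 2L, flip, `*`)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  k <- min(4L, ncol(fit$x))
  scores <- data.frame(id = rownames(stacked),
                       origin = ifelse(rownames(stacked) %in% virus_ids,
                                       "virus", "host"),
                       fit$x[, seq_len(k), drop = FALSE],
                       row.names = NULL)
  structure(list(scores = scores, variance_explained = ve,
                 loadings = fit$rotation), class = "rscu_pca")
}

#' Minimal circle around a virus cluster centroid
#'
#' The center is the mean (PC1, PC2) of the listed viruses; the radius is
#' the maximum Euclidean distance from that center to any listed virus —
#' the minimal radius covering the cluster given the fixed centroid.
#'
#' @param projection an `rscu_pca` object.
#' @param virus_ids ids of the clustered viruses (must all be in the
#'   projection).
#' @return list `center` (named `a`, `b`), `radius`, `member_virus_ids`;
#'   class `selection_circle`.
#' @export
cluster_circle <- function(projection, virus_ids) {
  sc <- projection$scores
  idx <- match(virus_ids, sc$id)
  if (anyNA(idx)) stop("unknown virus id(s): ",
                       paste(virus_ids[is.na(idx)], collapse = ", "))
  pts <- as.matrix(sc[idx, c("PC1", "PC2")])
  center <- colMeans(pts)
  radius <- if (nrow(pts) == 1L) 0 else
    max(sqrt((pts[, 1L] - center[1L])^2 + (pts[, 2L] - center[2L])^2))
  structure(list(center = c(a = unname(center[1L]), b = unname(center[2L])),
                 radius = radius, member_virus_ids = virus_ids),
            class = "selection_circle")
}

#' Select host genes inside a selection circle
#'
#' Closed-disk membership on (PC1, PC2):
#' `(PC1 - a)^2 + (PC2 - b)^2 <= r^2`. Viruses are excluded from the gene
#' list.
#'
#' @param projection an `rscu_pca` object.
#' @param circle a `selection_circle`.
#' @return list `circle`, `selected_gene_ids`; class `similarity_selection`.
#' @export
select_similar_genes <- function(projection, circle) {
  sc <- projection$scores
  d2 <- (sc$PC1 - circle$center[["a"]])^2 +
        (sc$PC2 - circle$center[["b"]])^2
  sel <- sc$id[sc$origin == "host" & d2 <= circle$radius^2]
  structure(list(circle = circle, selected_gene_ids = sel),
            class = "similarity_selection")
}

#' Per-virus selection with a fixed radius
#'
#' Centers a circle of fixed radius (default 0.3 units in the joint PCA
#' score space) on a single virus and selects the host genes inside it.
#'
#' @param projection an `rscu_pca` object.
#' @param virus_id a single virus id in the projection.
#' @param radius circle radius (default 0.3).
#' @return a `similarity_selection`.
#' @export
per_virus_circle <- function(projection, virus_id, radius = 0.3) {
  sc <- projection$scores
  idx <- match(virus_id, sc$id)
  if (is.na(idx)) stop("unknown virus id: ", virus_id)
  circle <- structure(list(center = c(a = sc$PC1[idx], b = sc$PC2[idx]),
                           radius = radius, member_virus_ids = virus_id),
                      class = "selection_circle")
  select_similar_genes(projection, circle)
}

#' Usage of codons whose cognate tRNA is missing
#'
#' For every codon with host tRNA copy number 0, reports each sequence's
#' RSCU value and class, flagging sequences where such a codon is
#' over-represented (RSCU > 1.6).
#'
#' @param rscu_mat per-sequence RSCU matrix ([rscu_matrix()]).
#' @param trna_table named numeric vector or two-column data.frame
#'   (`codon`, `copy_number`); codons, not anticodons.
#' @param over over-representation threshold (default 1.6).
#' @return data.frame `id, codon, rscu, class, flagged` with one row per
#'   (sequence, zero-tRNA codon); zero rows when no codon is missing.
#' @export
missing_trna_codon_report <- function(rscu_mat, trna_table, over = 1.6) {
  if (is.data.frame(trna_table)) {
    tt <- trna_table$copy_number
    names(tt) <- trna_table$codon
  } else tt <- trna_table
  missing_codons <- intersect(names(tt)[tt == 0], colnames(rscu_mat))
  empty <- data.frame(id = character(0), codon = character(0),
                      rscu = numeric(0), class = character(0),
                      flagged = logical(0))
  if (length(missing_codons) == 0L) return(empty)
  out <- do.call(rbind, lapply(missing_codons, function(cod) {
    v <- rscu_mat[, cod]
    data.frame(id = rownames(rscu_mat), codon = cod, rscu = v,
               class = ifelse(v > over, "over",
                       ifelse(v < 0.6, "under", "normal")),
               flagged = v > over, row.names = NULL)
  }))
  out[order(out$id, out$codon), , drop = FALSE]
}
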