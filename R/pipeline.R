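#' Pipeline configuration
#'
#' Collects the input paths and thresholds of the full analysis; defaults
#' are the study's published constants.
#'
#' @param virus_fasta,host_fasta FASTA paths (either may be NULL).
#' @param labels_tsv,annotation_tsv,trna_tsv optional TSV paths
#'   (sequence labels; gene-to-GO map; codon tRNA copy numbers).
#' @param min_length_nt CDS length filter, strict (default 300).
#' @param rscu_over,rscu_under RSCU class thresholds (1.6 / 0.6).
#' @param dinuc_over,dinuc_under dinucleotide thresholds (1.23 / 0.78).
#' @param enrich_alpha enrichment significance threshold (0.01).
#' @param per_virus_radius radius for single-virus circles (0.3).
#' @param outlier_rule neutrality-plot outlier rule (`"iqr1.5"`/`"none"`).
#' @param seed integer seed recorded in run logs.
#' @return list of settings; class `pipeline_config`.
#' @export
pipeline_config <- function(virus_fasta = NULL, host_fasta = NULL,
                            labels_tsv = NULL, annotation_tsv = NULL,
                            trna_tsv = NULL, min_length_nt = 300,
                            rscu_over = 1.6, rscu_under = 0.6,
                            dinuc_over = 1.23, dinuc_under = 0.78,
                            enrich_alpha = 0.01, per_virus_radius = 0.3,
                            outlier_rule = c("iqr1.5", "none"), seed = 1L) {
  outlier_rule <- match.arg(outlier_rule)
  stopifnot(rscu_over > rscu_under, dinuc_over > dinuc_under,
            enrich_alpha > 0, per_virus_radius >= 0, min_length_nt >= 0)
  structure(as.list(environment()), class = "pipeline_config")
}

load_config_sequences <- function(config) {
  labels <- if (!is.null(config$labels_tsv))
    read_label_tsv(config$labels_tsv) else NULL
  pieces <- list()
  if (!is.null(config$virus_fasta))
    pieces$virus <- read_cds_fasta(config$virus_fasta, "virus", labels)
  if (!is.null(config$host_fasta))
    pieces$host <- read_cds_fasta(config$host_fasta, "host", labels)
  if (length(pieces) == 0L) stop("no input FASTA configured")
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("cds_set", "data.frame")
  out
}

#' Run the per-sequence metrics stage
#'
#' Validates the configured sequences and computes composition, RSCU, ENc,
#' PR2 and dinucleotide tables, writing each as TSV when `out_dir` is
#' given.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if missing).
#' @return list of data.frames: `validation`, `profile` (composition + ENc
#'   + PR2 + ENc-GC3s flags), `rscu` (59-column matrix as data.frame),
#'   `dinucleotide`, plus `sequences` (the surviving `cds_set`).
#' @export
run_metrics <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  all_seq <- load_config_sequences(config)
  seqs <- filter_valid_cds(all_seq, min_length_nt = config$min_length_nt)
  validation <- attr(seqs, "validation")
  if (nrow(seqs) == 0L) stop("all sequences failed validation")
  profile <- composition_profile(seqs)
  profile <- merge(profile, enc_table(seqs), by = "id", sort = FALSE)
  profile <- merge(profile, pr2_point(seqs), by = "id", sort = FALSE)
  eg <- enc_gc3s_table(profile[, c("id", "gc3s", "enc")])
  profile <- merge(profile, eg[, c("id", "expected", "below_curve")],
                   by = "id", sort = FALSE, all.x = TRUE)
  profile <- merge(seqs[, c("id", "origin", "host_species", "genome_type",
                            "family")], profile, by = "id", sort = FALSE)
  rscu_df <- data.frame(id = seqs$id, rscu_matrix(seqs), row.names = NULL)
  dinuc <- dinucleotide_abundance(seqs,
                                  over = config$dinuc_over,
                                  under = config$dinuc_under)
  out <- list(validation = validation, profile = profile, rscu = rscu_df,
              dinucleotide = dinuc, sequences = seqs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("validation", "profile", "rscu", "dinucleotide"))
      write_tsv(out[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
    write_run_log(config, file.path(out_dir, "run_log.tsv"))
  }
  out
}

#' Run the similarity + enrichment stage
#'
#' Joint virus-host RSCU-PCA, circle selection around the given virus
#' cluster, and hypergeometric enrichment of the selected genes (skipped
#' with a warning when no annotation is configured).
#'
#' @param config a [pipeline_config()].
#' @param virus_cluster_ids ids of the clustered viruses used for the
#'   circle center; defaults to every virus.
#' @param metrics optional result of [run_metrics()] (computed on the fly
#'   otherwise).
#' @param out_dir optional output directory.
#' @return list `projection`, `selection`, `enrichment` (NULL when
#'   skipped), `scores`, `variance`.
#' @export
run_similarity <- function(config, virus_cluster_ids = NULL, metrics = NULL,
                           out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(metrics)) metrics <- run_metrics(config)
  seqs <- metrics$sequences
  rm_mat <- as.matrix(metrics$rscu[, -1L, drop = FALSE])
  rownames(rm_mat) <- metrics$rscu$id
  virus_ids <- seqs$id[seqs$origin == "virus"]
  if (length(virus_ids) == 0L) stop("no virus sequences in input")
  if (is.null(virus_cluster_ids)) virus_cluster_ids <- virus_ids
  if (!all(virus_cluster_ids %in% virus_ids))
    stop("cluster ids absent from the virus set: ",
         paste(setdiff(virus_cluster_ids, virus_ids), collapse = ", "))
  proj <- rscu_pca(rm_mat[seqs$origin == "host", , drop = FALSE],
                   rm_mat[seqs$origin == "virus", , drop = FALSE])
  circle <- cluster_circle(proj, virus_cluster_ids)
  selection <- select_similar_genes(proj, circle)
  enr <- NULL
  if (!is.null(config$annotation_tsv)) {
    ann <- read_annotation_tsv(config$annotation_tsv)
    if (length(ann$gene2terms) == 0L ||
        length(intersect(selection$selected_gene_ids,
                         names(ann$gene2terms))) == 0L) {
      warning("no selected gene is annotated; enrichment skipped")
    } else {
      enr <- enrich(selection$selected_gene_ids, ann,
                    alpha = config$enrich_alpha)
    }
  } else warning("no annotation configured; enrichment skipped")
  variance <- data.frame(axis = seq_along(proj$variance_explained),
                         variance_explained = proj$variance_explained)
  out <- list(projection = proj, selection = selection, enrichment = enr,
              scores = proj$scores, variance = variance)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(proj$scores, file.path(out_dir, "pca_scores.tsv"))
    write_tsv(variance, file.path(out_dir, "pca_variance.tsv"))
    sel_df <- data.frame(id = selection$selected_gene_ids)
    write_tsv(sel_df, file.path(out_dir, "selected_genes.tsv"))
    if (!is.null(enr)) write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
    write_run_log(config, file.path(out_dir, "run_log.tsv"))
  }
  out
}

#' Write a data.frame as TSV (full precision, no quoting)
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_run_log <- function(config, path) {
  vals <- vapply(config, function(v)
    if (is.null(v)) "" else paste(format(v), collapse = ","), character(1))
  log <- data.frame(key = c(names(vals), "r_version", "package_version"),
                    value = c(vals, as.character(getRversion()),
                              as.character(utils::packageVersion("mycocub"))))
  write_tsv(log, path)
}
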