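#' Build a parametric codon model for CDS simulation
#'
#' Codons are drawn i.i.d. from `P(codon) = P(aa) * P(codon | aa)`. The
#' within-family distributions are symmetric-Dirichlet draws with
#' concentration `1 / (bias_strength + eps)` (exactly uniform at
#' `bias_strength = 0`), then exponentially tilted toward G/C-ending codons
#' until the model-expected synonymous third-position GC (GC3s) matches
#' `target_gc3` within 0.005. Amino-acid frequencies default to uniform
#' over the 18 multi-codon amino acids with 1% each for Met and Trp, so
#' every ENc degeneracy class stays observable.
#'
#' @param target_gc3 desired expected GC3s as a fraction in \[0, 1\].
#' @param bias_strength >= 0; 0 gives uniform within-family usage, larger
#'   values concentrate each family on few codons.
#' @param seed integer seed for the Dirichlet draws.
#' @param aa_freqs optional named probability vector over the 20 amino
#'   acids (one-letter codes).
#' @param cpg_depletion factor in (0, 1\]: acceptance probability per CpG
#'   dinucleotide created while sampling (1 = no depletion).
#' @return list `aa_freqs`, `within_family`, `codon_probs` (named over the
#'   61 sense codons), `target_gc3`, `expected_gc3`, `bias_strength`,
#'   `cpg_depletion`, `tilt`; class `codon_model`.
#' @export
make_codon_model <- function(target_gc3, bias_strength = 0, seed = 1L,
                             aa_freqs = NULL, cpg_depletion = 1) {
  stopifnot(target_gc3 >= 0, target_gc3 <= 1, bias_strength >= 0,
            cpg_depletion > 0, cpg_depletion <= 1)
  if (is.null(aa_freqs)) {
    multi <- names(FAMILY_SIZE)[FAMILY_SIZE >= 2]
    aa_freqs <- stats::setNames(rep(0.98 / length(multi), length(multi)),
                                multi)
    aa_freqs[c("M", "W")] <- 0.01
  }
  aa_freqs <- aa_freqs / sum(aa_freqs)
  set.seed(seed)
  base <- lapply(SYN_FAMILIES, function(codons) {
    k <- length(codons)
    w <- if (k == 1L || bias_strength == 0) rep(1 / k, k) else {
      g <- stats::rgamma(k, shape = 1 / (bias_strength + 1e-8))
      g <- pmax(g, 1e-9)  # numerical floor so no codon is structurally 0
      g / sum(g)
    }
    stats::setNames(w, codons)
  })
  multi_aa <- intersect(names(aa_freqs)[aa_freqs > 0],
                        names(FAMILY_SIZE)[FAMILY_SIZE >= 2])
  if (length(multi_aa) == 0L)
    stop("target_gc3 unattainable: aa_freqs admit no synonymous family")
  syn_w <- aa_freqs[multi_aa] / sum(aa_freqs[multi_aa])
  expected_gc3_at <- function(t) {
    sum(vapply(multi_aa, function(aa) {
      w <- tilt_family(base[[aa]], t)
      sum(w[third_base(names(w)) %in% c("G", "C")])
    }, numeric(1)) * syn_w)
  }
  lo <- expected_gc3_at(-60)
  hi <- expected_gc3_at(60)
  if (target_gc3 < lo - 0.005 || target_gc3 > hi + 0.005)
    stop(sprintf("target_gc3 = %.3f unattainable (range %.3f..%.3f)",
                 target_gc3, lo, hi))
  t_star <-
    if (abs(expected_gc3_at(0) - target_gc3) < 1e-12) 0 else
      stats::uniroot(function(t) expected_gc3_at(t) - target_gc3,
                     c(-60, 60), tol = 1e-10)$root
  within <- lapply(base, tilt_family, t = t_star)
  achieved <- expected_gc3_at(t_star)
  if (abs(achieved - target_gc3) > 0.005)
    stop("tilt failed to reach target_gc3")
  codon_probs <- stats::setNames(numeric(length(SENSE_CODONS)), SENSE_CODONS)
  for (aa in names(within))
    codon_probs[names(within[[aa]])] <-
      (if (aa %in% names(aa_freqs)) aa_freqs[[aa]] else 0) * within[[aa]]
  codon_probs <- codon_probs / sum(codon_probs)
  # The depletion knob is defined on the rho_CG scale: calibrate the
  # internal per-CpG acceptance factor alpha so that the model-expected
  # rho_CG of the rejection sampler is cpg_depletion times its undepleted
  # value (rejection renormalisation and mononucleotide shifts make the
  # realised odds-ratio suppression weaker than the raw acceptance factor).
  alpha <- 1
  if (cpg_depletion < 1) {
    rho0 <- chain_rho_cg(codon_probs, 1)
    alpha <- stats::uniroot(
      function(a) chain_rho_cg(codon_probs, a) - cpg_depletion * rho0,
      c(1e-6, 1), tol = 1e-9)$root
  }
  structure(list(aa_freqs = aa_freqs, within_family = within,
                 codon_probs = codon_probs, target_gc3 = target_gc3,
                 expected_gc3 = achieved, bias_strength = bias_strength,
                 cpg_depletion = cpg_depletion, cpg_alpha = alpha,
                 tilt = t_star),
            class = "codon_model")
}

tilt_family <- function(w, t) {
  gc3 <- third_base(names(w)) %in% c("G", "C")
  v <- w * exp(t * gc3)
  v / sum(v)
}

codon_internal_cg <- function(codons) {
  vapply(codons, function(cod)
    (substr(cod, 1, 2) == "CG") + (substr(cod, 2, 3) == "CG"), numeric(1))
}

# Model-expected rho_CG of the rejection sampler with per-CpG acceptance
# factor alpha. The sampler is a Markov chain whose state is the last base
# of the previous codon: P(codon | s) propto p(codon) * alpha^m with m the
# number of CpGs created. Solved exactly over the 4-state chain.
chain_rho_cg <- function(codon_probs, alpha) {
  bases <- c("A", "C", "G", "T")
  icg <- codon_internal_cg(SENSE_CODONS)
  first <- substr(SENSE_CODONS, 1, 1)
  last <- third_base(SENSE_CODONS)
  cond <- sapply(bases, function(s) {
    m <- icg + (s == "C") * (first == "G")
    w <- codon_probs * alpha^m
    w / sum(w)
  })  # 61 x 4, column = previous last base
  trans <- t(sapply(bases, function(s)
    vapply(bases, function(b) sum(cond[last == b, s]), numeric(1))))
  ev <- eigen(t(trans))
  pi <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  pi <- pi / sum(pi)
  joint <- sweep(cond, 2, pi, `*`)  # P(prev state, codon)
  base_count <- sapply(bases, function(b) vapply(
    strsplit(SENSE_CODONS, ""), function(x) sum(x == b), numeric(1)))
  f_mono <- colSums(base_count * rowSums(joint)) / 3
  cg_per_codon <- sum(rowSums(joint) * icg) +
    sum(joint[first == "G", "C"])
  f_cg <- cg_per_codon / 3
  f_cg / (f_mono[["C"]] * f_mono[["G"]])
}

#' Simulate one coding sequence from a codon model
#'
#' `ATG` + `n_codons` i.i.d. sense codons + one stop codon (uniform over
#' TAA/TAG/TGA). When `cpg_depletion < 1`, each proposed codon is accepted
#' with probability `d^m` where `m` counts the CpG dinucleotides it creates
#' (inside the codon and across the boundary with the previous one), and
#' rejected codons are redrawn — a Markov thinning that depresses the CpG
#' odds ratio by roughly the factor `d`. Deterministic for a fixed seed.
#'
#' @param model a `codon_model`.
#' @param n_codons number of sense codons between start and stop (>= 100 so
#'   the 300-nt inclusion filter passes).
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return a single CDS string.
#' @export
generate_cds <- function(model, n_codons, seed = NULL) {
  stopifnot(inherits(model, "codon_model"), n_codons >= 1)
  if (!is.null(seed)) set.seed(seed)
  alpha <- if (is.null(model$cpg_alpha)) model$cpg_depletion else
    model$cpg_alpha
  probs <- model$codon_probs
  if (alpha >= 1) {
    codons <- sample(SENSE_CODONS, n_codons, replace = TRUE, prob = probs)
  } else {
    internal_cg <- codon_internal_cg(SENSE_CODONS)
    codons <- character(n_codons)
    prev_last <- "G"  # ATG precedes the first sampled codon
    for (i in seq_len(n_codons)) {
      repeat {
        cand <- sample(SENSE_CODONS, 1L, prob = probs)
        m <- internal_cg[[cand]] +
          (prev_last == "C" && substr(cand, 1, 1) == "G")
        if (m == 0 || stats::runif(1) < alpha^m) break
      }
      codons[i] <- cand
      prev_last <- substr(cand, 3, 3)
    }
  }
  paste0("ATG", paste(codons, collapse = ""),
         sample(STOP_CODONS, 1L))
}

#' Study design for the planted-similarity simulation
#'
#' @param n_host_genes,n_viruses counts (>= 1).
#' @param similar_fraction fraction of host genes drawn from the *virus*
#'   model (the planted "similar" genes).
#' @param gene_length_codons length-2 integer range of sense-codon counts
#'   per gene.
#' @param seed master seed; per-gene streams are derived from it so each
#'   gene's sequence does not depend on the collection size.
#' @return list of the arguments; class `study_design`.
#' @export
study_design <- function(n_host_genes = 1000L, n_viruses = 10L,
                         similar_fraction = 0.05,
                         gene_length_codons = c(200L, 400L), seed = 1L) {
  stopifnot(n_host_genes >= 1, n_viruses >= 1,
            similar_fraction >= 0, similar_fraction <= 1,
            length(gene_length_codons) == 2L,
            gene_length_codons[1L] >= 100L,
            gene_length_codons[1L] <= gene_length_codons[2L])
  structure(list(n_host_genes = as.integer(n_host_genes),
                 n_viruses = as.integer(n_viruses),
                 similar_fraction = similar_fraction,
                 gene_length_codons = as.integer(gene_length_codons),
                 seed = as.integer(seed)),
            class = "study_design")
}

# deterministic per-gene substream seed, independent of collection size
derive_seed <- function(master, stream, i) {
  as.integer((as.double(master) %% 65521 * 31627 + stream * 1000003 + i) %%
               2147483647) + 1L
}

#' Generate a planted-similarity virus + host study
#'
#' Viruses are drawn from `virus_model`; `similar_fraction` of the host
#' genes are also drawn from `virus_model` (recorded as ground truth),
#' the remainder from `host_model`. Gene lengths are uniform over
#' `gene_length_codons`. All sequences pass [validate_cds()] by
#' construction.
#'
#' @param design a [study_design()].
#' @param virus_model,host_model `codon_model`s; they should differ in
#'   `target_gc3` by a stated separation for the recovery experiment to be
#'   meaningful.
#' @return list `host` (a `cds_set`), `virus` (a `cds_set`), `truth`
#'   (data.frame `id`, `similar`).
#' @export
generate_study <- function(design, virus_model, host_model) {
  stopifnot(inherits(design, "study_design"))
  n_sim <- round(design$similar_fraction * design$n_host_genes)
  lo <- design$gene_length_codons[1L]
  hi <- design$gene_length_codons[2L]
  gen <- function(stream, i, model) {
    set.seed(derive_seed(design$seed, stream, i))
    len <- if (lo == hi) lo else sample(lo:hi, 1L)
    generate_cds(model, len, seed = NULL)
  }
  host_ids <- sprintf("host_%04d", seq_len(design$n_host_genes))
  similar <- seq_len(design$n_host_genes) <= n_sim
  host_seq <- vapply(seq_len(design$n_host_genes), function(i)
    gen(1L, i, if (similar[i]) virus_model else host_model), character(1))
  virus_ids <- sprintf("virus_%02d", seq_len(design$n_viruses))
  virus_seq <- vapply(seq_len(design$n_viruses), function(i)
    gen(2L, i, virus_model), character(1))
  list(host = coding_sequences(host_ids, host_seq, origin = "host"),
       virus = coding_sequences(virus_ids, virus_seq, origin = "virus"),
       truth = data.frame(id = host_ids, similar = similar))
}
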