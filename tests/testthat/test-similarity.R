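# minimal hand-built projection for the geometry tests
fake_projection <- function(ids, pc1, pc2, origin) {
  structure(list(scores = data.frame(id = ids, origin = origin,
                                     PC1 = pc1, PC2 = pc2),
                 variance_explained = c(0.6, 0.4),
                 loadings = NULL), class = "rscu_pca")
}

test_that("rscu_pca matches an independent eigendecomposition", {
  set.seed(51)
  m <- matrix(runif(5 * 59, 0, 2), nrow = 5,
              dimnames = list(paste0("g", 1:5), mycocub:::RSCU_CODONS))
  proj <- rscu_pca(m)
  centered <- scale(m, center = TRUE, scale = FALSE)
  eig <- eigen(cov(centered))
  scores_ref <- centered %*% eig$vectors
  for (j in 1:4) {  # per-axis sign freedom
    got <- proj$scores[[paste0("PC", j)]]
    ref <- scores_ref[, j]
    expect_true(max(abs(got - ref)) < 1e-8 || max(abs(got + ref)) < 1e-8,
                label = paste("axis", j))
  }
  ve_ref <- eig$values / sum(eig$values)
  expect_equal(proj$variance_explained[1:4], ve_ref[1:4], tolerance = 1e-9)
})

test_that("variance fractions are non-increasing and axis signs fixed", {
  set.seed(52)
  st <- tiny_study(n_host = 20, n_virus = 4)
  proj <- rscu_pca(rscu_matrix(st$host), rscu_matrix(st$virus))
  ve <- proj$variance_explained
  expect_true(all(diff(ve) <= 1e-12))
  expect_true(all(ve >= 0 & ve <= 1))
  expect_equal(sum(ve), 1, tolerance = 1e-9)
  for (j in seq_len(ncol(proj$loadings))) {
    l <- proj$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
  expect_equal(proj$scores$origin,
               rep(c("host", "virus"), c(20, 4)))
})

test_that("duplicating every row preserves variance fractions", {
  set.seed(53)
  m <- matrix(runif(6 * 59, 0, 2), nrow = 6,
              dimnames = list(paste0("g", 1:6), mycocub:::RSCU_CODONS))
  p1 <- rscu_pca(m)
  m2 <- rbind(m, m)
  rownames(m2) <- paste0("g", 1:12)
  p2 <- rscu_pca(m2)
  expect_equal(p1$variance_explained[1:4], p2$variance_explained[1:4],
               tolerance = 1e-9)
  expect_equal(abs(p2$scores$PC1[1:6]), abs(p2$scores$PC1[7:12]))
})

test_that("rank-1 input concentrates variance on axis 1", {
  u <- runif(8); v <- runif(59)
  m <- outer(u, v)
  dimnames(m) <- list(paste0("g", 1:8), mycocub:::RSCU_CODONS)
  proj <- rscu_pca(m)
  expect_gt(proj$variance_explained[1], 0.999)
  expect_error(rscu_pca(m[1, , drop = FALSE]), "at least 2 rows")
})

test_that("joint virus-host PCA differs from host-only PCA", {
  set.seed(54)
  st <- tiny_study(n_host = 15, n_virus = 5)
  joint <- rscu_pca(rscu_matrix(st$host), rscu_matrix(st$virus))
  solo <- rscu_pca(rscu_matrix(st$host))
  joint_host <- joint$scores$PC1[joint$scores$origin == "host"]
  expect_gt(max(abs(abs(joint_host) - abs(solo$scores$PC1))), 1e-3)
})

test_that("cluster_circle takes the centroid and the covering radius", {
  proj <- fake_projection(c("v1", "v2", "g1"), c(0, 0, 5), c(0, 2, 5),
                          c("virus", "virus", "host"))
  circ <- cluster_circle(proj, c("v1", "v2"))
  expect_equal(unname(circ$center), c(0, 1))
  expect_equal(circ$radius, 1)
  single <- cluster_circle(proj, "v1")
  expect_equal(single$radius, 0)
  expect_equal(unname(single$center), c(0, 0))
  expect_error(cluster_circle(proj, "nope"), "unknown virus id")
})

test_that("cluster radius equals a brute-force max-distance scan", {
  set.seed(55)
  pc1 <- rnorm(6); pc2 <- rnorm(6)
  proj <- fake_projection(paste0("v", 1:6), pc1, pc2, rep("virus", 6))
  circ <- cluster_circle(proj, paste0("v", 1:6))
  ref <- 0
  for (i in 1:6) ref <- max(ref, sqrt((pc1[i] - mean(pc1))^2 +
                                      (pc2[i] - mean(pc2))^2))
  expect_equal(circ$radius, ref)
  # every member lies within the radius
  d <- sqrt((pc1 - circ$center[["a"]])^2 + (pc2 - circ$center[["b"]])^2)
  expect_true(all(d <= circ$radius + 1e-12))
})

test_that("select_similar_genes applies closed-disk membership", {
  proj <- fake_projection(c("v1", "g1", "g2", "g3"),
                          c(0, 0.5, 1.0, 3.0), c(0, 0, 0, 0),
                          c("virus", "host", "host", "host"))
  circ <- structure(list(center = c(a = 0, b = 0), radius = 1,
                         member_virus_ids = "v1"),
                    class = "selection_circle")
  sel <- select_similar_genes(proj, circ)
  expect_setequal(sel$selected_gene_ids, c("g1", "g2"))  # boundary included
  # r = 0: generically nothing; full-range circle: everything
  circ$radius <- 0
  expect_equal(select_similar_genes(proj, circ)$selected_gene_ids,
               character(0))
  circ$radius <- 10
  expect_setequal(select_similar_genes(proj, circ)$selected_gene_ids,
                  c("g1", "g2", "g3"))
})

test_that("selection is monotone in the radius", {
  set.seed(56)
  proj <- fake_projection(paste0("g", 1:40), rnorm(40), rnorm(40),
                          c("virus", rep("host", 39)))
  prev <- character(0)
  for (r in seq(0, 3, by = 0.25)) {
    sel <- per_virus_circle(proj, "g1", radius = r)$selected_gene_ids
    expect_true(all(prev %in% sel))
    prev <- sel
  }
})

test_that("per_virus_circle selects by direct distance at r = 0.3", {
  proj <- fake_projection(c("v", "a", "b", "c"),
                          c(0, 0.1, 0.29, 0.31), c(0, 0, 0, 0),
                          c("virus", "host", "host", "host"))
  sel <- per_virus_circle(proj, "v")  # default radius 0.3
  expect_setequal(sel$selected_gene_ids, c("a", "b"))
  expect_error(per_virus_circle(proj, "zz"), "unknown virus id")
})

test_that("circle membership survives a global axis sign flip", {
  set.seed(57)
  proj <- fake_projection(paste0("g", 1:30), rnorm(30), rnorm(30),
                          c(rep("virus", 3), rep("host", 27)))
  circ <- cluster_circle(proj, paste0("g", 1:3))
  sel <- select_similar_genes(proj, circ)
  flipped <- proj
  flipped$scores$PC1 <- -flipped$scores$PC1
  circ2 <- cluster_circle(flipped, paste0("g", 1:3))
  sel2 <- select_similar_genes(flipped, circ2)
  expect_setequal(sel$selected_gene_ids, sel2$selected_gene_ids)
})

test_that("missing tRNA codons are reported with RSCU classes", {
  st <- tiny_study(n_host = 5, n_virus = 2)
  rm_mat <- rscu_matrix(st$host)
  trna_full <- setNames(rep(2, 59), mycocub:::RSCU_CODONS)
  expect_equal(nrow(missing_trna_codon_report(rm_mat, trna_full)), 0)
  # engineer a sequence using only CTG for Leu; zero-tRNA codon CTG
  cds <- make_cds(rep(c("CTG", "GCT"), 60))
  mono <- coding_sequences("only_ctg", cds)
  rm2 <- rscu_matrix(mono)
  trna <- trna_full
  trna["CTG"] <- 0
  rep <- missing_trna_codon_report(rm2, trna)
  expect_equal(rep$codon, "CTG")
  expect_equal(rep$rscu, 6)  # whole Leu family concentrated on CTG
  expect_true(rep$flagged)
  # data.frame form of the tRNA table behaves identically
  tdf <- data.frame(codon = names(trna), copy_number = unname(trna))
  expect_equal(missing_trna_codon_report(rm2, tdf), rep)
})

test_that("planted-bias virus is the one flagged for zero-tRNA codons", {
  # balanced background: every sense codon equally often -> RSCU exactly 1
  balanced <- vapply(1:6, function(i) make_cds(rep(SENSE, 3)), character(1))
  background <- coding_sequences(paste0("bg", 1:6), balanced)
  biased <- coding_sequences("biased_virus",
                             make_cds(rep(c("CTG", "GGG", "AAA"), 60)),
                             origin = "virus")
  all_seq <- rbind(background, biased)
  class(all_seq) <- c("cds_set", "data.frame")
  rm_mat <- rscu_matrix(all_seq)
  trna <- setNames(rep(1, 59), mycocub:::RSCU_CODONS)
  trna[c("CTG", "GGG")] <- 0
  rep <- missing_trna_codon_report(rm_mat, trna)
  flagged <- unique(rep$id[rep$flagged])
  expect_equal(flagged, "biased_virus")
  expect_setequal(rep$codon[rep$flagged], c("CTG", "GGG"))
})
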