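#' Relative dinucleotide abundance (rho)
#'
#' For each of the 16 dinucleotides XY, `rho_xy = f_xy / (f_x * f_y)`:
#' the observed frequency of XY over all L - 1 overlapping windows of the
#' sequence (codon boundaries and stop codon included, no circularisation)
#' divided by the product of the mononucleotide frequencies over L.
#' rho > 1.23 is classed over-represented, rho < 0.78 under-represented
#' (strict inequalities).
#'
#' @param sequence a single DNA string (length >= 2) or a `cds_set`.
#' @param over,under class thresholds (defaults 1.23 / 0.78).
#' @return For a single string, a list with `rho` (named numeric, `NA` where
#'   `f_x * f_y = 0`) and `classes` (named character), class
#'   `dinucleotide_profile`. For a `cds_set`, a data.frame with `id`, 16
#'   `rho_XY` columns and 16 `class_XY` columns.
#' @export
dinucleotide_abundance <- function(sequence, over = 1.23, under = 0.78) {
  if (is.data.frame(sequence)) {
    rows <- lapply(sequence$sequence, dinucleotide_abundance,
                   over = over, under = under)
    rho <- t(vapply(rows, function(p) p$rho, numeric(16L)))
    cls <- t(vapply(rows, function(p) p$classes, character(16L)))
    colnames(rho) <- paste0("rho_", DINUCLEOTIDES)
    colnames(cls) <- paste0("class_", DINUCLEOTIDES)
    return(data.frame(id = sequence$id, rho, cls, row.names = NULL))
  }
  bases <- strsplit(sequence, "")[[1L]]
  L <- length(bases)
  if (L < 2L) stop("sequence must have length >= 2")
  f_mono <- vapply(c("A", "C", "G", "T"), function(b) mean(bases == b),
                   numeric(1))
  dimers <- paste0(bases[-L], bases[-1L])
  f_di <- table(factor(dimers, levels = DINUCLEOTIDES)) / (L - 1L)
  # outer product is symmetric, so the vectorised layout aligns with the
  # lexicographic DINUCLEOTIDES order up to commuting the product
  denom <- as.vector(outer(f_mono, f_mono))
  rho <- ifelse(denom > 0, as.numeric(f_di) / denom, NA_real_)
  names(rho) <- DINUCLEOTIDES
  classes <- ifelse(is.na(rho), NA_character_,
             ifelse(rho > over, "over",
             ifelse(rho < under, "under", "normal")))
  names(classes) <- DINUCLEOTIDES
  structure(list(rho = rho, classes = classes),
            class = "dinucleotide_profile")
}

#' Group summary of dinucleotide abundance
#'
#' Mean and standard deviation of each rho within groups (e.g. genome type
#' or family).
#'
#' @param x a `cds_set`.
#' @param group name of the grouping column in `x` (default `"family"`).
#' @return data.frame: one row per (group, dinucleotide) with `mean`, `sd`,
#'   `n`.
#' @export
dinucleotide_summary <- function(x, group = "family") {
  prof <- dinucleotide_abundance(x)
  g <- x[[group]]
  res <- do.call(rbind, lapply(split(seq_len(nrow(prof)), g), function(idx) {
    sub <- prof[idx, paste0("rho_", DINUCLEOTIDES), drop = FALSE]
    data.frame(group = g[idx[1L]], dinucleotide = DINUCLEOTIDES,
               mean = colMeans(sub, na.rm = TRUE),
               sd = apply(sub, 2L, stats::sd, na.rm = TRUE),
               n = length(idx), row.names = NULL)
  }))
  rownames(res) <- NULL
  res
}
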