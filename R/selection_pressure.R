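#' Parity Rule 2 coordinates
#'
#' Third-position base counts pooled over the eight four-codon pools —
#' Ala (GC*), Gly (GG*), Pro (CC*), Thr (AC*), Val (GT*) and the
#' four-codon subsets of Arg (CG*), Leu (CT*), Ser (TC*) — give the
#' AT bias `A3/(A3+T3)` and GC bias `G3/(G3+C3)`. At mutational
#' equilibrium both equal 0.5 (the PR2 midpoint).
#'
#' @param counts a `codon_counts` vector from one CDS, or a `cds_set`
#'   (one row per sequence returned).
#' @return named numeric `at_bias, gc_bias` (`NA` when the corresponding
#'   denominator is zero), or a data.frame (`id`, `at_bias`, `gc_bias`).
#' @export
pr2_point <- function(counts) {
  if (is.data.frame(counts)) {
    m <- t(vapply(counts$sequence,
                  function(s) pr2_point(count_codons(s)), numeric(2)))
    return(data.frame(id = counts$id, m, row.names = NULL))
  }
  x <- counts[PR2_CODONS]
  x[is.na(x)] <- 0
  b3 <- third_base(PR2_CODONS)
  pool <- vapply(c("A", "C", "G", "T"), function(b) sum(x[b3 == b]),
                 numeric(1))
  at <- if (pool[["A"]] + pool[["T"]] > 0)
    pool[["A"]] / (pool[["A"]] + pool[["T"]]) else NA_real_
  gc <- if (pool[["G"]] + pool[["C"]] > 0)
    pool[["G"]] / (pool[["G"]] + pool[["C"]]) else NA_real_
  c(at_bias = at, gc_bias = gc)
}

#' Neutrality-plot regression of GC12 on GC3
#'
#' Ordinary least squares of GC12 against GC3 across genes of one host
#' group. A slope near 1 indicates mutation pressure dominates codon usage;
#' near 0, natural selection. Outliers (in GC12 or GC3) may be removed by
#' the 1.5 x IQR rule before fitting, with the removed ids reported.
#'
#' @param gc12,gc3 numeric vectors (percent or fraction, consistently).
#' @param ids optional identifiers (defaults to index).
#' @param outlier_rule `"iqr1.5"` (default: drop points whose GC12 *or* GC3
#'   falls outside \[Q1 - 1.5 IQR, Q3 + 1.5 IQR\] of its own variable) or
#'   `"none"`.
#' @return list with `slope`, `intercept`, `r` (Pearson), `p` (two-sided),
#'   `slope_ci` (95% confidence interval for the slope), `n_used`,
#'   `removed_ids`; class `neutrality_fit`.
#' @export
neutrality_fit <- function(gc12, gc3, ids = NULL,
                           outlier_rule = c("iqr1.5", "none")) {
  outlier_rule <- match.arg(outlier_rule)
  stopifnot(length(gc12) == length(gc3))
  if (is.null(ids)) ids <- as.character(seq_along(gc12))
  keep <- stats::complete.cases(gc12, gc3)
  if (outlier_rule == "iqr1.5")
    keep <- keep & !iqr_outlier(gc12) & !iqr_outlier(gc3)
  removed <- ids[!keep]
  x <- gc3[keep]
  y <- gc12[keep]
  if (length(x) < 3L) stop("fewer than 3 points after outlier removal")
  if (stats::var(x) == 0) stop("zero variance in GC3")
  fit <- stats::lm(y ~ x)
  if (stats::var(y) == 0) {
    # degenerate but well-defined OLS: flat line, correlation undefined
    ct <- list(estimate = NA_real_, p.value = NA_real_)
  } else {
    ct <- stats::cor.test(x, y, method = "pearson")
  }
  # exact collinear input is legitimate here; silence the perfect-fit note
  ci <- suppressWarnings(stats::confint(fit, "x", level = 0.95))
  structure(list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r = unname(ct$estimate), p = ct$p.value,
    slope_ci = c(lower = ci[1L], upper = ci[2L]),
    n_used = length(x), removed_ids = removed
  ), class = "neutrality_fit")
}

iqr_outlier <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  iqr <- q[2L] - q[1L]
  !is.na(v) & (v < q[1L] - 1.5 * iqr | v > q[2L] + 1.5 * iqr)
}

#' ENc vs GC3s table with the expected curve
#'
#' Joins observed ENc with the expected value at each gene's GC3s and flags
#' points strictly below the curve (points on the curve count as not below).
#'
#' @param profiles data.frame with columns `id`, `gc3s` (percent) and `enc`,
#'   e.g. merged from [composition_profile()] and [enc_table()]; or a
#'   `cds_set` (both computed on the fly).
#' @return data.frame `id, gc3s, enc, expected, below_curve`; the number of
#'   below-curve points is attached as attribute `n_below`.
#' @export
enc_gc3s_table <- function(profiles) {
  if (inherits(profiles, "cds_set"))
    profiles <- merge(gc3s(profiles), enc_table(profiles), by = "id",
                      sort = FALSE)
  stopifnot(all(c("id", "gc3s", "enc") %in% names(profiles)))
  ok <- !is.na(profiles$gc3s) & !is.na(profiles$enc)
  out <- profiles[ok, c("id", "gc3s", "enc")]
  out$expected <- expected_enc(out$gc3s / 100)
  out$below_curve <- out$enc < out$expected
  rownames(out) <- NULL
  attr(out, "n_below") <- sum(out$below_curve)
  out
}

#' Pearson (or Spearman) correlation with p-value
#'
#' Sample correlation with a two-sided p-value from the t transform with
#' n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return named numeric `r, p`.
#' @export
pearson_cor <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("degenerate (zero-variance) input")
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  c(r = unname(ct$estimate), p = ct$p.value)
}
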