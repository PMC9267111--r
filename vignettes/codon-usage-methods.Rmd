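---
title: "Methods: codon usage bias metrics and virus-host similarity selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon usage bias metrics and virus-host similarity selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycocub)
```

# Scope and model

`mycocub` quantifies codon usage bias (CUB) in sets of coding sequences and
asks whether a set of viral ORFs shares codon usage with a subset of host
genes. The intended setting is mycoviruses — RNA viruses of
plant-pathogenic fungi — where each virus contributes one analysed ORF and
each host genome contributes thousands of genes, but nothing in the
implementation is specific to fungi or viruses: any two labelled groups of
valid CDS can be compared.

The analysis treats each CDS as a bag of frame-0 codons. This is the
assumption underlying every classical CUB statistic implemented here
(RSCU, ENc, GC3s, PR2): codon order is ignored everywhere except in the
dinucleotide odds ratios, which by construction look across codon
boundaries.

# Sequence validation

A CDS enters the analysis only if it (i) is longer than 300 nt (strict
inequality — a 300-nt CDS is rejected), (ii) has length divisible by 3,
(iii) starts with `ATG`, (iv) ends with `TAA`/`TAG`/`TGA`, (v) has no
internal stop codon, and (vi) contains only `A`, `C`, `G`, `T`. Degenerate
IUPAC codes cause rejection rather than masking: a single `N` can silently
shift every downstream percentage, and the cost of dropping one sequence
is lower than the cost of an unauditable imputation. RNA-alphabet input is
mapped `U → T` on read, since all metrics are defined on the cDNA
alphabet. Validation never throws; it returns a reason-coded report so a
pipeline can log exactly why each record was excluded.

The stop codon is counted in the whole-sequence base composition (it is
part of the deposited CDS) but excluded from every positional GC
statistic and from codon counts.

# Composition statistics

Two different third-position GC fractions coexist deliberately:

* **GC3** (neutrality plot): fraction of G/C third bases after removing
  `ATG`, `TGG`, the stop codons, and the three isoleucine codons. The Ile
  exclusion follows the neutrality-plot convention in which the third
  codon position should be free to vary among all four bases under
  synonymous change; `ATA` vs `ATT/ATC` breaks that symmetry.
* **GC3s** (ENc–GC3s plot, CodonW convention): fraction of G/C third
  bases over all codons of amino acids with at least two synonymous
  codons — Ile included, Met/Trp/stops excluded.

The two generally differ; they coincide exactly only for sequences with
no isoleucine. Undefined values (no codons left after exclusions)
propagate as `NA`, never as 0 — a silent 0 would bias the neutrality
regression toward shallow slopes.

# RSCU and ENc

RSCU is the observed codon count relative to the uniform-usage
expectation within its synonymous family; 59 values per sequence (`ATG`
and `TGG` carry no synonymous information and are dropped, as are stops).
Families absent from a sequence get value 0 with class `absent`, distinct
from a genuine zero inside an observed family: principal component
analysis needs complete numeric vectors, but absence must stay auditable.
Class thresholds are strict: over-represented above 1.6,
under-represented below 0.6.

ENc uses Wright's estimator with the handling popularised by CodonW:

* per-family homozygosity `F̂ = (n Σ p̂² − 1)/(n − 1)`;
* families with `n ≤ 1` or `F̂ = 0` are unobservable and inherit the mean
  `F̂` of observed families in their degeneracy class;
* an entirely unobservable three-fold class (Ile) is replaced by the mean
  of the two-fold and four-fold class means;
* six-fold families (Leu, Ser, Arg) are kept whole rather than split
  4+2;
* the final value is capped at 61, with the raw estimate retained in the
  result for diagnostics. If a class other than the three-fold one is
  entirely unobservable the value is `NA`.

The expected-ENc curve is `2 + s + 29/(s² + (1 − s)²)`. The printed form
of this formula is typeset ambiguously in parts of the literature; this
is the standard reading, and it reproduces the expected values 31.0 (s =
0), 60.5 (s = 0.5), 32.0 (s = 1) with its maximum at s = 0.5. Points are
flagged `below_curve` under strict inequality, so a point exactly on the
curve counts as not below — a deterministic convention for a quantity
that is otherwise tie-ambiguous.

# PR2 and the neutrality regression

PR2 pools third-position counts across the eight four-codon pools (five
four-fold amino acids plus the four-codon subsets `CT*`, `CG*`, `TC*` of
the six-fold ones) and forms `A₃/(A₃+T₃)` and `G₃/(G₃+C₃)` from the
pooled counts. Pooling (rather than averaging per-family ratios) is the
standard construction and keeps the point well-defined when individual
families are sparse; either bias is `NA` when its denominator is zero.

The neutrality fit is ordinary least squares of GC12 on GC3 within one
host group. Outlier handling is a real degree of freedom in published
analyses and is rarely stated precisely, so it is explicit here: the
default removes points whose GC12 *or* GC3 falls outside 1.5×IQR of its
own variable within the group, reports the removed ids, and can be
switched off. Published per-host slopes computed with an unknown outlier
rule should therefore be treated as approximately reproducible at best.
The fit also returns the 95% confidence interval of the slope, which the
recovery tests use.

# Dinucleotide odds ratios

`ρ_xy = f_xy/(f_x f_y)` with `f_xy` over all `L − 1` overlapping windows
of the whole CDS — codon boundaries and the stop codon included, no
circularisation. The window convention matters at the margins: a
frame-restricted count would miss the position 3–1 boundary dinucleotides
that drive much of the CpG/TpA signal in coding sequence. Thresholds
1.23/0.78 are strict, and pairs whose mononucleotide product is zero are
`NA` rather than 0.

# Joint PCA and circle selection

The 59-column RSCU matrices of host genes and viruses are stacked and
decomposed with `prcomp` — column mean-centring, **no** variance scaling.
The scaling convention is load-bearing: a fixed-radius circle of "0.3
units" is only meaningful in a fixed score geometry, and unit-variance
scaling would change it. The joint fit is equally load-bearing: host
scores from a host-only PCA differ from host scores in the joint fit, and
the selection is defined in the joint space (this is asserted by test).

PCA axes are sign-indeterminate; signs are fixed so each axis's
largest-magnitude loading is positive, making score tables reproducible
across runs and linear-algebra backends.

Selection uses closed disks. The cluster circle takes the centroid of the
chosen viruses as centre and the maximal centre-to-virus distance as
radius — the minimal radius covering the cluster *given that centre*,
which is not the true minimum enclosing circle (whose centre would
differ; the fixed-centroid construction is the published procedure). The
per-virus variant centres a disk of fixed radius (default 0.3) on one
virus. Which viruses form "the cluster" is user input: the package does
not guess density-based cluster membership.

The missing-tRNA report cross-references RSCU values against a
codon-indexed tRNA copy-number table (anticodon decoding is the
supplier's responsibility) and flags sequences whose RSCU for a
zero-copy codon exceeds 1.6. A small synthetic example table ships in
`inst/extdata/synthetic_trna_copy_number.tsv`.

# Enrichment

One-sided upper-tail hypergeometric per term, background = all annotated
genes, `n` counting only selected genes that are annotated (selected
genes missing from the background are dropped with a warning — a
background-consistency requirement, not a convenience). Significance is
raw `p < 0.01` by default, matching the published procedure;
Benjamini–Hochberg adjustment is available behind a flag but off by
default, so reported term lists are comparable with raw-threshold
analyses. No GO-DAG propagation is performed: the annotation file is
assumed already closed under the true-path rule if the user wants it.

# The synthetic generator

The generator emulates exactly the features the metrics measure, and
nothing else:

* **Codon model**: i.i.d. codons from `P(aa) × P(codon | aa)`.
  Amino-acid frequencies default to uniform over the 18 multi-codon amino
  acids with 1% Met and Trp — chosen so every ENc degeneracy class is
  observable in genes of realistic length, not to mimic any particular
  proteome.
* **Bias strength**: within-family distributions are symmetric-Dirichlet
  draws with concentration `1/(bias_strength + 1e-8)`; 0 gives exactly
  uniform usage. This is a one-knob interpolation between no CUB
  (ENc ≈ 61) and extreme CUB (ENc → 20).
* **GC3 control**: an exponential tilt toward G/C-ending codons within
  each family, solved so the model-expected GC3s hits the target within
  0.005. The tilt preserves A↔T and G↔C symmetry at third positions, so
  unbiased models sit at the PR2 midpoint by construction. Because every
  synonymous family of the standard code has both G/C- and A/T-ending
  codons, any target in (0, 1) is attainable with the default amino-acid
  frequencies; the unattainability error can only trigger for custom
  `aa_freqs` that admit no synonymous family.
  One consequence: at `bias_strength = 0` with a target different from
  the model's natural GC3s (0.4907 under uniform families), the tilt
  makes within-family usage slightly non-uniform — exact uniformity and
  an arbitrary GC3s target cannot hold simultaneously.
* **CpG depletion**: codons are sampled sequentially and accepted with
  probability `α^m`, `m` = number of CpG dinucleotides created (inside
  the codon and across the boundary with the previous codon). The naive
  choice `α = d` does *not* make the realised CpG odds ratio equal `d`
  (rejection renormalisation and the induced mononucleotide shifts
  weaken the realised suppression; measured ≈ 0.64 for `α = 0.5`), so
  the knob is defined on the observable scale: at model-build time the
  stationary distribution of the 4-state chain over codon-boundary bases
  is solved exactly and `α` is calibrated so the model-expected
  `ρ_CG` ratio equals `cpg_depletion`. The calibration is analytic and
  blind to any test data.
* **Study design**: a fraction of host genes is drawn from the *virus*
  model and recorded as ground truth. Per-gene RNG streams are derived
  from the master seed and the gene index, so gene *i* is identical
  whether 10 or 10,000 genes are generated — a property the regression
  tests rely on.

What the generator does **not** emulate: amino-acid composition of real
proteomes, length/expression correlations, phylogenetic correlation among
viruses, multi-ORF genome architecture, and any codon autocorrelation
beyond the CpG knob. A green planted-recovery test therefore establishes
that the pipeline recovers *compositionally defined* similarity structure
at the stated separation — not that it would recover the published host
gene lists, which depend on real annotations and on which viruses were
judged "relatively concentrated".

# Numerical conventions

* Undefined statistics are `NA`, never 0; degenerate regressions (n < 3,
  zero GC3 variance) raise errors; a zero-variance GC12 yields slope 0
  with `NA` correlation.
* All class thresholds (1.6/0.6, 1.23/0.78) and the below-curve flag use
  strict inequalities; disk membership uses ≤.
* Codon columns are in fixed alphabetical order in every matrix and TSV.
* ENc is reported capped at [20, 61] with the raw value alongside.
* The tilt root-finder works on [−60, 60] with tolerance 1e-10; the CpG
  calibration root-finder on α ∈ [1e-6, 1] with tolerance 1e-9.

# Known limitations

* ENc missing-family fallbacks follow CodonW; other tools (e.g. DAMBE,
  EMBOSS `chips`) make different choices and can differ by a few units on
  short or skewed genes.
* The published per-host neutrality slopes are not exactly reproducible
  without the original outlier rule; comparisons should allow for this.
* Enrichment p-values are exact hypergeometric tails but the package
  deliberately performs no multiplicity correction by default and no GO
  propagation; both can change term lists materially.
* The circle-selection procedure inherits the arbitrariness of the
  virus-cluster choice; the package treats cluster membership as input.
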