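---
title: "Methods and design notes for lincluster"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for lincluster}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lincluster)
```

## Scope

`lincluster` detects genomic clusters of lincRNA genes — maximal runs of
near-adjacent genes on one chromosome — and scores each cluster's
co-expression, differential expression, conservation, miRNA targeting,
copy-number profile, and joint survival association. This vignette records
the model, its assumptions, the tunable parameters, and the design choices
made where the published description of the approach left the design open.

## Coordinates and input handling

All internal coordinates are 0-based half-open; Ensembl-style TSV and GTF
(1-based inclusive) are converted on read and back-converted on write, so a
read/write round trip reproduces the original integers exactly. BED6 passes
through unchanged. A single internal convention confines off-by-one
arithmetic to the I/O boundary. Chromosome names are taken verbatim
(`chr_prefix = "add"/"strip"` reconciles Ensembl and UCSC naming);
scaffolds are kept unless `primary_only = TRUE`, since lincRNA catalogs
list scaffold entries too.

The expression filter keeps genes whose value strictly exceeds 0.1 in at
least three samples — the literal reading of "greater than 0.1 in more
than two samples". It is idempotent, and the permutation universes of all
co-expression tests are defined *after* this filter, so random gene sets
are drawn from genes that could in principle have been scored.

## Cluster detection

A cluster is a maximal run of `min_size` or more consecutive genes in which
every consecutive gap is strictly below `max_gap_bp`. Choices within that
definition:

* **Gap definition.** The intergenic gap, start(next) − end(previous), is
  the default (`gap_mode = "intergenic"`): the bp-scale thresholds (15–80
  kb) are the scale of intergenic spacing, not of start-to-start distances,
  which would be inflated by gene length. Start-to-start is available as
  `gap_mode = "start"`. Overlapping genes yield negative gaps and trivially
  satisfy any threshold.
* **Minimum size 4.** The smallest reported clusters are quadruplets, so
  "more than four" is read as "four or more"; the parameter is exposed.
* **Strictness.** Gaps strictly below the threshold qualify; a gap exactly
  at the threshold splits the run.
* **Tie-breaks.** Within a chromosome genes sort by (start, end, gene_id),
  making detection deterministic for any input.
* **Strand is ignored**; clusters may mix orientations.

### Span-compactness permutation test

The test statistic is the cluster *span* — start of the first member to the
end of the last. The null draws a uniform start index among the windows of
the same member count on the same chromosome and recomputes the span;
`p = n_smaller / n_perm` with *strictly* smaller spans counted, so ties
(including redraws of the cluster's own window, which is not excluded — an
O(1/n) effect) never count as evidence. An optional pseudocount estimator
`(n_smaller + 1) / (n_perm + 1)` avoids exact zeros for downstream ranking.
Each cluster's draw uses a substream derived from (seed, cluster index), so
p-values do not depend on evaluation order.

Two properties of this null matter at small scale:

* The null population is the chromosome's own windows. A second compact
  cluster on the same chromosome contributes compact windows to the null,
  raising the first cluster's p-value by roughly (size of the other
  cluster)/(windows on the chromosome). With hundreds of genes per real
  chromosome this is negligible; on short synthetic chromosomes it
  dominates, so synthetic validation catalogs plant one cluster per
  chromosome.
* With `n_perm = 1000`, p-values live on the grid k/1000 and the smallest
  achievable value is 0; calibration checks use a one-grid-step
  randomized-PIT jitter before testing uniformity.

## Co-expression

**mRc** is the mean of |Pearson r| over unordered member pairs across the
tumor samples of one cancer type — the double sum of the defining equation
read as pairs j < k, excluding self-pairs, which would otherwise add a
guaranteed +1 per member and inflate every score. Pairs involving a
constant-expression gene are dropped and counted, never imputed as 0.
Pearson correlation is computed on the expression scale handed in (the
correlation is invariant to per-gene positive affine transforms, so
library-size style rescaling does not move mRc). Its permutation test draws
same-size gene sets from the expressed-gene universe genome-wide (not
per-chromosome), and `p_perm` is the fraction of draws with mRc at least
the observed value.

**Module enrichment** implements the stated formula verbatim:
`P = 1 − Σ_{t=0}^{Y} C(M,t)C(K−M,N−t)/C(K,N)`, i.e. the upper tail
P(X > Y) — one count more than the conventional P(X ≥ Y). Fidelity comes
first; `tail = "geq"` gives the conventional test. Terms are accumulated in
log space (`lchoose`) for stability; exactness to < 1e−12 is verified
against direct summation over the complete K ≤ 30 grid.

A consequence of the verbatim formula worth knowing: whenever Y = min(M, N)
— in particular whenever a cluster lies entirely inside *any* module,
however large — the sum exhausts the support and P = 0 exactly. The
permutation q is what keeps this degeneracy from producing spurious calls:
random same-size gene sets drawn from the universe reproduce min-p = 0
easily when modules are huge, so q stays large. The *cluster-related
module* is the minimum-p module (ties broken by larger overlap, then
label), and is accepted only with overlap Y ≥ 2, p ≤ 0.05, and q ≤ 0.05,
where q is the plain fraction of 1000 random draws whose minimum
(Y ≥ 2-constrained) enrichment p is at least as extreme — not a
BH-adjusted quantity, which the description of "permutation test q value"
does not support. A cluster is *co-expressed* in a cancer type only when
both the mRc and module criteria hold.

The lincRNA–mRNA screen retains pairs with |r| ≥ 0.35, computed separately
within tumor and normal sample groups.

## Differential expression

The cluster-level rule is the contribution; the per-gene test is
deliberately replaceable. The built-in stand-in is Welch's t on
log2(x + 1) with unadjusted p < 0.01 ("absolute P-value" is read as the
plain unadjusted p, with optional `adjust` and `lfc_threshold` gates off by
default), and `read_de_table()` ingests any externally computed
(gene, log2fc, p) table — e.g. moderated-model output — unchanged.

A cluster is co-DE when strictly more than half its members are
significant. Members missing from the DE table count toward the
denominator as non-DE; that is conservative for the "> half" rule.
Under a pure null the co-DE rate follows the binomial composition
P(Binom(L, 0.01) > L/2), which the tests verify empirically at L = 3 over
10,000 simulated clusters. Specificity labels partition clusters by the
number of cancer types with a co-DE call: one → unique, two or more →
common, none → none.

## Survival

Member expression is log2(x + 1)-transformed and z-scored per gene before
any fit, making coefficients comparable across genes and the median split
scale-free. The cluster risk score is the linear predictor of a
multivariate Cox fit over all members (fitting delegated to the standard
`survival` package; collinear or non-converging fits retry with a ridge
penalty and are flagged). Patients at or below the median risk score go to
the low-risk group — a fixed tie rule that yields ⌈n/2⌉ / ⌊n/2⌋ group
sizes and is invariant under strictly monotone transforms of the score.
The groups are compared by log-rank test, and Kaplan–Meier curves are
exported as step-function tables.

A caution the package reports but cannot remove: the median split is made
on the *fitted* risk score and the log-rank test is run on the same
patients used for fitting. With many members and few patients this is
optimistically biased — a seven-covariate fit on 100 patients separates
"low" and "high" risk groups impressively even when survival is pure noise.
The univariable screen's Cox p-values are exactly calibrated (verified
uniform under simulated nulls); the joint-model split p-values are not, and
should be read as descriptive unless validated on held-out samples. The
`cluster_level_only` flag (joint p < 0.05 while no member passes
univariably) inherits this caveat.

## Characterization

Cluster conservation is the unweighted mean of member per-gene phastCons /
phyloP means; per-gene means from a per-base track average over the full
gene span (transcript structure is not part of the input schema), ignore
uncovered bases, and genes absent from the track propagate as missing —
never as 0, which would masquerade as "unconserved". miRNA target counts
are per distinct miRNA after exact-duplicate removal of the merged
interaction set; a cluster's bipartite network lists (miRNA, member) edges
and counts miRNAs targeting ≥ 2 members. CNV gain frequency is the
fraction of samples with call > 0 (loss < 0) over all samples of the
cancer type; `high_level_only` restricts to ±2 calls. A simple
midpoint-overlap caller converts SEG-format segments when gene-level calls
are unavailable.

## The synthetic-data generator

The generator is first-class, tested code; every other module's validation
rests on it. It emulates:

* a diffuse genomic background — exponential intergenic gaps, mean 600 kb
  (ten times the default detection threshold), log-normal gene lengths
  (median 10 kb);
* planted compact clusters — consecutive blocks with internal gaps uniform
  in [1, `max_internal_gap`] (default plants use ≤ 30 kb), separated from
  the background by 300 kb flanks (five times the threshold) so ground
  truth is unambiguous;
* RPKM-like expression — exponentiated Gaussians (log-normal marginals)
  with a shared latent factor per planted cluster giving latent-scale
  pairwise correlation `coexpr_rho` (default 0.8). The exponentiation
  shrinks the Pearson correlation on the expression scale below the latent
  target; tests therefore band the realized mRc rather than pin it;
* tumor shifts of `de_effect` = 2 log2 units for DE genes, module labels
  that contain each planted cluster (with optional leakage), exponential
  survival with hazard exp(Σβ·x) and uniform censoring solved numerically
  to hit the target censoring fraction, Poisson miRNA targeting with a
  2× rate for clustered genes plus explicitly shared miRNAs, and
  cluster-wide CNV events in 30% of samples over sporadic 5% background
  calls.

The default chromosome carries 20 background genes. That number comes from
a collision calculation, not convenience: with P(gap < 60 kb) =
1 − exp(−0.1) ≈ 0.095, a catalog of 3 × 17 background gap triples has
under a 5% chance of containing any chance-compact quadruplet, so a
background-only catalog detects nothing in ≥ 95% of seeds and planted
memberships are the complete ground truth. Larger catalogs need
proportionally wider background gaps for the same guarantee; the
acceptance-scale recovery experiment (20 clusters, 20 chromosomes, 10
seeds) widens background gaps to 3 Mb for exactly this reason.

What the generator does **not** emulate: read-level noise, realistic
chromosome lengths and gene-density heterogeneity, batch structure,
tumor-purity effects, the dependence structure of real WGCNA modules, or
imprinted-locus biology. Passing tests demonstrate that the algorithms
implement their definitions and recover planted structure under the stated
noise model — not that real-data findings reproduce.

## Problem sizes and numerical choices

The test and verification suites run at desk scale: 100 random catalogs of
20–200 genes for the detection-oracle equivalence; 200 planted clusters
(20 per catalog × 10 seeds) with 1000-permutation significance for
recovery; 500 null windows for calibration; the complete K ≤ 30 grid
(86,335 evaluations) for hypergeometric exactness; 100 replicates of
4 × 101 null matrices against the analytic E|r| = sqrt(2/(π·100)); 10,000
3-gene null clusters for the co-DE rate; 20 seeds at n = 500 for Cox
recovery and 50 simulations at n = 300 for split power. Comparisons with
analytic values use three standard errors estimated from the replicates
themselves.

Degenerate inputs are handled explicitly: empty catalogs detect nothing
(not an error); a chromosome with fewer genes than a cluster's size cannot
form a null and errors; all-constant member sets error as "no variance";
zero-variance genes are dropped from pair counts, skipped (with a warning)
in survival screens, and excluded from DE significance only through their
p-value; clusters with no scored conservation member yield missing rows
with a warning; an empty expression filter result warns rather than errors.

## Known limitations

* Detection operates per chromosome on a single biotype catalog; clusters
  never span chromosomes, and mixed-biotype clustering is out of scope.
* The permutation null conditions on the observed gene positions of the
  chromosome; it tests compactness relative to those positions, not an
  explicit genome model.
* WGCNA module construction, GISTIC segmentation, moderated-model DE,
  ssGSEA scoring and downstream functional enrichment are inputs or out of
  scope, by design.
* The joint-model median-split log-rank p is training-set biased (see
  Survival above).
* q-values across many clusters are reported raw; optional
  Benjamini–Hochberg adjustment is available but per-cluster thresholds
  are the default behavior.
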