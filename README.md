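# lincluster

Detection and pan-cancer characterization of **lincRNA genomic clusters** —
runs of ≥ 4 consecutive long intergenic non-coding RNA genes on a chromosome
whose neighbours sit closer than a distance threshold (60 kb by default).
Co-located lincRNAs are frequently co-regulated; once a compact run is found,
the question is whether the run is tighter than chance and whether its members
behave as a unit across tumors: co-expressed, co-differentially expressed,
similarly conserved, similarly copy-number altered, and jointly — rather than
individually — prognostic. `lincluster` implements that whole workflow as a
tested R library with a thin command-line wrapper, exercised entirely on
synthetic data with known ground truth.

## The method

**Cluster detection.** Genes on each chromosome are scanned in coordinate
order; every maximal run of at least `min_size` genes with each consecutive
intergenic gap strictly below `max_gap_bp` is a candidate cluster. Each
candidate's *span* (start of first member to end of last) is compared with the
spans of 1000 random windows of the same member count drawn uniformly from the
same chromosome; the p-value is the fraction of random windows with strictly
smaller span, and candidates with p < 0.005 are retained.

**Co-expression.** Two criteria must both hold in a cancer type:

1. the mean absolute pairwise Pearson correlation of member expression
   across tumor samples,
   `mRc = mean_{j<k} |cor(Exp_j, Exp_k)|`,
   beats 1000 random same-size gene sets (permutation p ≤ 0.05); and
2. a *cluster-related module* exists: among externally supplied co-expression
   modules (e.g. WGCNA output), the module with minimum enrichment p under

   `P = 1 − Σ_{t=0}^{Y} C(M,t) · C(K−M, N−t) / C(K,N)`

   (K genes in the universe, M in the module, N in the cluster, Y shared)
   overlaps the cluster in ≥ 2 genes, has p ≤ 0.05, and survives a
   1000-draw permutation q ≤ 0.05.

**Differential expression.** Per-gene tumor-vs-normal tests (Welch's t on
log2(x+1), or any external DE table) feed the cluster rule: a cluster is
*co-differentially-expressed* when more than half of its members are
significant at p < 0.01; clusters co-DE in exactly one cancer type are
labelled *unique*, in two or more *common*.

**Survival.** Each member is screened by univariable Cox regression and
median-split Kaplan–Meier; the cluster risk score is the linear predictor of
a multivariate Cox fit over all members, patients are split at the median
risk score, and the low/high groups are compared by log-rank test. The
report flags clusters that separate survival jointly while no member does
individually.

**Characterization.** Per-cluster phastCons/phyloP conservation means,
miRNA-target counts with bipartite cluster networks from merged interaction
databases, and GISTIC-style CNV gain/loss frequencies with a within-cluster
dispersion statistic.

## Worked example

```r
library(lincluster)

cfg <- simulation_config(planted_clusters = list(
  list(chrom = "chr1", size = 4, max_internal_gap = 30000),
  list(chrom = "chr2", size = 5, max_internal_gap = 30000),
  list(chrom = "chr3", size = 7, max_internal_gap = 30000)),
  surv_betas = c(PL3_01 = 0.8, PL3_02 = -0.8), seed = 17)
fix <- simulate_all(cfg, "fixtures")          # writes all input formats
obj <- attr(fix, "objects")

cs <- detect_significant(obj$catalog,
                         detection_params(max_gap_bp = 60000, seed = 17))
as.data.frame(cs)[, c("cluster_id", "chrom", "size", "span_bp", "p_value")]
#>   cluster_id chrom size span_bp p_value
#> 1   Cluster1  chr1    4   90772       0
#> 2   Cluster2  chr2    5   76804       0
#> 3   Cluster3  chr3    7  213846       0

tumor <- filter_expressed(obj$tumor)          # > 0.1 in more than 2 samples
res <- call_coexpressed(tumor, attr(cs, "members")[["Cluster3"]],
                        obj$modules, n_perm = 1000, seed = 17)
#> Cluster3: mRc = 0.750 (perm p = 0), module M3 p = 0, q = 0.001
#> -> co-expressed: TRUE

rm_ <- cluster_risk_model(obj$tumor, obj$surv,
                          attr(cs, "members")[["Cluster3"]], "Cluster3")
rm_$logrank_p
#> [1] 4.89e-07
```

All three planted clusters come back with exact membership and permutation
p = 0 (no random window is more compact); the seven-member cluster passes
both co-expression criteria, and the risk score built on its members —
two of which carry planted hazard effects of opposite sign — separates the
median-split groups decisively.

The same workflow runs from the shell:

```sh
Rscript inst/cli/lincluster.R simulate --seed 17 --out fixtures/
Rscript inst/cli/lincluster.R detect --annotation fixtures/catalog.tsv \
    --max-gap 60000 --n-perm 1000 --alpha 0.005 --seed 17 --out clusters
Rscript inst/cli/lincluster.R run --config run.yaml   # full pipeline
```

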