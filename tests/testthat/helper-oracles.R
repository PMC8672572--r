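# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the code paths they check.

# Brute-force enumeration of maximal runs of >= min_size consecutive genes
# with every consecutive gap strictly below d. O(n^2): for every candidate
# run [i, j], check all gaps and maximality.
oracle_maximal_runs <- function(catalog, d, min_size,
                                gap_mode = "intergenic") {
  out <- list()
  for (ch in unique(catalog$chrom)) {
    sub <- catalog[catalog$chrom == ch, , drop = FALSE]
    n <- nrow(sub)
    gap <- function(i) {
      if (gap_mode == "start") sub$start[i + 1] - sub$start[i]
      else sub$start[i + 1] - sub$end[i]
    }
    for (i in seq_len(n)) {
      for (j in i:n) {
        if (j - i + 1 < min_size) next
        gaps_ok <- all(vapply(seq(i, j - 1), function(k) gap(k) < d,
                              logical(1)))
        if (!gaps_ok) next
        left_ok <- i == 1 || gap(i - 1) >= d
        right_ok <- j == n || gap(j) >= d
        if (left_ok && right_ok) {
          out[[length(out) + 1L]] <- sub$gene_id[i:j]
        }
      }
    }
  }
  out
}

# Second independent enumeration, formulated as grouping rather than
# scanning: genes are split at every gap >= d (cumulative break count)
# and groups of >= min_size genes are the maximal runs.
oracle_runs_by_breaks <- function(catalog, d, min_size,
                                  gap_mode = "intergenic") {
  out <- list()
  for (ch in unique(catalog$chrom)) {
    sub <- catalog[catalog$chrom == ch, , drop = FALSE]
    n <- nrow(sub)
    gaps <- if (gap_mode == "start") diff(sub$start)
            else sub$start[-1] - sub$end[-n]
    grp <- cumsum(c(TRUE, gaps >= d))
    runs <- split(sub$gene_id, grp)
    out <- c(out, unname(runs[lengths(runs) >= min_size]))
  }
  out
}

# Random catalog: n genes spread over chromosomes with iid gaps, mixing
# compact and diffuse spacing so qualifying runs appear at various sizes.
random_catalog <- function(n, seed, n_chrom = 2L, gap_mean = 60000) {
  set.seed(seed)
  chrom <- sort(sample(paste0("chr", seq_len(n_chrom)), n, replace = TRUE))
  starts <- unlist(lapply(split(seq_len(n), chrom), function(idx) {
    cumsum(round(rexp(length(idx), 1 / gap_mean)) + 500)
  }))
  lens <- round(runif(n, 200, 5000))
  gene_catalog(sprintf("g%03d", seq_len(n)), chrom, starts,
               starts + lens)
}

# Catalog with explicit per-gene starts/lengths on one chromosome.
catalog_from_gaps <- function(gaps, gene_len = 1000, chrom = "chr1") {
  n <- length(gaps) + 1L
  starts <- numeric(n)
  starts[1] <- 1000
  for (i in seq_along(gaps)) {
    starts[i + 1] <- starts[i] + gene_len + gaps[i]
  }
  gene_catalog(sprintf("g%d", seq_len(n)), chrom, starts,
               starts + gene_len)
}

# Exact hypergeometric upper tail P(X > Y) by direct summation with exact
# binomial coefficients (all values exact in double for K <= 30).
oracle_hyper_gt <- function(K, M, N, Y) {
  t <- 0:Y
  1 - sum(choose(M, t) * choose(K - M, N - t)) / choose(K, N)
}

# Standard simulation config with three planted clusters; used by several
# module tests.
three_cluster_config <- function(seed, ...) {
  simulation_config(planted_clusters = list(
    list(chrom = "chr1", size = 4L, max_internal_gap = 30000),
    list(chrom = "chr2", size = 5L, max_internal_gap = 30000),
    list(chrom = "chr3", size = 7L, max_internal_gap = 30000)),
    seed = seed, ...)
}

member_sets <- function(cs) {
  unname(lapply(attr(cs, "members"), identity))
}
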