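#' Parameters for genomic cluster detection
#'
#' @param max_gap_bp distance threshold d between consecutive genes (bp);
#'   a run qualifies when every consecutive gap is strictly below it.
#'   Default 60 kb, the threshold at which cluster discovery saturates on
#'   human lincRNA annotation.
#' @param min_size minimum number of member genes (default 4; quadruplets
#'   are the smallest reported clusters).
#' @param n_perm number of random windows drawn for the span-compactness
#'   permutation test (default 1000).
#' @param alpha significance cutoff on the permutation p-value
#'   (default 0.005).
#' @param seed master RNG seed; per-cluster substreams are derived from it
#'   so cluster p-values do not depend on evaluation order.
#' @param gap_mode `"intergenic"` (start of next minus end of previous,
#'   default) or `"start"` (start-to-start distance).
#' @param pseudocount if `TRUE`, report (n_smaller + 1) / (n_perm + 1)
#'   instead of the plain fraction, avoiding exact zeros.
#' @return a `detection_params` list.
#' @export
detection_params <- function(max_gap_bp = 60000, min_size = 4L,
                             n_perm = 1000L, alpha = 0.005, seed = 1L,
                             gap_mode = c("intergenic", "start"),
                             pseudocount = FALSE) {
  gap_mode <- match.arg(gap_mode)
  stopifnot(max_gap_bp > 0, min_size >= 2, n_perm >= 1,
            alpha > 0, alpha <= 1, is_count(seed))
  structure(list(max_gap_bp = max_gap_bp, min_size = as.integer(min_size),
                 n_perm = as.integer(n_perm), alpha = alpha,
                 seed = as.integer(seed), gap_mode = gap_mode,
                 pseudocount = isTRUE(pseudocount)),
            class = "detection_params")
}

consecutive_gaps <- function(start, end, gap_mode) {
  n <- length(start)
  if (n < 2L) return(numeric(0))
  if (gap_mode == "start") diff(start) else start[-1L] - end[-n]
}

#' Detect genomic clusters by sliding-window run finding
#'
#' Scans each chromosome in genomic order and returns every maximal run of
#' at least `min_size` consecutive genes in which each consecutive gap is
#' strictly less than `max_gap_bp`. Scanning resumes at the first gene
#' after a closed cluster, so cluster memberships partition the genes they
#' cover and no two clusters overlap. Strand is ignored; overlapping genes
#' (negative gaps) trivially satisfy the threshold. Permutation p-values
#' are left unset; see [detect_significant()].
#'
#' @param catalog a [gene_catalog()].
#' @param params a [detection_params()].
#' @return a `cluster_set`: data.frame with one row per cluster
#'   (`cluster_id`, `chrom`, `start`, `end`, `size`, `span_bp`, `p_value`,
#'   `n_smaller`, `n_perm`) and a `members` attribute listing member
#'   gene_ids in genomic order.
#' @export
detect_clusters <- function(catalog, params = detection_params()) {
  stopifnot(inherits(catalog, "gene_catalog"),
            inherits(params, "detection_params"))
  rows <- list(); members <- list()
  for (ch in unique(catalog$chrom)) {
    sub <- catalog[catalog$chrom == ch, , drop = FALSE]
    n <- nrow(sub)
    if (n < params$min_size) next
    gaps <- consecutive_gaps(sub$start, sub$end, params$gap_mode)
    ok <- gaps < params$max_gap_bp
    r <- rle(ok)
    pos <- cumsum(c(1L, r$lengths))
    for (k in seq_along(r$lengths)) {
      if (!r$values[k]) next
      n_genes <- r$lengths[k] + 1L
      if (n_genes < params$min_size) next
      i0 <- pos[k]; i1 <- pos[k] + r$lengths[k]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch,
        start = sub$start[i0],
        end = sub$end[i1],
        size = n_genes,
        span_bp = sub$end[i1] - sub$start[i0],
        stringsAsFactors = FALSE
      )
      members[[length(members) + 1L]] <- sub$gene_id[i0:i1]
    }
  }
  if (length(rows) == 0L) {
    df <- data.frame(cluster_id = character(0), chrom = character(0),
                     start = numeric(0), end = numeric(0),
                     size = integer(0), span_bp = numeric(0))
  } else {
    df <- do.call(rbind, rows)
    ord <- order(df$chrom, df$start)
    df <- df[ord, , drop = FALSE]
    members <- members[ord]
    df <- cbind(cluster_id = paste0("Cluster", seq_len(nrow(df))), df,
                stringsAsFactors = FALSE)
  }
  df$p_value <- rep(NA_real_, nrow(df))
  df$n_smaller <- rep(NA_integer_, nrow(df))
  df$n_perm <- rep(NA_integer_, nrow(df))
  rownames(df) <- NULL
  if (length(members)) names(members) <- df$cluster_id
  structure(df, members = members, params = params,
            catalog_label = attr(catalog, "genome_build") %||% "unspecified",
            class = c("cluster_set", "data.frame"))
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d cluster(s)\n", nrow(x)))
  print(head(as.data.frame(x), 10L))
  invisible(x)
}

#' Member genes of each cluster
#' @param cs a `cluster_set`.
#' @return data.frame (`cluster_id`, `gene_id`, `rank_in_cluster`).
#' @export
cluster_members <- function(cs) {
  members <- attr(cs, "members")
  if (length(members) == 0L) {
    return(data.frame(cluster_id = character(0), gene_id = character(0),
                      rank_in_cluster = integer(0)))
  }
  do.call(rbind, lapply(names(members), function(id) {
    data.frame(cluster_id = id, gene_id = members[[id]],
               rank_in_cluster = seq_along(members[[id]]),
               stringsAsFactors = FALSE)
  }))
}

#' Span-compactness permutation p-value for one cluster
#'
#' The cluster distance (span) is the distance from the start of the first
#' member to the end of the last. The null draws a uniform random start
#' index on the same chromosome and takes the same number of consecutive
#' genes; the p-value is the fraction of `n_perm` draws whose random span
#' is strictly smaller than the real span. The cluster's own window is not
#' excluded from the draw.
#'
#' @param cluster one-row slice of a `cluster_set` (or a list with `chrom`,
#'   `size`, `span_bp`).
#' @param catalog the [gene_catalog()] the cluster was detected on.
#' @param params a [detection_params()]; `n_perm`, `seed`, `pseudocount`
#'   are used.
#' @param seed optional override of `params$seed` for this evaluation.
#' @return list with `p_value`, `n_smaller`, `n_perm`, `seed`.
#' @export
permutation_pvalue <- function(cluster, catalog, params = detection_params(),
                               seed = NULL) {
  sub <- catalog[catalog$chrom == cluster$chrom, , drop = FALSE]
  L <- as.integer(cluster$size)
  n <- nrow(sub)
  if (n < L) stopf("insufficient genes for null on chromosome %s",
                   cluster$chrom)
  seed <- seed %||% params$seed
  n_windows <- n - L + 1L
  set.seed(seed)
  idx <- sample.int(n_windows, params$n_perm, replace = TRUE)
  rand_span <- sub$end[idx + L - 1L] - sub$start[idx]
  n_smaller <- sum(rand_span < cluster$span_bp)
  p <- if (params$pseudocount) (n_smaller + 1) / (params$n_perm + 1)
       else n_smaller / params$n_perm
  list(p_value = p, n_smaller = as.integer(n_smaller),
       n_perm = params$n_perm, seed = seed)
}

attach_pvalues <- function(cs, catalog, params) {
  if (nrow(cs) == 0L) return(cs)
  for (i in seq_len(nrow(cs))) {
    pr <- permutation_pvalue(cs[i, ], catalog, params,
                             seed = derive_seed(params$seed, i))
    cs$p_value[i] <- pr$p_value
    cs$n_smaller[i] <- pr$n_smaller
    cs$n_perm[i] <- pr$n_perm
  }
  cs
}

#' Detect clusters and keep those with significant span compactness
#'
#' Runs [detect_clusters()], attaches a permutation p-value to each
#' candidate, and retains clusters with `p_value < alpha`. Cluster IDs are
#' reassigned `Cluster1..N` over the retained set in (chrom, start) order.
#'
#' @inheritParams detect_clusters
#' @return a `cluster_set` of significant clusters with p-values set.
#' @export
detect_significant <- function(catalog, params = detection_params()) {
  cs <- detect_clusters(catalog, params)
  cs <- attach_pvalues(cs, catalog, params)
  keep <- which(cs$p_value < params$alpha)
  members <- attr(cs, "members")[keep]
  out <- as.data.frame(cs)[keep, , drop = FALSE]
  if (nrow(out)) {
    out$cluster_id <- paste0("Cluster", seq_len(nrow(out)))
    names(members) <- out$cluster_id
  }
  rownames(out) <- NULL
  structure(out, members = members, params = params,
            catalog_label = attr(cs, "catalog_label"),
            class = c("cluster_set", "data.frame"))
}

#' Cluster counts across a sweep of distance thresholds
#'
#' Re-runs detection at each threshold (15-80 kb in 5 kb steps mirrors the
#' original sweep) with a shared seed and tabulates how many clusters and
#' clustered genes each threshold yields, plus a cluster-size histogram
#' (quadruplets, quintuplets, ...).
#'
#' @param catalog a [gene_catalog()].
#' @param thresholds ascending numeric vector of `max_gap_bp` values.
#' @param base_params a [detection_params()] supplying all other settings.
#' @param significant apply the permutation filter (default) or tabulate
#'   the raw run-finding output.
#' @return data.frame (`threshold`, `n_clusters`, `n_clustered_genes`)
#'   with the per-threshold size histograms in attribute
#'   `"size_histogram"` (a named list of named integer vectors).
#' @export
threshold_sweep <- function(catalog, thresholds,
                            base_params = detection_params(),
                            significant = TRUE) {
  stopifnot(all(thresholds > 0), !is.unsorted(thresholds))
  hist_list <- list()
  rows <- lapply(thresholds, function(d) {
    p <- base_params
    p$max_gap_bp <- d
    cs <- if (significant) detect_significant(catalog, p)
          else detect_clusters(catalog, p)
    sizes <- cs$size
    h <- table(factor(sizes, levels = sort(unique(sizes))))
    hist_list[[as.character(d)]] <<- setNames(as.integer(h), names(h))
    data.frame(threshold = d, n_clusters = nrow(cs),
               n_clustered_genes = sum(sizes))
  })
  out <- do.call(rbind, rows)
  attr(out, "size_histogram") <- hist_list
  out
}

#' Write a cluster set as BED + membership TSV
#'
#' Emits `<prefix>.bed` (one line per cluster; chrom/start/end = cluster
#' span in 0-based half-open coordinates, name = cluster_id, score =
#' -log10(p) capped at `score_cap`) and `<prefix>_members.tsv`
#' (`cluster_id`, `gene_id`, `rank_in_cluster`).
#'
#' @param cs a non-empty `cluster_set`.
#' @param path_prefix output prefix.
#' @param score_cap cap applied to -log10(p) (and used when p = 0).
#' @return invisibly, the two file paths.
#' @export
write_cluster_set <- function(cs, path_prefix, score_cap = 10) {
  if (nrow(cs) == 0L) stopf("empty cluster set")
  p <- cs$p_value
  score <- ifelse(is.na(p), 0, pmin(-log10(pmax(p, 10^(-score_cap))),
                                    score_cap))
  bed <- data.frame(cs$chrom,
                    format(cs$start, scientific = FALSE, trim = TRUE),
                    format(cs$end, scientific = FALSE, trim = TRUE),
                    cs$cluster_id, round(score, 3), ".")
  bed_path <- paste0(path_prefix, ".bed")
  tsv_path <- paste0(path_prefix, "_members.tsv")
  write.table(bed, bed_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(cluster_members(cs), tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(bed = bed_path, members = tsv_path))
}

#' Read a cluster membership TSV written by [write_cluster_set()]
#' @param path membership TSV path.
#' @return data.frame (`cluster_id`, `gene_id`, `rank_in_cluster`).
#' @export
read_cluster_members <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("cluster_id", "gene_id", "rank_in_cluster")
  if (!all(need %in% colnames(df))) stopf("not a cluster membership table")
  df[, need]
}
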