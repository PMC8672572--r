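#' Per-cluster conservation averages
#'
#' The conservation of a cluster is the unweighted mean of its members'
#' per-gene phastCons and phyloP means. Per-gene scores come either from a
#' 3-column table (`gene_id`, `phastcons_mean`, `phylop_mean`) or are
#' derived from a per-base track via [track_to_gene_scores()]. Members
#' without a score are skipped (never treated as zero) and the number of
#' contributing members is reported.
#'
#' @param scores data.frame with columns `gene_id`, `phastcons_mean`,
#'   `phylop_mean` (either score column may be absent).
#' @param cs a `cluster_set`.
#' @return data.frame (`cluster_id`, `mean_phastcons`, `mean_phylop`,
#'   `n_scored`); clusters with no scored member yield NA with a warning.
#' @export
cluster_conservation <- function(scores, cs) {
  stopifnot(is.data.frame(scores), "gene_id" %in% colnames(scores))
  members <- attr(cs, "members")
  pc <- setNames(scores$phastcons_mean %||% rep(NA_real_, nrow(scores)),
                 scores$gene_id)
  pp <- setNames(scores$phylop_mean %||% rep(NA_real_, nrow(scores)),
                 scores$gene_id)
  rows <- lapply(names(members), function(id) {
    g <- members[[id]]
    v_pc <- pc[g]; v_pp <- pp[g]
    n_scored <- sum(!is.na(v_pc) | !is.na(v_pp))
    if (n_scored == 0L) {
      warnf("cluster %s has no scored member", id)
    }
    data.frame(cluster_id = id,
               mean_phastcons = mean(v_pc, na.rm = TRUE),
               mean_phylop = mean(v_pp, na.rm = TRUE),
               n_scored = n_scored, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$mean_phastcons[is.nan(out$mean_phastcons)] <- NA_real_
  out$mean_phylop[is.nan(out$mean_phylop)] <- NA_real_
  out
}

#' Per-gene conservation means from a per-base track
#'
#' Averages a per-base score (bedGraph-style: `chrom`, `start`, `end`,
#' `score`, 0-based half-open intervals) over each gene's full span.
#' Missing bases are ignored; genes with no covered base get NA.
#'
#' @param track data.frame (`chrom`, `start`, `end`, `score`) or a
#'   bedGraph file path.
#' @param catalog a [gene_catalog()].
#' @param score_name output column name (default `"phastcons_mean"`).
#' @return data.frame (`gene_id`, `<score_name>`).
#' @export
track_to_gene_scores <- function(track, catalog,
                                 score_name = "phastcons_mean") {
  if (is.character(track)) {
    track <- read.delim(track, header = FALSE,
                        col.names = c("chrom", "start", "end", "score"))
  }
  vals <- vapply(seq_len(nrow(catalog)), function(i) {
    seg <- track[track$chrom == catalog$chrom[i], , drop = FALSE]
    if (nrow(seg) == 0L) return(NA_real_)
    ov_start <- pmax(seg$start, catalog$start[i])
    ov_end <- pmin(seg$end, catalog$end[i])
    w <- pmax(ov_end - ov_start, 0)
    if (sum(w) == 0) return(NA_real_)
    sum(seg$score * w) / sum(w)
  }, numeric(1))
  out <- data.frame(gene_id = catalog$gene_id, vals,
                    stringsAsFactors = FALSE)
  colnames(out)[2L] <- score_name
  out
}

#' miRNA target statistics per gene and per cluster
#'
#' From a merged interaction table, counts distinct targeting miRNAs per
#' gene, builds a bipartite (miRNA, member) edge list per cluster, and
#' counts "shared" miRNAs targeting at least two members of the same
#' cluster. Counts are invariant to duplicated interaction rows.
#'
#' @param inter interaction table (see [merge_interactions()]).
#' @param cs a `cluster_set`.
#' @param universe gene IDs over which per-gene counts are reported
#'   (genes without interactions get 0).
#' @return list: `gene_counts` (`gene_id`, `n_mirnas`, `in_cluster`),
#'   `edges` (`cluster_id`, `mirna_id`, `gene_id`), `cluster_summary`
#'   (`cluster_id`, `n_members`, `n_mirnas`, `n_shared_mirnas`).
#' @export
mirna_target_stats <- function(inter, cs, universe) {
  inter <- dedupe_interactions(inter)
  members <- attr(cs, "members")
  clustered <- unlist(members, use.names = FALSE)
  counts <- table(factor(inter$gene_id, levels = universe))
  gene_counts <- data.frame(gene_id = universe,
                            n_mirnas = as.integer(counts),
                            in_cluster = universe %in% clustered,
                            stringsAsFactors = FALSE)
  edges <- list(); summ <- list()
  for (id in names(members)) {
    sub <- inter[inter$gene_id %in% members[[id]], , drop = FALSE]
    if (nrow(sub)) {
      edges[[id]] <- data.frame(cluster_id = id, mirna_id = sub$mirna_id,
                                gene_id = sub$gene_id,
                                stringsAsFactors = FALSE)
    }
    per_mirna <- tapply(sub$gene_id, sub$mirna_id,
                        function(g) length(unique(g)))
    summ[[id]] <- data.frame(
      cluster_id = id, n_members = length(members[[id]]),
      n_mirnas = length(unique(sub$mirna_id)),
      n_shared_mirnas = sum(per_mirna >= 2L),
      stringsAsFactors = FALSE)
  }
  list(
    gene_counts = gene_counts,
    edges = if (length(edges)) do.call(rbind, c(edges,
      make.row.names = FALSE)) else
      data.frame(cluster_id = character(0), mirna_id = character(0),
                 gene_id = character(0)),
    cluster_summary = if (length(summ)) do.call(rbind, c(summ,
      make.row.names = FALSE)) else
      data.frame(cluster_id = character(0), n_members = integer(0),
                 n_mirnas = integer(0), n_shared_mirnas = integer(0))
  )
}

#' Write a bipartite cluster network as an edge-list TSV
#' @param edges edge data.frame from [mirna_target_stats()].
#' @param path output path.
#' @export
write_edge_list <- function(edges, path) {
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Copy-number gain/loss frequency per cluster member
#'
#' From GISTIC-style thresholded calls (integers in -2..2, genes x
#' samples), the gain frequency of a gene is the fraction of samples with
#' call > 0 and the loss frequency the fraction with call < 0 (all
#' samples of the cancer type as denominator). `high_level_only` restricts
#' gains to call = 2 and losses to call = -2. A per-cluster dispersion
#' statistic (the SD of member frequencies) quantifies how similar the
#' profiles of co-clustered genes are.
#'
#' @param cnv integer matrix, genes x samples, values in -2..2.
#' @param cs a `cluster_set`.
#' @param high_level_only count only high-level amplification/deletion.
#' @return list: `genes` (`gene_id`, `cluster_id`, `gain_freq`,
#'   `loss_freq`), `clusters` (`cluster_id`, `sd_gain`, `sd_loss`,
#'   `n_scored`).
#' @export
cnv_frequency <- function(cnv, cs, high_level_only = FALSE) {
  if (ncol(cnv) == 0L) stopf("CNV matrix has zero samples")
  if (any(cnv != round(cnv)) || any(abs(cnv) > 2)) {
    stopf("CNV calls must be integers in -2..2")
  }
  gain_cut <- if (high_level_only) 1 else 0
  loss_cut <- if (high_level_only) -1 else 0
  members <- attr(cs, "members")
  rows <- list(); crows <- list()
  for (id in names(members)) {
    g <- members[[id]]
    present <- intersect(g, rownames(cnv))
    gf <- lf <- setNames(rep(NA_real_, length(g)), g)
    if (length(present)) {
      sub <- cnv[present, , drop = FALSE]
      gf[present] <- rowSums(sub > gain_cut) / ncol(cnv)
      lf[present] <- rowSums(sub < loss_cut) / ncol(cnv)
    }
    rows[[id]] <- data.frame(gene_id = g, cluster_id = id,
                             gain_freq = unname(gf), loss_freq = unname(lf),
                             stringsAsFactors = FALSE)
    crows[[id]] <- data.frame(
      cluster_id = id,
      sd_gain = if (length(present) >= 2L) sd(gf[present]) else NA_real_,
      sd_loss = if (length(present) >= 2L) sd(lf[present]) else NA_real_,
      n_scored = length(present), stringsAsFactors = FALSE)
  }
  list(genes = do.call(rbind, c(rows, make.row.names = FALSE)),
       clusters = do.call(rbind, c(crows, make.row.names = FALSE)))
}

#' Assign gene-level CNV calls from SEG-format segments
#'
#' A simple gene-overlap caller for when thresholded gene-level calls are
#' unavailable: each gene receives the call of the segment covering its
#' midpoint (0 when no segment covers it).
#'
#' @param segments data.frame (`sample_id`, `chrom`, `start`, `end`,
#'   `call`) with integer calls in -2..2.
#' @param catalog a [gene_catalog()].
#' @return integer matrix genes x samples.
#' @export
segments_to_calls <- function(segments, catalog) {
  samples <- unique(segments$sample_id)
  mid <- (catalog$start + catalog$end) / 2
  m <- matrix(0L, nrow(catalog), length(samples),
              dimnames = list(catalog$gene_id, samples))
  for (s in samples) {
    seg <- segments[segments$sample_id == s, , drop = FALSE]
    for (i in seq_len(nrow(seg))) {
      hit <- catalog$chrom == seg$chrom[i] & mid >= seg$start[i] &
        mid < seg$end[i]
      m[hit, s] <- as.integer(seg$call[i])
    }
  }
  m
}
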