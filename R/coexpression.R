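#' Hypergeometric enrichment p-value for cluster/module overlap
#'
#' With K genes in the universe, M in a co-expression module, N in the
#' cluster and Y shared, the statistic is
#' \deqn{P = 1 - \sum_{t=0}^{Y} \frac{\binom{M}{t}\binom{K-M}{N-t}}{\binom{K}{N}}}
#' i.e. the upper-tail probability P(X > Y) for X hypergeometric — the sum
#' runs through t = Y and is then complemented, which is one count more
#' than the conventional P(X >= Y). Terms are accumulated in log space.
#' `tail = "geq"` gives the conventional test instead.
#'
#' @param K universe size; @param M module size; @param N cluster size;
#' @param Y shared gene count.
#' @param tail `"gt"` (default, P(X > Y)) or `"geq"` (P(X >= Y)).
#' @return p-value in `[0, 1]`.
#' @export
hypergeometric_enrichment <- function(K, M, N, Y, tail = c("gt", "geq")) {
  tail <- match.arg(tail)
  stopifnot(is_count(K), is_count(M), is_count(N), is_count(Y))
  if (M > K || N > K) stopf("M and N must not exceed K")
  if (Y < 0 || Y > min(M, N)) stopf("Y must lie in [0, min(M, N)]")
  upper <- if (tail == "gt") Y else Y - 1L
  if (upper < 0) return(1)
  t <- 0:upper
  log_terms <- lchoose(M, t) + lchoose(K - M, N - t) - lchoose(K, N)
  log_terms <- log_terms[is.finite(log_terms)]
  if (length(log_terms) == 0L) return(1)
  mx <- max(log_terms)
  cdf <- exp(mx) * sum(exp(log_terms - mx))
  max(0, min(1, 1 - cdf))
}

#' Find the cluster-related co-expression module
#'
#' Scores every module that shares at least one gene with the cluster by
#' [hypergeometric_enrichment()] and selects the module with minimum p
#' (ties broken by larger overlap Y, then lexicographic label). The module
#' is cluster-related only when its overlap Y >= 2 and p <= 0.05; the
#' permutation q must additionally pass (see [module_permutation_q()]).
#'
#' @param members character vector of cluster member gene IDs (or a
#'   one-row `cluster_set` slice whose members are looked up).
#' @param modules named character vector: gene_id -> module label over the
#'   K-gene universe. Genes labelled `"unassigned"` count toward K but are
#'   never tested as a module.
#' @param p_threshold enrichment significance cutoff (default 0.05).
#' @param tail passed to [hypergeometric_enrichment()].
#' @return `NULL` when no module overlaps the cluster; otherwise a list
#'   with `module_label`, `K`, `M`, `N`, `Y`, `p`, `q_perm` (NA until
#'   computed) and `is_cluster_related`.
#' @export
cluster_related_module <- function(members, modules, p_threshold = 0.05,
                                   tail = "gt") {
  members <- unique(as.character(members))
  K <- length(modules)
  present <- members[members %in% names(modules)]
  if (length(present) < length(members)) {
    warnf("%d cluster member(s) absent from the module universe",
          length(members) - length(present))
  }
  N <- length(present)
  if (N == 0L) return(NULL)
  labels <- setdiff(unique(modules), "unassigned")
  sizes <- table(modules)
  hits <- table(factor(modules[present], levels = labels))
  cand <- labels[hits >= 1L]
  if (length(cand) == 0L) return(NULL)
  res <- data.frame(
    module_label = cand,
    M = as.integer(sizes[cand]),
    Y = as.integer(hits[cand]),
    stringsAsFactors = FALSE
  )
  res$p <- mapply(function(M, Y)
    hypergeometric_enrichment(K, M, N, Y, tail = tail), res$M, res$Y)
  ord <- order(res$p, -res$Y, res$module_label)
  best <- res[ord[1L], ]
  list(module_label = best$module_label, K = K, M = best$M, N = N,
       Y = best$Y, p = best$p, q_perm = NA_real_,
       is_cluster_related = best$Y >= 2L && best$p <= p_threshold)
}

# Minimum enrichment p over modules for an arbitrary gene set, under the
# Y >= 2 constraint used by the cluster-related-module rule; 1 when no
# module overlaps the set in >= 2 genes.
min_module_p <- function(genes, modules, labels, sizes, K, tail) {
  hits <- table(factor(modules[genes], levels = labels))
  cand <- labels[hits >= 2L]
  if (length(cand) == 0L) return(1)
  p <- mapply(function(M, Y)
    hypergeometric_enrichment(K, M, length(genes), Y, tail = tail),
    as.integer(sizes[cand]), as.integer(hits[cand]))
  min(p)
}

#' Permutation q-value for the cluster-related module
#'
#' Draws `n_perm` random gene sets of the cluster's size from the K-gene
#' universe and recomputes the minimum enrichment p over modules, subject
#' to the >= 2 overlap constraint (draws with no such module score p = 1).
#' q is the fraction of draws at least as extreme as the observed minimum.
#'
#' @inheritParams cluster_related_module
#' @param n_perm number of random draws (default 1000).
#' @param seed RNG seed.
#' @return q in `[0, 1]` on the grid k / n_perm.
#' @export
module_permutation_q <- function(members, modules, n_perm = 1000L,
                                 seed = 1L, tail = "gt") {
  obs <- cluster_related_module(members, modules, tail = tail)
  if (is.null(obs)) stopf("no candidate module for this cluster")
  labels <- setdiff(unique(modules), "unassigned")
  sizes <- table(modules)
  K <- length(modules)
  universe <- names(modules)
  set.seed(seed)
  hits <- vapply(seq_len(n_perm), function(i) {
    g <- sample(universe, obs$N)
    min_module_p(g, modules, labels, sizes, K, tail) <= obs$p
  }, logical(1))
  mean(hits)
}

pair_abs_cor <- function(x) {
  # x: members-by-samples; returns |r| for usable unordered pairs and the
  # number of pairs dropped for zero variance
  keep <- apply(x, 1L, function(v) sd(v) > 0)
  L <- nrow(x)
  total <- L * (L - 1) / 2
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 2L) {
    return(list(abs_r = numeric(0), n_pairs = 0L,
                n_dropped = as.integer(total)))
  }
  cm <- cor(t(x))
  vals <- abs(cm[upper.tri(cm)])
  list(abs_r = vals, n_pairs = length(vals),
       n_dropped = as.integer(total - length(vals)))
}

#' Mean absolute pairwise correlation of cluster members (mRc)
#'
#' mRc is the mean over all unordered member pairs of the absolute Pearson
#' correlation of their expression across the tumor samples of one cancer
#' type. Pairs involving a constant-expression gene are dropped (not set
#' to zero) and the usable pair count is reported.
#'
#' @param expr numeric genes-by-samples matrix (tumor samples of one
#'   cancer type).
#' @param members character vector of member gene IDs.
#' @param cancer_type label carried into the result.
#' @return list with `mrc`, `n_pairs`, `n_dropped`, `cancer_type`,
#'   `p_perm` (NA until [mrc_permutation_test()]).
#' @export
mean_abs_pcc <- function(expr, members, cancer_type = NA_character_) {
  members <- unique(as.character(members))
  present <- intersect(members, rownames(expr))
  if (length(present) < 2L) stopf("fewer than 2 cluster members in matrix")
  if (ncol(expr) < 3L) stopf("need at least 3 samples")
  pc <- pair_abs_cor(expr[present, , drop = FALSE])
  if (pc$n_pairs == 0L) stopf("no variance: all member pairs dropped")
  list(mrc = mean(pc$abs_r), n_pairs = pc$n_pairs,
       n_dropped = pc$n_dropped, cancer_type = cancer_type,
       p_perm = NA_real_, n_perm = NA_integer_, seed = NA_integer_)
}

#' Permutation test for the mRc co-expression score
#'
#' Samples `n_perm` random gene sets of the cluster's size from the rows
#' of `expr` (the expressed-gene universe) and recomputes mRc for each;
#' the p-value is the fraction of draws with mRc at least the observed.
#'
#' @inheritParams mean_abs_pcc
#' @param n_perm number of draws (default 1000).
#' @param seed RNG seed.
#' @return as [mean_abs_pcc()] with `p_perm`, `n_perm`, `seed` filled.
#' @export
mrc_permutation_test <- function(expr, members, n_perm = 1000L, seed = 1L,
                                 cancer_type = NA_character_) {
  obs <- mean_abs_pcc(expr, members, cancer_type)
  L <- length(intersect(unique(members), rownames(expr)))
  if (nrow(expr) < L) stopf("expression universe smaller than cluster")
  set.seed(seed)
  ge <- vapply(seq_len(n_perm), function(i) {
    g <- sample(rownames(expr), L)
    pc <- pair_abs_cor(expr[g, , drop = FALSE])
    if (pc$n_pairs == 0L) return(FALSE)
    mean(pc$abs_r) >= obs$mrc
  }, logical(1))
  obs$p_perm <- mean(ge)
  obs$n_perm <- as.integer(n_perm)
  obs$seed <- as.integer(seed)
  obs
}

#' Two-criterion co-expression call for a cluster
#'
#' A cluster is called co-expressed in a cancer type when both criteria
#' hold: (1) the mRc permutation p <= `p_threshold`, and (2) a
#' cluster-related module exists (overlap Y >= 2, enrichment p <=
#' `p_threshold`) with permutation q <= `q_threshold`.
#'
#' @param expr tumor expression matrix (genes x samples).
#' @param members cluster member gene IDs.
#' @param modules named gene -> module assignment (see
#'   [cluster_related_module()]).
#' @param n_perm permutation count shared by both sub-tests.
#' @param seed RNG seed (the module test uses `seed + 1`).
#' @param p_threshold,q_threshold thresholds, both 0.05 by default.
#' @param cancer_type label carried into the report.
#' @return list with `co_expressed` (logical, or NA when a sub-test is
#'   not assessable), `mrc` sub-report, `module` sub-report.
#' @export
call_coexpressed <- function(expr, members, modules, n_perm = 1000L,
                             seed = 1L, p_threshold = 0.05,
                             q_threshold = 0.05,
                             cancer_type = NA_character_) {
  mrc <- tryCatch(
    mrc_permutation_test(expr, members, n_perm, seed, cancer_type),
    error = function(e) NULL)
  mod <- cluster_related_module(members, modules, p_threshold)
  if (!is.null(mod) && mod$is_cluster_related) {
    mod$q_perm <- module_permutation_q(members, modules, n_perm,
                                       seed = derive_seed(seed, 1L))
    mod$is_cluster_related <- mod$is_cluster_related &&
      mod$q_perm <= q_threshold
  }
  if (is.null(mrc)) {
    return(list(co_expressed = NA, mrc = NULL, module = mod,
                cancer_type = cancer_type))
  }
  ok_mrc <- mrc$p_perm <= p_threshold
  ok_mod <- !is.null(mod) && mod$is_cluster_related
  list(co_expressed = ok_mrc && ok_mod, mrc = mrc, module = mod,
       cancer_type = cancer_type)
}

#' lincRNA-mRNA pairs passing an absolute-correlation filter
#'
#' Computes the Pearson correlation between every lincRNA row and every
#' mRNA row across the shared samples, separately within each sample
#' group (e.g. tumor and normal), and keeps pairs with |r| >=
#' `min_abs_pcc` (default 0.35).
#'
#' @param linc_expr,mrna_expr matrices sharing sample columns.
#' @param group named character vector sample_id -> group label; `NULL`
#'   treats all samples as one `"all"` group.
#' @param min_abs_pcc retention threshold on |r| (inclusive).
#' @return data.frame (`lincRNA`, `mRNA`, `r`, `group`).
#' @export
correlated_mrnas <- function(linc_expr, mrna_expr, group = NULL,
                             min_abs_pcc = 0.35) {
  if (!identical(colnames(linc_expr), colnames(mrna_expr))) {
    stopf("lincRNA and mRNA matrices must share sample columns")
  }
  if (is.null(group)) {
    group <- setNames(rep("all", ncol(linc_expr)), colnames(linc_expr))
  }
  out <- list()
  for (g in unique(group[colnames(linc_expr)])) {
    cols <- names(group)[group == g]
    cols <- intersect(cols, colnames(linc_expr))
    if (length(cols) < 3L) next
    r <- cor(t(linc_expr[, cols, drop = FALSE]),
             t(mrna_expr[, cols, drop = FALSE]))
    hit <- which(abs(r) >= min_abs_pcc & !is.na(r), arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    out[[g]] <- data.frame(
      lincRNA = rownames(r)[hit[, 1L]],
      mRNA = colnames(r)[hit[, 2L]],
      r = r[hit],
      group = g, stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) {
    return(data.frame(lincRNA = character(0), mRNA = character(0),
                      r = numeric(0), group = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
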