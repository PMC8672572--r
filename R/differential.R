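#' Per-gene tumor-vs-normal differential expression
#'
#' A plain two-group Welch t-test on log2(x + 1) per gene over the shared
#' gene universe; `log2fc` is the tumor-minus-normal difference of means
#' on the log scale. Externally computed tables (e.g. from a moderated
#' linear model) can be substituted anywhere a DE table is consumed, via
#' [read_de_table()].
#'
#' @param tumor,normal numeric genes-by-samples matrices with >= 2
#'   samples each; rows are matched by gene ID (intersection used).
#' @param p_threshold significance cutoff on the unadjusted p (default
#'   0.01).
#' @param log_transform apply log2(x + 1) first (default TRUE).
#' @param adjust optional p.adjust method applied before thresholding
#'   (`"none"` default).
#' @param lfc_threshold optional additional |log2fc| gate (default 0).
#' @return data.frame (`gene_id`, `log2fc`, `p`, `significant`).
#' @export
de_test <- function(tumor, normal, p_threshold = 0.01,
                    log_transform = TRUE, adjust = "none",
                    lfc_threshold = 0) {
  if (ncol(tumor) < 2L || ncol(normal) < 2L) {
    stopf("each group needs at least 2 samples")
  }
  genes <- intersect(rownames(tumor), rownames(normal))
  if (length(genes) == 0L) stopf("no shared genes between groups")
  tt <- tumor[genes, , drop = FALSE]
  nn <- normal[genes, , drop = FALSE]
  if (log_transform) {
    tt <- log2(tt + 1)
    nn <- log2(nn + 1)
  }
  res <- vapply(seq_along(genes), function(i) {
    x <- tt[i, ]; y <- nn[i, ]
    fc <- mean(x) - mean(y)
    if (sd(x) == 0 && sd(y) == 0) {
      return(c(fc, if (fc == 0) 1 else 0))
    }
    c(fc, t.test(x, y)$p.value)
  }, numeric(2))
  p <- p.adjust(res[2L, ], method = adjust)
  data.frame(gene_id = genes, log2fc = res[1L, ], p = p,
             significant = p < p_threshold & abs(res[1L, ]) >= lfc_threshold,
             stringsAsFactors = FALSE)
}

#' Read an externally computed differential-expression table
#' @param path TSV with columns `gene_id`, `log2fc`, `p`.
#' @param p_threshold cutoff defining `significant`.
#' @return data.frame in the [de_test()] layout.
#' @export
read_de_table <- function(path, p_threshold = 0.01) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "p")
  if (!all(need %in% colnames(df))) {
    stopf("DE table must have columns gene_id, log2fc, p")
  }
  df$significant <- df$p < p_threshold
  df[, c(need, "significant")]
}

#' Co-differential-expression label per cluster
#'
#' A cluster is co-differentially-expressed in a cancer type when strictly
#' more than half of its members are significant in the per-gene DE table.
#' Members missing from the table still count toward the denominator and
#' as non-DE (conservative toward the rule); clusters with no member in
#' the table at all are marked not assessable (`co_de = NA`).
#'
#' @param cs a `cluster_set`.
#' @param de a DE table from [de_test()] or [read_de_table()].
#' @param cancer_type label carried into the result.
#' @return data.frame (`cluster_id`, `cancer_type`, `n_members`, `n_de`,
#'   `co_de`).
#' @export
classify_co_de <- function(cs, de, cancer_type = NA_character_) {
  members <- attr(cs, "members")
  sig <- setNames(de$significant, de$gene_id)
  rows <- lapply(names(members), function(id) {
    g <- members[[id]]
    covered <- g %in% names(sig)
    n_de <- sum(sig[g[covered]], na.rm = TRUE)
    data.frame(cluster_id = id, cancer_type = cancer_type,
               n_members = length(g), n_de = as.integer(n_de),
               co_de = if (!any(covered)) NA else n_de > length(g) / 2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Common / unique specificity labels across cancer types
#'
#' Counts, for each cluster, the cancer types in which it is
#' co-differentially-expressed: exactly one makes it `"unique"`, two or
#' more `"common"`, none `"none"`. Not-assessable entries count as not
#' co-DE.
#'
#' @param labels data.frame rbind of per-cancer [classify_co_de()] outputs.
#' @return data.frame (`cluster_id`, `n_cancers_co_de`, `specificity`).
#' @export
label_specificity <- function(labels) {
  stopifnot(nrow(labels) >= 1L)
  co <- tapply(labels$co_de, labels$cluster_id,
               function(v) sum(v %in% TRUE))
  data.frame(
    cluster_id = names(co),
    n_cancers_co_de = as.integer(co),
    specificity = ifelse(co == 0L, "none",
                  ifelse(co == 1L, "unique", "common")),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
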