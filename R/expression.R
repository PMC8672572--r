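#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a header row of sample IDs and a first column of gene IDs, the
#' layout used by TANRIC- and Xena-style expression tables. Values must be
#' numeric and non-negative; missing cells are rejected.
#'
#' @param path TSV file path.
#' @param group optional named character vector (sample_id -> group label,
#'   e.g. cancer type or tumor/normal status) attached as the `"group"`
#'   attribute.
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
read_expression_matrix <- function(path, group = NULL) {
  raw <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (ncol(raw) < 2L) stopf("expression TSV needs gene column + samples")
  sample_ids <- colnames(raw)[-1L]
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) stopf("duplicated sample ID '%s'", dup[1])
  gene_ids <- as.character(raw[[1L]])
  dupg <- gene_ids[duplicated(gene_ids)]
  if (length(dupg)) stopf("duplicated gene ID '%s'", dupg[1])
  m <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    for (j in seq_len(ncol(m))) {
      v <- suppressWarnings(as.numeric(m[, j]))
      if (anyNA(v)) {
        i <- which(is.na(v))[1]
        stopf("non-numeric cell at gene '%s', sample '%s'",
              gene_ids[i], sample_ids[j])
      }
    }
    stopf("non-numeric expression matrix")
  }
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stopf("non-numeric cell at gene '%s', sample '%s'",
          gene_ids[idx[1]], sample_ids[idx[2]])
  }
  if (any(m < 0)) stopf("negative expression value")
  dimnames(m) <- list(gene_ids, sample_ids)
  if (!is.null(group)) attr(m, "group") <- group[sample_ids]
  m
}

#' Write an expression matrix as TSV
#' @param m numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep genes expressed above a threshold in enough samples
#'
#' A gene is retained when its value strictly exceeds `min_value` in at
#' least `min_samples` samples (default: > 0.1 in three or more samples,
#' i.e. "more than two"). Row order is preserved; the operation is
#' idempotent.
#'
#' @param m numeric genes-by-samples matrix.
#' @param min_value expression threshold (strict).
#' @param min_samples minimum number of samples exceeding the threshold.
#' @return the filtered matrix (possibly zero rows, with a warning).
#' @export
filter_expressed <- function(m, min_value = 0.1, min_samples = 3L) {
  stopifnot(min_value >= 0, min_samples >= 0)
  keep <- rowSums(m > min_value) >= min_samples
  out <- m[keep, , drop = FALSE]
  if (nrow(out) == 0L) warnf("no genes pass the expression filter")
  attr(out, "group") <- attr(m, "group")
  out
}
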