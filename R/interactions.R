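#' Read a miRNA-gene interaction table
#'
#' TSV with columns `mirna_id`, `gene_id` and optionally `source`; when
#' `source` is absent every pair is tagged with `default_source`.
#'
#' @param path TSV path.
#' @param default_source provenance tag used when the file has none.
#' @return data.frame with columns `mirna_id`, `gene_id`, `source`.
#' @export
read_interactions <- function(path, default_source = basename(path)) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("mirna_id", "gene_id")
  if (!all(need %in% colnames(df))) {
    stopf("interaction table must have columns mirna_id, gene_id")
  }
  if (!"source" %in% colnames(df)) df$source <- default_source
  interaction_table(df$mirna_id, df$gene_id, df$source)
}

#' Construct an interaction table
#' @param mirna_id,gene_id character vectors (non-empty entries).
#' @param source per-pair provenance tag.
#' @return deduplicated data.frame (`mirna_id`, `gene_id`, `source`); the
#'   source tags of exact duplicate pairs are concatenated with `","`.
#' @export
interaction_table <- function(mirna_id, gene_id, source = "unspecified") {
  mirna_id <- as.character(mirna_id)
  gene_id <- as.character(gene_id)
  if (any(!nzchar(mirna_id)) || any(!nzchar(gene_id))) {
    stopf("empty mirna_id or gene_id in interaction table")
  }
  df <- data.frame(mirna_id = mirna_id, gene_id = gene_id,
                   source = rep_len(as.character(source), length(mirna_id)),
                   stringsAsFactors = FALSE)
  dedupe_interactions(df)
}

dedupe_interactions <- function(df) {
  key <- paste(df$mirna_id, df$gene_id, sep = "\r")
  src <- vapply(split(df$source, key), function(s)
    paste(sort(unique(unlist(strsplit(s, ",", fixed = TRUE)))),
          collapse = ","), character(1))
  uniq <- !duplicated(key)
  out <- df[uniq, c("mirna_id", "gene_id"), drop = FALSE]
  out$source <- unname(src[paste(out$mirna_id, out$gene_id, sep = "\r")])
  out <- out[order(out$mirna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge several interaction tables into one comprehensive set
#'
#' Union of (miRNA, gene) pairs with exact-duplicate removal; provenance
#' tags of merged duplicates are concatenated. Commutative and associative
#' over pair sets.
#'
#' @param tables list of interaction tables (see [interaction_table()]).
#' @return a single deduplicated interaction table.
#' @export
merge_interactions <- function(tables) {
  stopifnot(length(tables) >= 1L)
  dedupe_interactions(do.call(rbind, tables))
}
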