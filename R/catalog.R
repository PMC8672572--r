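#' Construct a gene catalog
#'
#' A gene catalog is the substrate scanned for genomic clusters: one row per
#' gene with 0-based half-open coordinates, grouped by chromosome and sorted
#' by (start, end, gene_id). All coordinate conversion from 1-based inclusive
#' dialects (Ensembl TSV, GTF) happens at the I/O boundary, never downstream.
#'
#' @param gene_id character vector of unique stable gene identifiers.
#' @param chrom chromosome (or scaffold) name per gene, taken verbatim.
#' @param start,end integer gene span, 0-based half-open.
#' @param strand one of `"+"`, `"-"`, `"."` per gene.
#' @param name optional display name per gene (may be empty).
#' @param genome_build free-text label recorded on the catalog.
#' @return A `gene_catalog`: a data.frame with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `name`, sorted within chromosome.
#' @export
gene_catalog <- function(gene_id, chrom, start, end, strand = ".",
                         name = "", genome_build = "unspecified") {
  df <- data.frame(
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = rep_len(as.character(strand), length(gene_id)),
    name = rep_len(as.character(name), length(gene_id)),
    stringsAsFactors = FALSE
  )
  validate_catalog_rows(df)
  df <- df[order(df$chrom, df$start, df$end, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, genome_build = genome_build,
            class = c("gene_catalog", "data.frame"))
}

validate_catalog_rows <- function(df) {
  if (any(!nzchar(df$chrom))) stopf("empty chromosome name")
  bad <- which(df$start > df$end)
  if (length(bad)) {
    stopf("start > end for gene '%s'", df$gene_id[bad[1]])
  }
  if (any(df$start < 0)) stopf("negative start coordinate")
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup)) stopf("duplicate gene_id: '%s'", dup[1])
  ok <- df$strand %in% c("+", "-", ".")
  if (any(!ok)) stopf("invalid strand '%s'", df$strand[which(!ok)[1]])
  invisible(df)
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat(sprintf("gene_catalog: %d genes on %d chromosome(s) [%s]\n",
              nrow(x), length(unique(x$chrom)),
              attr(x, "genome_build") %||% "unspecified"))
  print(head(as.data.frame(x), 6L))
  invisible(x)
}

#' Read a gene catalog from Ensembl-style TSV, GTF, or BED6
#'
#' Ensembl biomart-style TSV and GTF carry 1-based inclusive coordinates and
#' are shifted to the internal 0-based half-open convention on read; BED6 is
#' already 0-based half-open and passes through unchanged. GTF parsing keeps
#' `gene` feature lines only.
#'
#' @param path file path.
#' @param format `"ensembl_tsv"`, `"gtf"`, or `"bed6"`.
#' @param genome_build label stored on the catalog.
#' @param chr_prefix `"none"` (verbatim, default), `"add"` (prepend `chr`
#'   where absent) or `"strip"` (remove a leading `chr`). Provided because
#'   Ensembl and UCSC resources disagree on chromosome naming.
#' @param primary_only drop scaffold/patch contigs, keeping only
#'   chromosomes named 1-22, X, Y, MT/M (with or without `chr`).
#' @return A [gene_catalog()].
#' @export
read_gene_catalog <- function(path,
                              format = c("ensembl_tsv", "gtf", "bed6"),
                              genome_build = "unspecified",
                              chr_prefix = c("none", "add", "strip"),
                              primary_only = FALSE) {
  format <- match.arg(format)
  chr_prefix <- match.arg(chr_prefix)
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- switch(format,
    ensembl_tsv = read_ensembl_tsv(path),
    gtf = read_gtf_genes(path),
    bed6 = read_bed6(path)
  )
  df$chrom <- apply_chr_prefix(df$chrom, chr_prefix)
  if (primary_only) {
    keep <- grepl("^(chr)?([0-9]{1,2}|X|Y|MT?)$", df$chrom)
    df <- df[keep, , drop = FALSE]
  }
  gene_catalog(df$gene_id, df$chrom, df$start, df$end, df$strand, df$name,
               genome_build = genome_build)
}

apply_chr_prefix <- function(chrom, mode) {
  switch(mode,
    none = chrom,
    add = ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom)),
    strip = sub("^chr", "", chrom)
  )
}

read_ensembl_tsv <- function(path) {
  raw <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 5L) stopf("ensembl_tsv needs >= 5 columns, got %d", ncol(raw))
  gene_id <- raw[[1L]]
  chrom <- raw[[2L]]
  start1 <- suppressWarnings(as.numeric(raw[[3L]]))
  end1 <- suppressWarnings(as.numeric(raw[[4L]]))
  bad <- which(is.na(start1) | is.na(end1))
  if (length(bad)) {
    stopf("malformed coordinate at line %d of %s", bad[1] + 1L, path)
  }
  strand <- normalize_strand(raw[[5L]])
  name <- if (ncol(raw) >= 6L) raw[[6L]] else ""
  # 1-based inclusive -> 0-based half-open
  data.frame(gene_id = gene_id, chrom = chrom, start = start1 - 1,
             end = end1, strand = strand, name = name,
             stringsAsFactors = FALSE)
}

normalize_strand <- function(s) {
  out <- ifelse(s %in% c("+", "1"), "+",
         ifelse(s %in% c("-", "-1"), "-", "."))
  out
}

read_gtf_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if ("type" %in% colnames(md)) gr <- gr[md$type == "gene"]
  md <- S4Vectors::mcols(gr)
  if (!"gene_id" %in% colnames(md)) stopf("GTF lacks gene_id attribute")
  name <- if ("gene_name" %in% colnames(md)) {
    ifelse(is.na(md$gene_name), "", md$gene_name)
  } else ""
  # GRanges is 1-based inclusive
  data.frame(
    gene_id = md$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
    name = name,
    stringsAsFactors = FALSE
  )
}

read_bed6 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  md <- S4Vectors::mcols(gr)
  gene_id <- if ("name" %in% colnames(md)) md$name else
    paste0("bed_", seq_along(gr))
  data.frame(
    gene_id = gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
    name = gene_id,
    stringsAsFactors = FALSE
  )
}

#' Write a gene catalog as Ensembl-style TSV
#'
#' Inverse of `read_gene_catalog(format = "ensembl_tsv")`: internal 0-based
#' half-open coordinates are shifted back to 1-based inclusive, so a
#' read/write round trip reproduces the original integers exactly.
#'
#' @param catalog a [gene_catalog()].
#' @param path output file path.
#' @export
write_gene_catalog <- function(catalog, path) {
  out <- data.frame(
    `Gene stable ID` = catalog$gene_id,
    `Chromosome/scaffold name` = catalog$chrom,
    `Gene start (bp)` = format(catalog$start + 1, scientific = FALSE,
                               trim = TRUE),
    `Gene end (bp)` = format(catalog$end, scientific = FALSE, trim = TRUE),
    Strand = catalog$strand,
    `Gene name` = catalog$name,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
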