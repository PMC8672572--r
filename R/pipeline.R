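#' Run the full cluster-analysis pipeline from one configuration
#'
#' Orchestrates detect -> characterize -> co-expression -> differential
#' expression -> survival from a single configuration (a YAML file path
#' or an equivalent named list). Stages whose inputs are absent are
#' skipped with a notice; a machine-readable manifest records parameters,
#' the seed, input checksums and per-stage output row counts. Reruns with
#' the same configuration are byte-identical.
#'
#' Recognised configuration keys: `annotation` (+ `annotation_format`),
#' `tumor_expr`, `normal_expr`, `modules`, `interactions`, `conservation`,
#' `cnv`, `clinical`, `out_dir`, `seed`, `max_gap_bp`, `min_size`,
#' `n_perm`, `alpha`, `p_de`, `min_abs_pcc`, `cancer_type`.
#'
#' @param config YAML path or named list.
#' @param overrides named list applied on top of the config (CLI flags).
#' @return invisibly, the manifest list (also written as
#'   `manifest.json` in `out_dir`).
#' @export
run_pipeline <- function(config, overrides = list()) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg[names(overrides)] <- overrides
  if (is.null(cfg$annotation)) stopf("config needs 'annotation'")
  if (is.null(cfg$out_dir)) stopf("config needs 'out_dir'")
  seed <- as.integer(cfg$seed %||% 1L)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cancer_type <- cfg$cancer_type %||% "CANCER"

  inputs <- unlist(cfg[intersect(names(cfg),
    c("annotation", "tumor_expr", "normal_expr", "modules",
      "interactions", "conservation", "cnv", "clinical"))])
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in)) {
    stopf("input file(s) not found: %s", paste(missing_in, collapse = ", "))
  }
  manifest <- list(
    tool = "lincluster",
    version = as.character(utils::packageVersion("lincluster")),
    seed = seed,
    params = cfg[setdiff(names(cfg), "out_dir")],
    input_md5 = as.list(tools::md5sum(inputs)),
    stages = list()
  )
  note <- function(...) message(sprintf(...))

  params <- detection_params(
    max_gap_bp = cfg$max_gap_bp %||% 60000,
    min_size = cfg$min_size %||% 4L,
    n_perm = cfg$n_perm %||% 1000L,
    alpha = cfg$alpha %||% 0.005,
    seed = seed)
  note("detect: max_gap=%d min_size=%d n_perm=%d alpha=%g seed=%d",
       params$max_gap_bp, params$min_size, params$n_perm, params$alpha,
       seed)
  catalog <- read_gene_catalog(cfg$annotation,
                               format = cfg$annotation_format %||%
                                 "ensembl_tsv")
  cs <- detect_significant(catalog, params)
  if (nrow(cs)) {
    write_cluster_set(cs, file.path(out_dir, "clusters"))
  }
  manifest$stages$detect <- list(n_clusters = nrow(cs),
                                 n_clustered_genes = sum(cs$size))

  if (!is.null(cfg$conservation) && nrow(cs)) {
    scores <- read.delim(cfg$conservation, stringsAsFactors = FALSE)
    cons <- suppressWarnings(cluster_conservation(scores, cs))
    write.table(cons, file.path(out_dir, "conservation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest$stages$conservation <- list(n_rows = nrow(cons))
  } else note("conservation: skipped (no input)")

  if (!is.null(cfg$interactions) && nrow(cs)) {
    inter <- read_interactions(cfg$interactions)
    mt <- mirna_target_stats(inter, cs, catalog$gene_id)
    write_edge_list(mt$edges, file.path(out_dir, "mirna_edges.tsv"))
    write.table(mt$cluster_summary,
                file.path(out_dir, "mirna_cluster_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$mirna <- list(n_edges = nrow(mt$edges))
  } else note("mirna: skipped (no input)")

  if (!is.null(cfg$cnv) && nrow(cs)) {
    raw <- read.delim(cfg$cnv, check.names = FALSE,
                      stringsAsFactors = FALSE)
    cnv <- as.matrix(raw[, -1L, drop = FALSE])
    rownames(cnv) <- raw[[1L]]
    fr <- cnv_frequency(cnv, cs)
    write.table(fr$genes, file.path(out_dir, "cnv_frequency.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$cnv <- list(n_rows = nrow(fr$genes))
  } else note("cnv: skipped (no input)")

  tumor <- NULL
  if (!is.null(cfg$tumor_expr)) {
    tumor <- filter_expressed(read_expression_matrix(cfg$tumor_expr))
  }

  if (!is.null(tumor) && !is.null(cfg$modules) && nrow(cs)) {
    mod_df <- read.delim(cfg$modules, stringsAsFactors = FALSE)
    modules <- setNames(mod_df$module_label, mod_df$gene_id)
    members <- attr(cs, "members")
    rows <- lapply(names(members), function(id) {
      r <- call_coexpressed(tumor, members[[id]], modules,
                            n_perm = params$n_perm,
                            seed = derive_seed(seed, match(id,
                                                           names(members))),
                            cancer_type = cancer_type)
      data.frame(
        cluster_id = id, cancer_type = cancer_type,
        mrc = r$mrc$mrc %||% NA_real_,
        p_perm = r$mrc$p_perm %||% NA_real_,
        module = r$module$module_label %||% NA_character_,
        K = r$module$K %||% NA_integer_, M = r$module$M %||% NA_integer_,
        N = r$module$N %||% NA_integer_, Y = r$module$Y %||% NA_integer_,
        p_module = r$module$p %||% NA_real_,
        q_perm = r$module$q_perm %||% NA_real_,
        co_expressed = r$co_expressed, stringsAsFactors = FALSE)
    })
    coex <- do.call(rbind, c(rows, make.row.names = FALSE))
    write.table(coex, file.path(out_dir, "coexpr_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest$stages$coexpr <- list(n_rows = nrow(coex))
  } else note("coexpr: skipped (needs tumor_expr + modules)")

  if (!is.null(tumor) && !is.null(cfg$normal_expr) && nrow(cs)) {
    normal <- read_expression_matrix(cfg$normal_expr)
    de <- de_test(tumor, normal, p_threshold = cfg$p_de %||% 0.01)
    lab <- classify_co_de(cs, de, cancer_type)
    spec_lab <- label_specificity(lab)
    write.table(de, file.path(out_dir, "de_genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(lab, file.path(out_dir, "cluster_de_labels.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(spec_lab, file.path(out_dir, "cluster_specificity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$diffexpr <- list(n_genes = nrow(de),
                                     n_co_de = sum(lab$co_de %in% TRUE))
  } else note("diffexpr: skipped (needs tumor_expr + normal_expr)")

  if (!is.null(tumor) && !is.null(cfg$clinical) && nrow(cs)) {
    surv <- read_survival_table(cfg$clinical)
    rep_ <- cluster_survival_report(
      cs, setNames(list(tumor), cancer_type),
      setNames(list(surv), cancer_type))
    write.table(rep_, file.path(out_dir, "survival_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$survival <- list(n_rows = nrow(rep_))
  } else note("survival: skipped (needs tumor_expr + clinical)")

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}
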