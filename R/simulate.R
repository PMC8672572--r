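#' Configuration for the synthetic-data generator
#'
#' Defaults describe the regime the detector is designed for: a diffuse
#' genomic background (mean intergenic gap 600 kb, ten times the 60 kb
#' detection threshold) with planted compact clusters whose internal gaps
#' stay below 30 kb, log-normal gene lengths, a shared latent expression
#' factor giving within-cluster correlation 0.8, tumor shifts of 2 log2
#' units for differentially expressed genes, and 30% censoring.
#'
#' The default chromosome holds 20 background genes: with exponential
#' gaps of mean 600 kb, the chance that three consecutive background gaps
#' all fall below a 60 kb threshold is (1 - exp(-0.1))^3, so a catalog of
#' 3 x 17 gap triples carries under a 5% chance of any spurious compact
#' quadruplet — background detections are then the exception, keeping the
#' planted memberships an unambiguous ground truth. Larger catalogs need
#' proportionally wider background gaps for the same guarantee.
#'
#' @param n_chromosomes number of background chromosomes.
#' @param genes_per_chromosome background genes per chromosome.
#' @param background_gap_mean mean intergenic gap (bp) of the background
#'   renewal process.
#' @param planted_clusters list of `list(chrom=, size=, max_internal_gap=)`
#'   entries; internal gaps are drawn uniformly in `[1, max_internal_gap]`.
#' @param flank_gap_bp gap separating a planted block from background
#'   genes (default 300 kb, five times the usual detection threshold, so
#'   detection ground truth is unambiguous).
#' @param gene_length_meanlog,gene_length_sdlog log-normal gene lengths.
#' @param coexpr_rho latent-scale pairwise correlation of co-cluster
#'   members.
#' @param de_effect tumor shift in log2 units for DE genes.
#' @param de_fraction fraction of background genes made DE.
#' @param de_clusters indices of planted clusters whose members are all DE.
#' @param module_leakage fraction of planted-cluster members reassigned
#'   out of their module.
#' @param surv_betas named numeric vector (gene_id -> log-hazard
#'   coefficient) or NULL.
#' @param censor_rate target average censoring fraction.
#' @param n_tumor,n_normal sample counts.
#' @param mirna_rate mean distinct targeting miRNAs per background gene.
#' @param mirna_ratio rate multiplier for clustered genes.
#' @param n_mirnas miRNA pool size.
#' @param cnv_event_fraction fraction of samples carrying a cluster-wide
#'   CNV event.
#' @param cnv_background_rate per-gene-per-sample rate of sporadic calls.
#' @param seed master seed (mandatory).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_chromosomes = 3L,
                              genes_per_chromosome = 20L,
                              background_gap_mean = 6e5,
                              planted_clusters = list(),
                              flank_gap_bp = 3e5,
                              gene_length_meanlog = log(1e4),
                              gene_length_sdlog = 0.8,
                              coexpr_rho = 0.8,
                              de_effect = 2,
                              de_fraction = 0.1,
                              de_clusters = integer(0),
                              module_leakage = 0,
                              surv_betas = NULL,
                              censor_rate = 0.3,
                              n_tumor = 100L,
                              n_normal = 50L,
                              mirna_rate = 2,
                              mirna_ratio = 2,
                              n_mirnas = 200L,
                              cnv_event_fraction = 0.3,
                              cnv_background_rate = 0.05,
                              seed) {
  if (missing(seed)) stopf("simulation seed is mandatory")
  stopifnot(background_gap_mean > 0, flank_gap_bp > 0,
            coexpr_rho >= 0, coexpr_rho < 1,
            de_fraction >= 0, de_fraction <= 1,
            censor_rate >= 0, censor_rate < 1,
            cnv_event_fraction >= 0, cnv_event_fraction <= 1)
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a gene catalog with planted compact clusters
#'
#' Background gene starts follow a renewal process (exponential gaps with
#' the configured mean); planted clusters are inserted as consecutive
#' blocks with internal gaps uniform in `[1, max_internal_gap]`,
#' separated from the background by `flank_gap_bp` on both sides. Gene
#' lengths are log-normal. The output is coordinate-sorted and
#' collision-free by construction (insertions shift downstream genes).
#'
#' @param cfg a [simulation_config()].
#' @return list with `catalog` (a [gene_catalog()]) and `truth` (ground
#'   truth bookkeeping: planted memberships plus the config).
#' @export
simulate_catalog <- function(cfg) {
  set.seed(derive_seed(cfg$seed, 101L))
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  rows <- list()
  planted <- list()
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    n_bg <- cfg$genes_per_chromosome
    gaps <- rexp(n_bg, rate = 1 / cfg$background_gap_mean)
    lens <- round(rlnorm(n_bg, cfg$gene_length_meanlog,
                         cfg$gene_length_sdlog))
    starts <- cumsum(gaps + c(0, lens[-n_bg]))
    starts <- round(starts) + 1000
    df <- data.frame(
      gene_id = sprintf("BG_%s_%03d", ch, seq_len(n_bg)),
      chrom = ch, start = starts, end = starts + lens,
      strand = sample(c("+", "-"), n_bg, replace = TRUE),
      stringsAsFactors = FALSE)
    plants_here <- which(vapply(cfg$planted_clusters,
                                function(p) p$chrom == ch, logical(1)))
    for (k in plants_here) {
      p <- cfg$planted_clusters[[k]]
      # insert only after a background gene so earlier planted blocks on
      # the same chromosome are never split
      cand <- grep("^BG_", df$gene_id)
      cand <- cand[cand < nrow(df)]
      ins <- cand[sample.int(length(cand), 1L)]
      block_start <- df$end[ins] + cfg$flank_gap_bp
      L <- p$size
      blens <- round(rlnorm(L, cfg$gene_length_meanlog,
                            cfg$gene_length_sdlog))
      bgaps <- round(runif(L - 1L, 1, p$max_internal_gap))
      bstart <- block_start + cumsum(c(0, blens[-L] + bgaps))
      block <- data.frame(
        gene_id = sprintf("PL%d_%02d", k, seq_len(L)),
        chrom = ch, start = bstart, end = bstart + blens,
        strand = sample(c("+", "-"), L, replace = TRUE),
        stringsAsFactors = FALSE)
      shift <- (max(block$end) + cfg$flank_gap_bp) - df$end[ins]
      after <- seq_len(nrow(df)) > ins
      df$start[after] <- df$start[after] + shift
      df$end[after] <- df$end[after] + shift
      df <- rbind(df[!after, ], block, df[after, ])
      planted[[length(planted) + 1L]] <- list(
        index = k, chrom = ch, size = L, members = block$gene_id)
    }
    rows[[ci]] <- df
  }
  all_rows <- do.call(rbind, rows)
  catalog <- gene_catalog(all_rows$gene_id, all_rows$chrom,
                          all_rows$start, all_rows$end, all_rows$strand,
                          genome_build = "synthetic")
  truth <- list(planted = planted, config = cfg)
  list(catalog = catalog, truth = truth)
}

#' Simulate tumor and normal expression with planted structure
#'
#' Members of the same planted cluster share a per-sample latent factor,
#' giving pairwise latent-scale correlation `coexpr_rho`; all latent
#' values are exponentiated (base 2) to a non-negative RPKM-like scale,
#' so the induced Pearson correlation on the expression scale is slightly
#' shrunk relative to the latent target. DE genes (a random background
#' fraction plus all members of `de_clusters`) are shifted by `de_effect`
#' log2 units in tumor samples. Module labels place each planted cluster
#' inside its own module (padded with random background genes, with
#' optional leakage); remaining genes are spread over background modules.
#'
#' @param catalog catalog from [simulate_catalog()].
#' @param truth ground truth from [simulate_catalog()] (updated in the
#'   return value).
#' @param cfg the same [simulation_config()].
#' @return list: `tumor`, `normal` (matrices), `modules` (named vector
#'   gene -> module label), `truth` (with `de_genes` and `modules` added).
#' @export
simulate_expression <- function(catalog, truth, cfg) {
  set.seed(derive_seed(cfg$seed, 202L))
  genes <- catalog$gene_id
  G <- length(genes)
  n <- cfg$n_tumor + cfg$n_normal
  z <- matrix(rnorm(G * n), G, n, dimnames = list(genes, NULL))
  for (p in truth$planted) {
    f <- rnorm(n)
    idx <- match(p$members, genes)
    z[idx, ] <- sqrt(cfg$coexpr_rho) * matrix(f, length(idx), n,
                                              byrow = TRUE) +
      sqrt(1 - cfg$coexpr_rho) * z[idx, ]
  }
  planted_members <- unlist(lapply(truth$planted, `[[`, "members"))
  bg <- setdiff(genes, planted_members)
  de_genes <- sample(bg, round(cfg$de_fraction * length(bg)))
  for (k in cfg$de_clusters) {
    hit <- vapply(truth$planted, function(p) p$index == k, logical(1))
    de_genes <- union(de_genes,
                      unlist(lapply(truth$planted[hit], `[[`, "members")))
  }
  # latent log2 scale: baseline 3, sd 1; tumor shift for DE genes
  log2x <- 3 + z
  is_tumor <- c(rep(TRUE, cfg$n_tumor), rep(FALSE, cfg$n_normal))
  log2x[de_genes, is_tumor] <- log2x[de_genes, is_tumor] + cfg$de_effect
  vals <- 2^log2x
  colnames(vals) <- c(sprintf("T%03d", seq_len(cfg$n_tumor)),
                      sprintf("N%03d", seq_len(cfg$n_normal)))
  tumor <- vals[, is_tumor, drop = FALSE]
  normal <- vals[, !is_tumor, drop = FALSE]
  modules <- setNames(rep("unassigned", G), genes)
  for (p in truth$planted) {
    lab <- paste0("M", p$index)
    mem <- p$members
    if (cfg$module_leakage > 0) {
      drop_n <- floor(cfg$module_leakage * length(mem))
      if (drop_n > 0) mem <- mem[-sample.int(length(mem), drop_n)]
    }
    pad <- sample(setdiff(bg, names(modules)[modules != "unassigned"]),
                  2L * p$size)
    modules[c(mem, pad)] <- lab
  }
  free <- names(modules)[modules == "unassigned"]
  filler <- sample(paste0("B", 1:5), length(free), replace = TRUE)
  modules[free] <- filler
  truth$de_genes <- de_genes
  truth$modules <- modules
  list(tumor = tumor, normal = normal, modules = modules, truth = truth)
}

#' Simulate overall survival driven by expression
#'
#' Event times are exponential with hazard proportional to
#' `exp(sum(beta * x))`, where x is the z-scored log2(x + 1) tumor
#' expression of the genes named in `surv_betas`. Censoring times are
#' independent uniform on `[0, c_max]`, with `c_max` solved numerically
#' so the expected censoring fraction matches `censor_rate`.
#'
#' @param tumor tumor expression matrix.
#' @param truth ground truth list (updated).
#' @param cfg the [simulation_config()]; `surv_betas` may be NULL for a
#'   null simulation.
#' @return list: `surv` (a [survival_table()]), `truth`.
#' @export
simulate_survival <- function(tumor, truth, cfg) {
  set.seed(derive_seed(cfg$seed, 303L))
  n <- ncol(tumor)
  lp <- rep(0, n)
  betas <- cfg$surv_betas
  if (!is.null(betas) && length(betas)) {
    genes <- intersect(names(betas), rownames(tumor))
    x <- log2(tumor[genes, , drop = FALSE] + 1)
    x <- (x - rowMeans(x)) / apply(x, 1L, sd)
    lp <- drop(crossprod(x, betas[genes]))
  }
  base_rate <- 1 / 1000  # median ~693 days at lp = 0
  T_ <- rexp(n, rate = base_rate * exp(lp))
  if (cfg$censor_rate <= 0) {
    time <- T_; event <- rep(1L, n)
  } else {
    # E[P(C < T)] with C ~ U(0, cmax): mean(pmin(T/cmax, 1))... censoring
    # occurs when C < T, so solve mean over samples for cmax.
    f <- function(cmax) mean(pmin(T_ / cmax, 1)) - cfg$censor_rate
    cmax <- uniroot(f, c(min(T_) / 2, max(T_) * 50),
                    extendInt = "downX")$root
    C_ <- runif(n, 0, cmax)
    time <- pmin(T_, C_)
    event <- as.integer(T_ <= C_)
  }
  surv <- survival_table(colnames(tumor), round(time, 2), event)
  truth$surv_betas <- betas
  list(surv = surv, truth = truth)
}

#' Simulate miRNA interactions and CNV calls with cluster structure
#'
#' Clustered genes receive distinct targeting miRNAs at `mirna_ratio`
#' times the background Poisson rate, plus explicitly shared miRNAs that
#' target two or more members of the same planted cluster. CNV events
#' span whole planted clusters in a `cnv_event_fraction` of tumor
#' samples (a random gain or loss per cluster), on top of sporadic
#' background calls, so co-clustered members share gain/loss frequencies.
#'
#' @param catalog catalog from [simulate_catalog()].
#' @param truth ground truth (updated with the CNV event map).
#' @param cfg the [simulation_config()].
#' @return list: `interactions` (interaction table), `cnv` (genes x
#'   samples integer matrix), `truth`.
#' @export
simulate_interactions_and_cnv <- function(catalog, truth, cfg) {
  set.seed(derive_seed(cfg$seed, 404L))
  genes <- catalog$gene_id
  pool <- sprintf("miR-%03d", seq_len(cfg$n_mirnas))
  planted_members <- unlist(lapply(truth$planted, `[[`, "members"))
  rate <- ifelse(genes %in% planted_members,
                 cfg$mirna_rate * cfg$mirna_ratio, cfg$mirna_rate)
  counts <- rpois(length(genes), rate)
  mi <- list()
  for (i in seq_along(genes)) {
    if (counts[i] > 0) {
      mi[[length(mi) + 1L]] <- data.frame(
        mirna_id = sample(pool, min(counts[i], length(pool))),
        gene_id = genes[i], source = "simulated",
        stringsAsFactors = FALSE)
    }
  }
  for (p in truth$planted) {
    if (p$size < 2L) next
    shared <- sample(pool, 3L)
    for (m in shared) {
      targets <- sample(p$members, max(2L, ceiling(p$size / 2)))
      mi[[length(mi) + 1L]] <- data.frame(
        mirna_id = m, gene_id = targets, source = "simulated_shared",
        stringsAsFactors = FALSE)
    }
  }
  inter <- dedupe_interactions(do.call(rbind, mi))
  n <- cfg$n_tumor
  cnv <- matrix(0L, length(genes), n,
                dimnames = list(genes, sprintf("T%03d", seq_len(n))))
  sporadic <- matrix(rbinom(length(genes) * n, 1,
                            cfg$cnv_background_rate) *
                       sample(c(-1L, 1L), length(genes) * n,
                              replace = TRUE),
                     length(genes), n)
  cnv[] <- sporadic
  events <- list()
  for (p in truth$planted) {
    sign_ <- sample(c(1L, -1L), 1L)
    hit <- which(runif(n) < cfg$cnv_event_fraction)
    cnv[p$members, hit] <- sign_
    events[[length(events) + 1L]] <- list(index = p$index, sign = sign_,
                                          samples = colnames(cnv)[hit])
  }
  truth$cnv_events <- events
  list(interactions = inter, cnv = cnv, truth = truth)
}

#' Run the full generator and write every input format to disk
#'
#' Convenience wrapper producing a complete, re-parseable fixture set:
#' catalog TSV, tumor/normal expression TSVs, module TSV, interaction
#' TSV, CNV TSV, clinical TSV, and `ground_truth.json`.
#'
#' @param cfg a [simulation_config()].
#' @param out_dir output directory (created).
#' @return invisibly, a named vector of file paths plus the in-memory
#'   objects as attribute `"objects"`.
#' @export
simulate_all <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cat_res <- simulate_catalog(cfg)
  expr <- simulate_expression(cat_res$catalog, cat_res$truth, cfg)
  surv <- simulate_survival(expr$tumor, expr$truth, cfg)
  ic <- simulate_interactions_and_cnv(cat_res$catalog, surv$truth, cfg)
  truth <- ic$truth
  paths <- c(
    catalog = file.path(out_dir, "catalog.tsv"),
    tumor = file.path(out_dir, "tumor_expr.tsv"),
    normal = file.path(out_dir, "normal_expr.tsv"),
    modules = file.path(out_dir, "modules.tsv"),
    interactions = file.path(out_dir, "interactions.tsv"),
    cnv = file.path(out_dir, "cnv_calls.tsv"),
    clinical = file.path(out_dir, "clinical.tsv"),
    truth = file.path(out_dir, "ground_truth.json"))
  write_gene_catalog(cat_res$catalog, paths["catalog"])
  write_expression_matrix(expr$tumor, paths["tumor"])
  write_expression_matrix(expr$normal, paths["normal"])
  write.table(data.frame(gene_id = names(expr$modules),
                         module_label = unname(expr$modules)),
              paths["modules"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(ic$interactions, paths["interactions"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene_id = rownames(ic$cnv), ic$cnv,
                         check.names = FALSE),
              paths["cnv"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = surv$surv$sample_id,
                         OS_days = surv$surv$time,
                         OS_event = surv$surv$event),
              paths["clinical"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth_json <- truth
  truth_json$config <- unclass(cfg)
  jsonlite::write_json(truth_json, paths["truth"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  objects <- list(catalog = cat_res$catalog, tumor = expr$tumor,
                  normal = expr$normal, modules = expr$modules,
                  interactions = ic$interactions, cnv = ic$cnv,
                  surv = surv$surv, truth = truth)
  invisible(structure(paths, objects = objects))
}
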