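#' Read a clinical survival table
#' @param path TSV with columns `sample_id`, `OS_days`, `OS_event`
#'   (event coded 0/1).
#' @return data.frame (`sample_id`, `time`, `event`).
#' @export
read_survival_table <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "OS_days", "OS_event")
  if (!all(need %in% colnames(df))) {
    stopf("survival table must have columns sample_id, OS_days, OS_event")
  }
  survival_table(df$sample_id, df$OS_days, df$OS_event)
}

#' Construct a survival table
#' @param sample_id unique sample identifiers.
#' @param time non-negative follow-up times (days).
#' @param event 0 = censored, 1 = death observed.
#' @return data.frame (`sample_id`, `time`, `event`).
#' @export
survival_table <- function(sample_id, time, event) {
  if (any(duplicated(sample_id))) stopf("duplicate sample_id")
  if (any(time < 0)) stopf("negative survival time")
  if (!all(event %in% c(0, 1))) stopf("event must be 0/1")
  data.frame(sample_id = as.character(sample_id), time = as.numeric(time),
             event = as.integer(event), stringsAsFactors = FALSE)
}

# log2(x+1) then per-gene z-score, restricted to the given samples; genes
# with zero variance come back as NULL entries.
prepare_covariates <- function(expr, genes, samples, log_transform = TRUE) {
  x <- expr[genes, samples, drop = FALSE]
  if (log_transform) x <- log2(x + 1)
  sds <- apply(x, 1L, sd)
  keep <- sds > 0
  x <- x[keep, , drop = FALSE]
  x <- (x - rowMeans(x)) / apply(x, 1L, sd)
  list(z = x, dropped = genes[!keep])
}

#' Median split of a risk score with log-rank comparison
#'
#' Samples at or below the median risk go to the low-risk group (a fixed,
#' deterministic tie rule); group sizes differ by at most one when scores
#' are distinct. Group assignment is invariant under any strictly
#' monotone transform of the score.
#'
#' @param risk named numeric vector (sample_id -> risk score).
#' @param surv a [survival_table()] covering those samples.
#' @return list with `group` (factor low/high per sample), `split_value`,
#'   `logrank_p`.
#' @export
median_split_logrank <- function(risk, surv) {
  surv <- surv[match(names(risk), surv$sample_id), , drop = FALSE]
  med <- median(risk)
  grp <- factor(ifelse(risk <= med, "low", "high"),
                levels = c("low", "high"))
  if (length(unique(grp)) < 2L) {
    return(list(group = grp, split_value = med, logrank_p = NA_real_))
  }
  sd <- survival::survdiff(
    survival::Surv(surv$time, surv$event) ~ grp)
  p <- stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE)
  list(group = grp, split_value = med, logrank_p = p)
}

#' Univariable Cox and Kaplan-Meier screen of cluster members
#'
#' Per member gene: a univariable proportional-hazards fit on the z-scored
#' log2(x + 1) expression covariate (hazard ratio and Wald p), plus the
#' log-rank p from a median split on the same covariate. Constant genes
#' are skipped with a warning.
#'
#' @param expr genes-by-samples matrix.
#' @param surv a [survival_table()]; samples are intersected with the
#'   expression columns.
#' @param cs a `cluster_set` (or a character vector of gene IDs).
#' @return data.frame (`cluster_id`, `gene_id`, `hr`, `p_cox`,
#'   `p_logrank_medsplit`).
#' @export
univariate_screen <- function(expr, surv, cs) {
  member_map <- if (inherits(cs, "cluster_set")) attr(cs, "members")
                else list(geneset = as.character(cs))
  samples <- intersect(colnames(expr), surv$sample_id)
  surv <- surv[match(samples, surv$sample_id), , drop = FALSE]
  if (length(samples) < 10L || sum(surv$event) < 1L) {
    stopf("need >= 10 samples with >= 1 event")
  }
  rows <- list()
  for (id in names(member_map)) {
    genes <- intersect(member_map[[id]], rownames(expr))
    cov <- prepare_covariates(expr, genes, samples)
    if (length(cov$dropped)) {
      warnf("skipping constant gene(s): %s",
            paste(cov$dropped, collapse = ", "))
    }
    for (g in rownames(cov$z)) {
      x <- cov$z[g, ]
      fit <- survival::coxph(survival::Surv(surv$time, surv$event) ~ x)
      s <- summary(fit)
      ms <- median_split_logrank(setNames(x, samples), surv)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = id, gene_id = g,
        hr = unname(s$coefficients[1L, "exp(coef)"]),
        p_cox = unname(s$coefficients[1L, "Pr(>|z|)"]),
        p_logrank_medsplit = ms$logrank_p,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(cluster_id = character(0), gene_id = character(0),
                      hr = numeric(0), p_cox = numeric(0),
                      p_logrank_medsplit = numeric(0)))
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Multivariate Cox risk model for one cluster
#'
#' Fits a joint proportional-hazards model over all cluster members on
#' z-scored log2(x + 1) expression; the risk score is the linear
#' predictor. Patients are split at the median risk score into low/high
#' groups (ties to low) compared by log-rank test, and the two
#' Kaplan-Meier curves are exported as step-function tables. Collinear or
#' non-converging fits are retried with a ridge penalty and flagged.
#'
#' @param expr genes-by-samples matrix.
#' @param surv a [survival_table()].
#' @param members character vector of member gene IDs.
#' @param cluster_id label carried into the result.
#' @return list: `cluster_id`, `coefficients` (named), `risk_scores`
#'   (named), `split_value`, `logrank_p`, `group`, `km` (data.frame
#'   `group`, `time`, `surv`), `ridged` (logical).
#' @export
cluster_risk_model <- function(expr, surv, members,
                               cluster_id = "cluster") {
  genes <- intersect(unique(members), rownames(expr))
  samples <- intersect(colnames(expr), surv$sample_id)
  surv <- surv[match(samples, surv$sample_id), , drop = FALSE]
  if (length(samples) <= 5L * length(genes)) {
    warnf("fewer than 5 samples per covariate; fit may be unstable")
  }
  cov <- prepare_covariates(expr, genes, samples)
  if (nrow(cov$z) == 0L) stopf("no usable (non-constant) members")
  X <- t(cov$z)
  y <- survival::Surv(surv$time, surv$event)
  ridged <- FALSE
  fit <- tryCatch({
    f <- survival::coxph(y ~ X)
    if (anyNA(stats::coef(f))) stop("collinear")
    f
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) {
    ridged <- TRUE
    warnf("cluster %s: ridge-stabilized fit", cluster_id)
    fit <- survival::coxph(y ~ survival::ridge(X, theta = 1))
  }
  beta <- stats::coef(fit)
  names(beta) <- colnames(X)
  lp <- drop(X %*% beta)
  names(lp) <- samples
  ms <- median_split_logrank(lp, surv)
  sf <- survival::survfit(y ~ ms$group)
  km <- data.frame(
    group = rep(sub("^.*=", "", names(sf$strata)),
                times = sf$strata),
    time = sf$time, surv = sf$surv, stringsAsFactors = FALSE)
  list(cluster_id = cluster_id, coefficients = beta, risk_scores = lp,
       split_value = ms$split_value, logrank_p = ms$logrank_p,
       group = ms$group, km = km, ridged = ridged)
}

#' Cluster-level survival report across a cluster set
#'
#' For each cluster and cancer type: the joint risk-model log-rank p and
#' whether any member is individually significant in the univariable
#' screen. The flag `cluster_level_only` marks the phenomenon of interest
#' — a cluster whose joint model separates survival (log-rank p <
#' `alpha`) while no individual member passes `alpha` univariably.
#'
#' @param cs a `cluster_set`.
#' @param expr_by_cancer named list of expression matrices.
#' @param surv_by_cancer named list of [survival_table()]s (same names).
#' @param alpha significance level for both the joint and member tests.
#' @return data.frame (`cluster_id`, `cancer_type`, `logrank_p`,
#'   `any_member_significant`, `cluster_level_only`).
#' @export
cluster_survival_report <- function(cs, expr_by_cancer, surv_by_cancer,
                                    alpha = 0.05) {
  members <- attr(cs, "members")
  rows <- list()
  for (ct in names(expr_by_cancer)) {
    expr <- expr_by_cancer[[ct]]
    surv <- surv_by_cancer[[ct]]
    uni <- univariate_screen(expr, surv, cs)
    for (id in names(members)) {
      rm_ <- tryCatch(
        cluster_risk_model(expr, surv, members[[id]], id),
        error = function(e) NULL)
      if (is.null(rm_)) next
      member_p <- uni$p_cox[uni$cluster_id == id]
      any_sig <- length(member_p) > 0 && any(member_p < alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = id, cancer_type = ct, logrank_p = rm_$logrank_p,
        any_member_significant = any_sig,
        cluster_level_only = !is.na(rm_$logrank_p) &&
          rm_$logrank_p < alpha && !any_sig,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(cluster_id = character(0), cancer_type = character(0),
                      logrank_p = numeric(0),
                      any_member_significant = logical(0),
                      cluster_level_only = logical(0)))
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
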