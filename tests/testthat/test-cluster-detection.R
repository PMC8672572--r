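test_that("sliding-window detection matches hand-checked gap layouts", {
  # gaps (50k, 50k, 50k, 100k) at d = 60k: first four genes only
  cat <- catalog_from_gaps(c(50e3, 50e3, 50e3, 100e3))
  cs <- detect_clusters(cat, detection_params(max_gap_bp = 60e3))
  expect_equal(nrow(cs), 1L)
  expect_equal(attr(cs, "members")[[1]], paste0("g", 1:4))

  # below minimum size: no clusters
  cat3 <- catalog_from_gaps(c(1e3, 1e3))
  expect_equal(nrow(detect_clusters(cat3, detection_params())), 0L)

  # all-compact chromosome: a single maximal cluster, never two
  cat6 <- catalog_from_gaps(rep(10e3, 5))
  cs6 <- detect_clusters(cat6, detection_params(max_gap_bp = 60e3))
  expect_equal(nrow(cs6), 1L)
  expect_equal(cs6$size, 6L)

  # strict inequality: gap exactly d does not join
  cat_eq <- catalog_from_gaps(rep(60e3, 4))
  expect_equal(nrow(detect_clusters(cat_eq,
                                    detection_params(max_gap_bp = 60e3))),
               0L)

  # empty catalog is fine
  empty <- gene_catalog(character(0), character(0), numeric(0), numeric(0))
  expect_equal(nrow(detect_clusters(empty, detection_params())), 0L)
})

test_that("detection equals brute-force maximal-run enumeration on random catalogs", {
  for (s in 1:25) {
    n <- sample(20:120, 1)
    cat <- random_catalog(n, seed = s, gap_mean = 40000)
    d <- sample(c(20e3, 40e3, 60e3), 1)
    ms <- sample(2:4, 1)
    cs <- detect_clusters(cat, detection_params(max_gap_bp = d,
                                                min_size = ms))
    oracle <- oracle_maximal_runs(cat, d, ms)
    expect_equal(member_sets(cs), oracle,
                 info = sprintf("seed=%d d=%g min_size=%d", s, d, ms))
    # the two independent oracle formulations agree with each other too
    expect_equal(oracle, oracle_runs_by_breaks(cat, d, ms))
  }
})

test_that("cluster membership partitions genes and members are consecutive", {
  cat <- random_catalog(150, seed = 99, gap_mean = 30000)
  cs <- detect_clusters(cat, detection_params(max_gap_bp = 40e3,
                                              min_size = 3L))
  all_members <- unlist(member_sets(cs))
  expect_equal(anyDuplicated(all_members), 0L)
  for (m in member_sets(cs)) {
    ch <- cat$chrom[match(m[1], cat$gene_id)]
    sub <- cat$gene_id[cat$chrom == ch]
    idx <- match(m, sub)
    expect_equal(idx, seq(idx[1], length.out = length(idx)))
  }
})

test_that("start-to-start gap mode is supported", {
  # genes of length 30k with 10k intergenic gaps: start-start = 40k
  cat <- catalog_from_gaps(rep(10e3, 4), gene_len = 30e3)
  p_int <- detection_params(max_gap_bp = 20e3, gap_mode = "intergenic")
  p_sta <- detection_params(max_gap_bp = 20e3, gap_mode = "start")
  expect_equal(nrow(detect_clusters(cat, p_int)), 1L)
  expect_equal(nrow(detect_clusters(cat, p_sta)), 0L)
})

test_that("permutation p-value behaves at the analytic anchor points", {
  # equally spaced catalog: every window of size L has the same span, so
  # no random span is strictly smaller
  cat <- catalog_from_gaps(rep(10e3, 30))
  cs <- detect_clusters(cat, detection_params(max_gap_bp = 60e3))
  pr <- permutation_pvalue(cs[1, ], cat, detection_params(seed = 5))
  expect_equal(pr$p_value, 0)
  expect_equal(pr$n_smaller, 0L)

  # pseudocount estimator avoids exact zero
  pr2 <- permutation_pvalue(cs[1, ], cat,
                            detection_params(seed = 5,
                                             pseudocount = TRUE))
  expect_equal(pr2$p_value, 1 / 1001)

  # chromosome smaller than the cluster: no null available
  tiny <- gene_catalog(paste0("t", 1:3), "chr1",
                       c(0, 10, 20), c(5, 15, 25))
  fake <- cs[1, ]
  fake$chrom <- "chr1"
  expect_error(permutation_pvalue(fake, tiny, detection_params()),
               "insufficient genes")
})

test_that("a planted ultra-compact cluster is significant under any seed", {
  # 500 genes with ~600 kb background gaps; plant 5 genes with 1 kb gaps
  set.seed(123)
  n <- 500
  gaps <- round(rexp(n - 1, 1 / 6e5)) + 1
  gaps[250:253] <- 1000
  cat <- catalog_from_gaps(gaps)
  cs <- detect_clusters(cat, detection_params(max_gap_bp = 60e3,
                                              min_size = 5L))
  target <- which(vapply(member_sets(cs), function(m) "g251" %in% m,
                         logical(1)))[1]
  for (s in 1:10) {
    pr <- permutation_pvalue(cs[target, ], cat,
                             detection_params(seed = s, min_size = 5L))
    expect_lt(pr$p_value, 0.005)
  }
})

test_that("a median-span window earns a p-value near one half", {
  set.seed(7)
  cat <- catalog_from_gaps(round(rexp(299, 1 / 1e5)))
  L <- 5L
  sub <- as.data.frame(cat)
  spans <- vapply(seq_len(nrow(sub) - L + 1),
                  function(i) sub$end[i + L - 1] - sub$start[i], numeric(1))
  fake <- list(chrom = "chr1", size = L, span_bp = median(spans))
  pr <- permutation_pvalue(fake, cat, detection_params(seed = 11))
  expect_lt(abs(pr$p_value - 0.5), 3 * sqrt(0.25 / 1000) + 0.01)
})

test_that("significance filtering retains planted clusters and honors alpha", {
  cfg <- three_cluster_config(seed = 31)
  sim <- simulate_catalog(cfg)
  params <- detection_params(seed = 31)
  cs <- detect_significant(sim$catalog, params)
  expect_equal(nrow(cs), 3L)
  got <- member_sets(cs)
  want <- lapply(sim$truth$planted, `[[`, "members")
  expect_setequal(vapply(got, paste, "", collapse = ","),
                  vapply(want, paste, "", collapse = ","))
  expect_equal(cs$cluster_id, paste0("Cluster", 1:3))

  # alpha = 1 disables filtering
  params1 <- detection_params(alpha = 1, seed = 31)
  expect_equal(nrow(detect_significant(sim$catalog, params1)),
               nrow(detect_clusters(sim$catalog, params1)))
})

test_that("detection and p-values are deterministic under a fixed seed", {
  cfg <- three_cluster_config(seed = 77)
  sim <- simulate_catalog(cfg)
  a <- detect_significant(sim$catalog, detection_params(seed = 42))
  b <- detect_significant(sim$catalog, detection_params(seed = 42))
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "members"), attr(b, "members"))
})

test_that("clustered-gene coverage grows monotonically with the threshold", {
  for (s in 1:3) {
    cat <- random_catalog(150, seed = 200 + s, gap_mean = 35000)
    thresholds <- seq(15e3, 80e3, 5e3)
    covered <- lapply(thresholds, function(d) {
      cs <- detect_clusters(cat, detection_params(max_gap_bp = d))
      unlist(member_sets(cs))
    })
    for (i in seq_along(thresholds)[-1]) {
      expect_true(all(covered[[i - 1]] %in% covered[[i]]))
    }
  }
})

test_that("threshold sweep tabulates counts and size histograms", {
  cat <- random_catalog(200, seed = 5, gap_mean = 30000)
  tab <- threshold_sweep(cat, c(15e3, 60e3, 80e3),
                         detection_params(seed = 5), significant = FALSE)
  expect_equal(nrow(tab), 3L)
  expect_true(all(diff(tab$n_clustered_genes) >= 0))
  h <- attr(tab, "size_histogram")
  for (i in seq_len(nrow(tab))) {
    expect_equal(sum(h[[as.character(tab$threshold[i])]]),
                 tab$n_clusters[i])
  }
  one <- threshold_sweep(cat, 60e3, detection_params(seed = 5),
                         significant = FALSE)
  expect_equal(nrow(one), 1L)
})
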