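test_that("log transform is log1p, monotone and invertible", {
  expect_equal(log_transform(0), matrix(0, 1, 1), ignore_attr = TRUE)
  expect_equal(as.numeric(log_transform(exp(1) - 1)), 1)
  x <- matrix(c(0, 1, 10, 1000), 2)
  expect_equal(expm1(log_transform(x)), x, tolerance = 1e-12)
  expect_error(log_transform(matrix(-1)), "negative")
})

test_that("log transform stabilizes negative-binomial variance", {
  set.seed(81)
  x <- rnbinom(1e4, mu = 50, size = 2)
  expect_lt(var(log1p(x)), var(x))
})

test_that("clustering separates well-split populations deterministically", {
  set.seed(82)
  n <- 60
  truth <- rep(1:2, each = n / 2)
  mat <- cbind(CD3 = rnorm(n, ifelse(truth == 1, 10, 0), 0.5),
               CD4 = rnorm(n, ifelse(truth == 1, 10, 0), 0.5),
               CK = rnorm(n, ifelse(truth == 1, 0, 10), 0.5))
  cl <- hierarchical_cluster(mat, k = 2)
  expect_equal(mclust::adjustedRandIndex(cl, truth), 1.0)
  # CD3/CD4-high population is relabelled cluster 1
  expect_true(all(cl[truth == 1] == 1L))
  expect_identical(as.integer(cl), as.integer(hierarchical_cluster(mat, k = 2)))
  expect_equal(unique(hierarchical_cluster(mat, k = 1)), 1L)
  expect_error(hierarchical_cluster(mat[1:3, ], k = 5), "k")
})

test_that("duplicating rows leaves the originals' cluster cut unchanged", {
  set.seed(83)
  n <- 30
  truth <- rep(1:2, each = n / 2)
  mat <- cbind(CD3 = rnorm(n, ifelse(truth == 1, 8, 0)),
               CD4 = rnorm(n, ifelse(truth == 1, 8, 0)),
               CK = rnorm(n, ifelse(truth == 1, 0, 8)))
  cl <- hierarchical_cluster(mat, k = 2)
  cl_dup <- hierarchical_cluster(rbind(mat, mat), k = 2)
  expect_equal(as.integer(cl_dup[seq_len(n)]), as.integer(cl))
})

test_that("the immune gate follows the decision tree and its tie-breaks", {
  cfg <- default_gate_config()
  mk <- c("CD45", "CD3", "CD4", "CD8a", "CD20", "CD56", "CD14", "CD68")
  row <- function(...) {
    v <- stats::setNames(rep(0, 8), mk)
    hits <- c(...)
    v[hits] <- log1p(100)
    matrix(v, 1, dimnames = list(NULL, mk))
  }
  expect_equal(gate_immune_subtype(row("CD45", "CD3", "CD4"), cfg), "cd4_t")
  expect_equal(gate_immune_subtype(row("CD45", "CD3", "CD8a"), cfg), "cd8_t")
  # double positive resolves to cd8_t by branch order
  expect_equal(gate_immune_subtype(row("CD45", "CD3", "CD4", "CD8a"), cfg),
               "cd8_t")
  expect_equal(gate_immune_subtype(row("CD45", "CD20"), cfg), "b_cell")
  expect_equal(gate_immune_subtype(row("CD45", "CD56"), cfg), "nk")
  expect_equal(gate_immune_subtype(row("CD45", "CD14"), cfg),
               "monocyte_macrophage")
  expect_equal(gate_immune_subtype(row(), cfg), "non_immune")
  expect_equal(gate_immune_subtype(row("CD45"), cfg), "unclassified")
  expect_error(gate_immune_subtype(row()[, -1, drop = FALSE], cfg),
               "missing gate markers")
})

test_that("gate labels are invariant under monotone rescaling", {
  set.seed(84)
  ph <- simulate_phenotype_matrix(n_contact = 20, n_standalone = 40, seed = 4)
  cfg <- default_gate_config()
  g1 <- gate_immune_subtype(ph$log, cfg)
  resc <- function(x) 3 * x + 2  # strictly monotone
  cfg2 <- gate_config(vapply(cfg$thresholds, resc, numeric(1)))
  g2 <- gate_immune_subtype(resc(ph$log), cfg2)
  expect_equal(g1, g2)
})

test_that("coordinate matching is greedy with lowest-id tie-breaking", {
  set.seed(85)
  ev <- data.frame(id = 1:40, x = runif(40, 0, 500), y = runif(40, 0, 500))
  roi <- data.frame(id = 1:40, x = ev$x + rnorm(40, 0, 1),
                    y = ev$y + rnorm(40, 0, 1))
  m <- match_coordinates(ev, roi, tolerance_um = 5)
  expect_equal(nrow(m$matches), 40L)
  expect_equal(length(m$unmatched_events), 0L)
  # empty ROI set
  m0 <- match_coordinates(ev, roi[0, ], tolerance_um = 5)
  expect_equal(nrow(m0$matches), 0L)
  # one ROI equidistant to two events: lowest event id wins
  ev2 <- data.frame(id = 1:2, x = c(0, 2), y = c(0, 0))
  roi2 <- data.frame(id = 9, x = 1, y = 0)
  expect_warning(m2 <- match_coordinates(ev2, roi2, tolerance_um = 5),
                 "ambiguous")
  expect_equal(m2$matches$event_id, 1)
  expect_equal(m2$unmatched_events, 2)
})

test_that("coordinate matching honours an affine transform", {
  ev <- data.frame(id = 1:3, x = c(10, 20, 30), y = c(5, 5, 5))
  # ROIs in a shifted frame: x' = x - 100, y' = y - 50
  roi <- data.frame(id = 1:3, x = ev$x - 100, y = ev$y - 50)
  tr <- cbind(diag(2), c(100, 50))
  m <- match_coordinates(ev, roi, tolerance_um = 1, transform = tr)
  expect_equal(nrow(m$matches), 3L)
})

test_that("Fisher enrichment matches frozen enumeration examples", {
  f <- fisher_enrichment(rbind(c(2, 0), c(0, 2)))
  expect_equal(f$p_value, 1 / 3, tolerance = 1e-12)
  f <- fisher_enrichment(rbind(c(5, 5), c(5, 5)))
  expect_equal(f$p_value, 1)
  expect_equal(f$odds_ratio, 1)
  f <- fisher_enrichment(rbind(c(10, 0), c(0, 10)))
  expect_equal(f$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(f$odds_ratio, Inf)
  expect_error(fisher_enrichment(rbind(c(-1, 0), c(0, 1))), "non-negative")
})

test_that("Fisher p-values agree with fisher.test on random tables", {
  set.seed(86)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 6), 2, 2)
    expect_equal(fisher_enrichment(tab)$p_value,
                 fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("differential marker comparison has power for a 2x shift", {
  hits <- 0; diffs <- numeric(30)
  means <- phenotype_class_means()
  shift_log <- log1p(2 * means["epithelial", "HLA-DR"]) -
    log1p(means["epithelial", "HLA-DR"])
  for (s in 1:30) {
    set.seed(900 + s)
    a <- matrix(rnbinom(30, mu = 2 * means["epithelial", "HLA-DR"], size = 8),
                ncol = 1, dimnames = list(NULL, "HLA-DR"))
    b <- matrix(rnbinom(30, mu = means["epithelial", "HLA-DR"], size = 8),
                ncol = 1, dimnames = list(NULL, "HLA-DR"))
    cmp <- differential_marker(log_transform(a), log_transform(b), "HLA-DR")
    if (cmp$p_value < 0.01) hits <- hits + 1
    diffs[s] <- cmp$median_diff
  }
  expect_gte(hits / 30, 0.9)
  expect_lt(abs(mean(diffs) - shift_log) / shift_log, 0.2)
  ident <- matrix(rep(1:10, 2), ncol = 1, dimnames = list(NULL, "HLA-DR"))
  expect_equal(differential_marker(ident[1:10, , drop = FALSE],
                                   ident[1:10, , drop = FALSE],
                                   "HLA-DR")$p_value, 1)
})

test_that("the phenotype simulator is reproducible and balanced", {
  a <- simulate_phenotype_matrix(seed = 11)
  b <- simulate_phenotype_matrix(seed = 11)
  expect_identical(a$raw, b$raw)
  expect_equal(nrow(a$raw), 42 + 143)
  expect_equal(sum(a$meta$contact), 42)
  expect_true(all(c("CD45", "CD3", "CD4", "CD8a", "CD20", "CD56", "CD14",
                    "CD68") %in% colnames(a$raw)))
})
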