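test_that("percent input follows the Cp arithmetic", {
  ## Cp[ChIP] equal to the dilution-corrected input Cp gives 100%
  expect_equal(percent_input(24, 25, dilution_factor = 2), 100)
  expect_equal(percent_input(30, 25, 1), 100 / 2^5)  # 3.125%
  expect_equal(percent_input(28, 27, 2), 25)         # exponent 2
  expect_error(percent_input(30, 25, 0.5), ">= 1")
  expect_error(percent_input(-1, 25, 1), "positive")
})

test_that("delta-delta-Cp fold changes and replicate statistics", {
  same <- ddcp_fold_change(20, 15, 20, 15)
  expect_equal(same$fold_change, 1)
  ## ddCp of -2 doubles twice; +1 halves
  expect_equal(ddcp_fold_change(18, 15, 20, 15)$fold_change, 4)
  expect_equal(ddcp_fold_change(21, 15, 20, 15)$fold_change, 0.5)
  ## replicates: mean, SD and a two-tailed t-test
  set.seed(6)
  tt <- ddcp_fold_change(c(18.1, 17.9, 18.0), c(15, 15.1, 14.9),
                         c(20.0, 20.2, 19.8), c(15.1, 15.0, 14.9))
  expect_equal(tt$fold_change, 4, tolerance = 0.2)
  expect_length(tt$per_replicate, 3L)
  expect_lt(tt$p_value, 0.05)
})

test_that("qPCR formulas match independent arithmetic on random inputs", {
  set.seed(44)
  for (i in 1:100) {
    cpc <- runif(1, 15, 35); cpi <- runif(1, 15, 35)
    df <- sample(1:64, 1)
    ## independent route: percent = 100 * 2^cpi / (2^cpc * df)
    expect_equal(percent_input(cpc, cpi, df),
                 100 * 2^cpi / (2^cpc * df))
    tt <- runif(1, 15, 35); tr <- runif(1, 15, 35)
    ct <- runif(1, 15, 35); cr <- runif(1, 15, 35)
    expect_equal(ddcp_fold_change(tt, tr, ct, cr)$fold_change,
                 2^(ct - cr) / 2^(tt - tr))
  }
})

test_that("QC filtering removes shallow cells then orphaned genes", {
  counts <- rbind(
    g1 = c(5, 0, 2),
    g2 = c(1, 3, 0),
    g3 = c(0, 4, 0)   # detected only in the cell to be removed
  )
  mat <- labeled_matrix(counts, c("a", "b", "a"))
  expect_equal(unname(mat$detected), c(2, 2, 1))
  ident <- qc_filter(mat, 0)
  expect_equal(dim(ident$counts), dim(counts))
  f <- qc_filter(mat, 2)                 # cell 3 detects 1 gene (< 2)
  expect_equal(ncol(f$counts), 2L)
  expect_equal(rownames(f$counts), c("g1", "g2", "g3"))
  f2 <- qc_filter(labeled_matrix(rbind(g1 = c(5, 0), g3 = c(0, 4)),
                                 c("a", "b")), 1)
  expect_equal(nrow(f2$counts), 2L)
  ## cascade: removing the only cell expressing g3 drops g3
  counts2 <- rbind(g1 = c(5, 1, 0), g2 = c(4, 2, 0), g3 = c(0, 0, 9))
  f3 <- qc_filter(labeled_matrix(counts2, c("a", "b", "b")), 2)
  expect_equal(rownames(f3$counts), c("g1", "g2"))
  expect_error(qc_filter(mat, 100), "every cell")
  ## boundary: a cell detecting exactly cutoff - 1 genes is removed
  big <- labeled_matrix(matrix(1, 1500, 2), c("a", "b"))
  big$counts[1500, 2] <- 0               # cell 2 detects 1499
  big <- labeled_matrix(big$counts, big$clusters)
  expect_equal(ncol(qc_filter(big, 1500)$counts), 1L)
})

test_that("z-score localization follows the stated SD convention", {
  ## equal-depth cells so depth normalization is the identity; one cell per
  ## cluster; gene zz has log1p cluster means (0, 0, 10)
  hi <- exp(10) - 1
  D <- 30000
  counts <- rbind(zz = c(0, 0, hi), flat = c(500, 500, 500),
                  pad = c(D - 500, D - 500, D - 500 - hi))
  mat <- labeled_matrix(counts, c("c1", "c2", "c3"))
  z <- zscore_localization(mat, c("zz", "flat"))
  expect_equal(unname(z$z["zz", ]), c(-0.577, -0.577, 1.155),
               tolerance = 1e-3)        # sample-SD convention
  expect_equal(unname(z$z["flat", ]), c(0, 0, 0))
  ## z-scores sum to ~0 per gene, generically
  set.seed(71)
  m2 <- labeled_matrix(matrix(rpois(600, 5), 20, 30),
                       rep(c("a", "b", "c"), each = 10))
  z2 <- zscore_localization(m2)
  expect_true(all(abs(rowSums(z2$z)) < 1e-9))
  expect_warning(zscore_localization(m2, c("gene_1", "nope")), "absent")
  expect_error(zscore_localization(labeled_matrix(counts, rep("a", 3))),
               "2 clusters")
})

test_that("COV uses sample SD on linear normalized expression", {
  ## equal-depth cells: normalization is the identity
  counts <- rbind(g1 = c(1, 2, 3), g2 = c(4, 4, 4), pad = c(5, 4, 3))
  mat <- labeled_matrix(counts, c("a", "a", "b"))
  cv <- cov_per_gene(mat, min_mean = 0.01)
  expect_equal(cv$cov[cv$gene == "g1"], 0.5)    # sd 1 / mean 2
  expect_equal(cv$cov[cv$gene == "g2"], 0)      # constant gene
  ## min_mean excludes silent genes
  counts3 <- rbind(counts, zero = c(0, 0, 0))
  cv3 <- cov_per_gene(labeled_matrix(counts3, c("a", "a", "b")))
  expect_false("zero" %in% cv3$gene)
  ## scaling every library by a common factor leaves COV unchanged
  cv10 <- cov_per_gene(labeled_matrix(counts * 10, c("a", "a", "b")))
  expect_equal(cv$cov, cv10$cov)
  expect_error(cov_per_gene(mat, min_mean = 0), "min_mean")
})

test_that("robustness contrast summarizes groups and tests pairwise", {
  cvt <- data.frame(gene = sprintf("g%02d", 1:40),
                    mean = c(rep(10, 20), rep(2, 20)),
                    sd = 1,
                    cov = c(rnorm(20, 0.3, 0.01), rnorm(20, 1.2, 0.01)))
  rob <- robustness_contrast(cvt, list(se = cvt$gene[1:20],
                                       re = cvt$gene[21:40]))
  expect_equal(nrow(rob$summary), 2L)
  expect_gt(rob$summary$mean_expression[1], rob$summary$mean_expression[2])
  expect_lt(rob$summary$mean_cov[1], rob$summary$mean_cov[2])
  expect_lt(rob$tests$padj_cov, 0.05)
  ## identical groups: no signal
  ident <- robustness_contrast(cvt, list(a = cvt$gene, b = cvt$gene))
  expect_gt(ident$tests$p_cov, 0.9)
  expect_equal(ident$summary$mean_cov[1], ident$summary$mean_cov[2])
  ## single group: summaries only
  single <- robustness_contrast(cvt, list(only = cvt$gene))
  expect_null(single$tests)
  expect_warning(robustness_contrast(cvt, list(a = cvt$gene,
                                               empty = "nope")), "empty")
})

test_that("SE gene linking applies windows and SE precedence", {
  rk <- find_cutoff(mk_ranking(c(1, 2, 3, 4, 100)))
  ## loci at BED 0,10,20,30,40 (width 1); SE is the locus at 40
  genes <- genes_df(c("on_se", "far", "near_both"), "chrA",
                    c(41, 25000, 31), c(45, 26000, 35), "+")
  link <- se_gene_linking(rk, genes, window = 20000)
  expect_true("on_se" %in% link$se)          # overlaps the SE locus
  expect_true("far" %in% link$none)          # > 20 kb from every locus
  expect_true("near_both" %in% link$se)      # SE takes precedence over RE
  ## boundary: exactly window + 1 away is unlinked
  g2 <- genes_df("edge", "chrA", 41 + 20002, 41 + 20006, "+")
  expect_true("edge" %in% se_gene_linking(rk, g2, window = 20000)$none)
})

test_that("MatrixMarket round-trip preserves counts and labels", {
  set.seed(12)
  m <- labeled_matrix(matrix(rpois(50, 3), 10, 5),
                      c("a", "a", "b", "b", "b"))
  d <- withr::local_tempdir()
  write_expression_mtx(m, d, prefix = "t")
  back <- read_expression_mtx(file.path(d, "t.mtx"),
                              file.path(d, "t_genes.tsv"),
                              file.path(d, "t_cells.tsv"),
                              file.path(d, "t_clusters.tsv"))
  expect_equal(as.matrix(back$counts), as.matrix(m$counts),
               ignore_attr = TRUE)
  expect_equal(as.character(back$clusters), as.character(m$clusters))
})

test_that("the reference cell-state table is internally consistent", {
  cs <- default_cell_states()
  expect_equal(nrow(cs), 13L)
  expect_equal(anyDuplicated(cs$cluster), 0L)
  expect_equal(unname(table(cs$germ_layer)["ectoderm"]), 5L)
})
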