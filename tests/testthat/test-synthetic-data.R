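test_that("genome generator is deterministic and respects its contract", {
  g1 <- gen_genome_and_genes(11, n_chroms = 2, chrom_len = 2e6, n_genes = 100)
  g2 <- gen_genome_and_genes(11, n_chroms = 2, chrom_len = 2e6, n_genes = 100)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_gff3(g1$genes, f1); write_gff3(g2$genes, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical per seed

  expect_equal(nrow(g1$genes), 100L)
  expect_equal(anyDuplicated(g1$genes$gene_id), 0L)
  expect_setequal(unique(g1$genes$chrom), c("chr1", "chr2"))
  ## no two genes overlap
  ggr <- genes_as_granges(g1$genes)
  expect_equal(max(GenomicRanges::countOverlaps(ggr, ggr,
                                                ignore.strand = TRUE)), 1L)
  expect_equal(nrow(gen_genome_and_genes(11, n_genes = 0)$genes), 0L)
  expect_error(gen_genome_and_genes(11, n_chroms = 1, chrom_len = 1e5,
                                    n_genes = 1000), "capacity")
})

test_that("stage-peak generator plants recoverable temporal classes", {
  sizes <- c(chr1 = 1e6, chr2 = 1e6)
  one_each <- setNames(rep(1L, 7), c("100", "010", "001", "110", "101",
                                     "011", "111"))
  sp <- gen_stage_peaks(5, one_each, chrom_sizes = sizes)
  ## stage unions: stage k contains peaks of every pattern with bit k set
  expect_equal(lengths(sp$stages), c(stage8 = 4L, stage9 = 4L,
                                     `stage10.5` = 4L))
  cls <- temporal_classify(sp$stages[[1]], sp$stages[[2]], sp$stages[[3]])
  expect_setequal(mcols(cls$loci)$pattern, names(one_each))
  expect_equal(length(unique(mcols(cls$loci)$class)), 7L)

  none <- gen_stage_peaks(5, setNames(rep(0L, 7), names(one_each)),
                          chrom_sizes = sizes)
  expect_true(all(lengths(none$stages) == 0L))

  persistent <- gen_stage_peaks(5, setNames(c(rep(0L, 6), 10L),
                                            names(one_each)),
                                chrom_sizes = sizes)
  expect_true(all(lengths(persistent$stages) == 10L))
  ## pairwise overlap audit: every locus's three stage peaks overlap
  s1 <- persistent$stages[[1]]; s2 <- persistent$stages[[2]]
  s3 <- persistent$stages[[3]]
  ord <- function(g) g[order(start(g))]
  s1 <- ord(s1); s2 <- ord(s2); s3 <- ord(s3)
  for (i in 1:10) {
    expect_true(overlaps_bp(s1[i], s2[i]))
    expect_true(overlaps_bp(s2[i], s3[i]))
    expect_true(overlaps_bp(s1[i], s3[i]))
  }
})

test_that("signal generator plants super-enhancers recoverable by ranking", {
  sizes <- c(chr1 = 5e6, chr2 = 5e6)
  ## no SEs, no noise: RE signal is exactly re_amp x width
  quiet <- gen_signal_with_ses(3, sizes, n_re = 20, n_se = 0, noise_sd = 0,
                               re_amp = 1.5, peak_width = 1000)
  re1 <- quiet$truth$re_loci[1, ]
  ws <- window_sum(quiet$track, bp(re1$chrom, re1$start, re1$end))
  expect_equal(ws, 1.5 * 1000)

  planted <- gen_signal_with_ses(3, sizes, n_re = 60, n_se = 5,
                                 se_amp = 10, re_amp = 1)
  loci <- stitch(planted$peaks)
  rk <- find_cutoff(rank_loci(loci, planted$track))
  expect_equal(nrow(rk), 65L)
  top5 <- rk[rk$rank <= 5, c("chrom", "start", "end")]
  truth <- planted$truth$se_loci
  expect_setequal(paste(top5$chrom, top5$start), paste(truth$chrom,
                                                       truth$start))

  ## same seed gives byte-identical bedGraph
  again <- gen_signal_with_ses(3, sizes, n_re = 60, n_se = 5,
                               se_amp = 10, re_amp = 1)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_bedgraph(planted$track, f1); write_bedgraph(again$track, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("morphant count generator plants fold changes with NB noise", {
  g <- genes_df(sprintf("g%03d", 1:50), "chr1",
                seq(1, by = 10000, length.out = 50),
                seq(5000, by = 10000, length.out = 50), "+")
  tgt <- data.frame(gene_id = c("g001", "g002"), factor = c("A", "A"),
                    direction = c("activated", "repressed"), effect = 2)
  cnt <- gen_morphant_counts(9, g, tgt, n_reps = 4, dispersion = 1e-4,
                             base_meanlog = log(5000), base_sdlog = 0.2)
  lfc <- log2(rowMeans(cnt$morphant_A) / rowMeans(cnt$wt))
  expect_equal(unname(lfc["g001"]), -2, tolerance = 0.05)
  expect_equal(unname(lfc["g002"]), 2, tolerance = 0.05)
  expect_lt(max(abs(lfc[setdiff(g$gene_id, tgt$gene_id)])), 0.3)
  ## factor-B morphant is unaffected by A-only targets
  lfcB <- log2(rowMeans(cnt$morphant_B) / rowMeans(cnt$wt))
  expect_lt(max(abs(lfcB)), 0.3)
  ## determinism
  cnt2 <- gen_morphant_counts(9, g, tgt, n_reps = 4, dispersion = 1e-4,
                              base_meanlog = log(5000), base_sdlog = 0.2)
  expect_identical(cnt$wt, cnt2$wt)
  expect_identical(cnt$morphant_A, cnt2$morphant_A)
})

test_that("single-nucleus generator plants robustness and cluster markers", {
  g <- genes_df(sprintf("g%03d", 1:150), "chr1",
                seq(1, by = 10000, length.out = 150),
                seq(5000, by = 10000, length.out = 150), "+")
  robust <- g$gene_id[1:15]
  r <- gen_sc_matrix(21, g, robust_genes = robust, n_cells = 500,
                     depth = 1500)
  expect_s3_class(r$mat, "labeled_matrix")
  expect_equal(ncol(r$mat$counts), 500L)
  ## robust genes: higher mean, lower COV on average
  cv <- cov_per_gene(r$mat)
  rg <- cv[cv$gene %in% robust, ]
  bg <- cv[!cv$gene %in% robust, ]
  expect_gt(mean(rg$mean), mean(bg$mean))
  expect_lt(mean(rg$cov), mean(bg$cov))
  ## planted marker genes localize to their cluster by z-score
  zl <- zscore_localization(r$mat)
  for (k in names(r$truth$markers)) {
    for (gene in r$truth$markers[[k]]) {
      expect_equal(colnames(zl$z)[which.max(zl$z[gene, ])], k)
    }
  }
  ## empty matrix case
  r0 <- gen_sc_matrix(21, g, n_cells = 0)
  expect_equal(ncol(r0$mat$counts), 0L)
  ## determinism
  r2 <- gen_sc_matrix(21, g, robust_genes = robust, n_cells = 500,
                      depth = 1500)
  expect_identical(r$mat$counts, r2$mat$counts)
})

test_that("window-sequence generator plants motif sites deterministically", {
  pk <- bp("chr1", c(1000, 3000), c(1400, 3400), summit = c(1200, 3200),
           name = c("p1", "p2"))
  plant <- data.frame(peak = "p1", consensus = "TGTTTGTTT", offset = 0,
                      strand = "+")
  s1 <- gen_window_sequences(17, pk, flank = 200, plant = plant)
  s2 <- gen_window_sequences(17, pk, flank = 200, plant = plant)
  expect_identical(s1, s2)
  expect_equal(nchar(s1[["p1"]]), 400L)
  expect_true(grepl("TGTTTGTTT", s1[["p1"]], fixed = TRUE))
})
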