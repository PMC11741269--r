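test_that("BED and narrowPeak parsing follows the format definitions", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t300", f)
  p <- read_peaks(f, "bed")
  expect_equal(length(p), 1L)
  expect_equal(start(p), 101L)  # internal 1-based
  expect_equal(end(p), 300L)
  expect_true(is.na(mcols(p)$summit))

  np <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t100\t600\tpk1\t900\t.\t5.2\t3.1\t2.0\t50",
               "chr1\t700\t900\tpk2\t800\t.\t4.0\t2.0\t1.5\t-1"), np)
  q <- read_peaks(np, "narrowPeak")
  expect_equal(mcols(q)$summit[1], 151L)  # absolute summit 150 (BED), 1-based
  expect_true(is.na(mcols(q)$summit[2])) # offset -1 means absent

  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), empty)
  expect_equal(length(read_peaks(empty, "bed")), 0L)
})

test_that("malformed records raise errors naming the line", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t300", "chr1\t100"), f)
  expect_error(read_peaks(f, "bed"), "line 2")
  writeLines(c("# a comment", "chr1\t500\t400"), f)
  expect_error(read_peaks(f, "bed"), "line 2.*start >= end")
  writeLines("chr1\tabc\t300", f)
  expect_error(read_peaks(f, "bed"), "line 1")
})

test_that("peak sets are sorted, deduplicated and written deterministically", {
  p <- bp(c("chr2", "chr1", "chr1", "chr1"), c(50, 500, 10, 10),
          c(80, 900, 40, 40), name = c("d", "c", "a", "a2"))
  expect_equal(as.character(seqnames(p)), c("chr1", "chr1", "chr2"))
  expect_equal(start(p), c(11L, 501L, 51L))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(p, f)
  expect_equal(read.table(f, sep = "\t")$V2, c(10L, 500L, 50L))
})

test_that("overlap predicate uses half-open arithmetic and is symmetric", {
  a <- bp("chr1", 100, 300)
  b <- bp("chr1", 300, 400)
  c_ <- bp("chr1", 250, 450)
  expect_false(overlaps_bp(a, b))        # abutting intervals share no base
  expect_true(overlaps_bp(a, c_))        # overlap 50
  expect_false(overlaps_bp(a, c_, min_bp = 51))
  expect_true(overlaps_bp(a, c_, min_bp = 50))
  expect_false(overlaps_bp(a, bp("chr2", 100, 300)))
  expect_error(overlaps_bp(a, b, min_bp = 0), "positive")
  set.seed(41)
  for (i in 1:25) {
    x <- random_peaks(1); y <- random_peaks(1)
    m <- sample(1:100, 1)
    expect_identical(overlaps_bp(x, y, m), overlaps_bp(y, x, m))
  }
})

test_that("merge bridges gaps up to max_gap and preserves covered bases", {
  one <- bp("chr1", 1000, 2000)
  expect_equal(start(merge_peaks(one, 10000)), 1001L)
  two <- bp(c("chr1", "chr1"), c(0, 5000), c(1000, 6000))
  m1 <- merge_peaks(two, 4000)            # gap of 4000 bridged
  expect_equal(length(m1), 1L)
  expect_equal(c(start(m1), end(m1)), c(1L, 6000L))
  m2 <- merge_peaks(two, 3999)            # gap exceeds threshold
  expect_equal(length(m2), 2L)
  expect_equal(sum(mcols(m1)$n_constituents), 2L)
})

test_that("merge is idempotent and permutation-invariant", {
  set.seed(7)
  for (i in 1:20) {
    p <- random_peaks(sample(2:40, 1))
    gap <- sample(0:500, 1)
    m <- merge_peaks(p, gap)
    expect_identical(GenomicRanges::granges(merge_peaks(m, gap)),
                     GenomicRanges::granges(m))
    shuffled <- p[sample(seq_along(p))]
    expect_identical(GenomicRanges::granges(merge_peaks(shuffled, gap)),
                     GenomicRanges::granges(m))
    ## every input base remains covered by some merged locus
    uncovered <- GenomicRanges::setdiff(
      GenomicRanges::reduce(p, ignore.strand = TRUE),
      GenomicRanges::granges(m), ignore.strand = TRUE
    )
    expect_equal(length(uncovered), 0L)
  }
})

test_that("window_sum integrates per-base signal with absent runs as zero", {
  iv <- bp("chr1", 100, 300)
  expect_equal(window_sum(GRanges(), iv), 0)
  expect_equal(window_sum(trk("chr1", 0, 10000, 1), iv), 200)
  expect_equal(window_sum(trk("chr1", 0, 150, 2), iv), 100)
  ## additivity over a partition
  set.seed(13)
  track <- trk("chr1", c(0, 400, 1200), c(300, 900, 1500), c(2, 0.5, 3))
  whole <- bp("chr1", 50, 1400)
  cuts <- sort(c(50, sample(60:1390, 5), 1400))
  parts <- bp(rep("chr1", 6), cuts[-7], cuts[-1])
  expect_equal(window_sum(track, whole), sum(window_sum(track, parts)))
})

test_that("aggregate_profile bins anchor-centered windows with zero padding", {
  regions <- bp("chr1", c(30000, 60000), c(30400, 60400),
                summit = c(30200, 60200))
  zero <- aggregate_profile(GRanges(), regions, flank = 1000, bin = 100)
  expect_true(all(zero$profile == 0))
  uni <- aggregate_profile(trk("chr1", 0, 100000, 1), regions,
                           flank = 1000, bin = 20)
  expect_true(all(uni$profile == 20))  # bin width x value
  wide <- aggregate_profile(trk("chr1", 0, 100000, 1), regions[1],
                            flank = 25000, bin = 100)
  expect_equal(ncol(wide$profile), 500L)
  ## anchor closer to the chromosome start than flank: zero-padded
  near <- bp("chr1", 100, 200, summit = 150)
  pad <- aggregate_profile(trk("chr1", 0, 5000, 1), near,
                           flank = 1000, bin = 100)
  expect_equal(ncol(pad$profile), 20L)
  expect_true(any(pad$profile < 100))  # leading bins partially padded
  expect_equal(sum(pad$profile), 150 + 1000)  # 150 real bases left + 1000 right
  expect_error(aggregate_profile(GRanges(), regions, flank = 1000, bin = 30),
               "divisible")
})

test_that("profile column means equal per-bin window sums (oracle)", {
  set.seed(23)
  for (i in 1:5) {
    run_start <- cumsum(sample(80:250, 8))
    track <- trk("chr1", run_start, run_start + sample(30:80, 8),
                 runif(8, 0, 4))
    regions <- bp("chr1", c(500, 900), c(700, 1100))
    prof <- aggregate_profile(track, regions, flank = 200, bin = 50)
    ## independent: midpoint-anchored bins computed one by one
    mids <- c(floor((500 + 700) / 2), floor((900 + 1100) / 2))
    expected <- sapply(0:7, function(b) {
      mean(sapply(mids, function(a) {
        window_sum(track, bp("chr1", a - 200 + b * 50, a - 200 + (b + 1) * 50))
      }))
    })
    expect_equal(unname(prof$means), expected)
  }
})

test_that("gene annotation computes strand-aware TSS and round-trips GFF3", {
  g <- genes_df(c("gA", "gB"), "chr1", c(1001, 5001), c(2000, 6000),
                c("+", "-"))
  expect_equal(g$tss, c(1001L, 6000L))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(g, f)
  back <- read_gene_annotation(f)
  expect_equal(back$gene_id, g$gene_id)
  expect_equal(back$tss, g$tss)
  expect_error(genes_df(c("gA", "gA"), "chr1", c(1, 10), c(5, 20)), "unique")
})

test_that("bedGraph round-trips and rejects invalid values", {
  t1 <- trk("chr1", c(0, 500), c(200, 900), c(1.5, 2))
  f <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(t1, f)
  back <- read_bedgraph(f)
  expect_equal(start(back), start(t1))
  expect_equal(mcols(back)$score, mcols(t1)$score)
  writeLines("chr1\t0\t100\t-5", f)
  expect_error(read_bedgraph(f), "nonnegative")
})
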