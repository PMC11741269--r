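## Shared fixtures and independent brute-force oracles. The oracles are
## deliberately naive (per-pair loops, per-position scoring) and never call
## the code paths they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

## peak set from BED coordinates, terse
bp <- function(chrom, start, end, ...) peak_set(chrom, start, end, ...)

## signal track from BED-coordinate runs
trk <- function(chrom, start, end, value) {
  GRanges(chrom, IRanges::IRanges(start + 1, end), score = value)
}

## random peak set on one or two chromosomes
random_peaks <- function(n, max_pos = 20000L, width_range = c(50L, 400L),
                         chroms = c("chrA", "chrB")) {
  if (n == 0L) return(bp(character(0), 0, 0))
  s <- sample.int(max_pos, n, replace = TRUE)
  w <- sample(seq(width_range[1], width_range[2]), n, replace = TRUE)
  bp(sample(chroms, n, replace = TRUE), s, s + w)
}

## ---- brute-force single-linkage temporal classification oracle ----
## peaks given as one data.frame (chrom, start, end, stage); half-open bed
## coordinates; returns sorted pattern strings, one per component.
bf_patterns <- function(df, min_bp = 1L) {
  n <- nrow(df)
  if (n == 0L) return(character(0))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (df$chrom[i] == df$chrom[j]) {
        ov <- min(df$end[i], df$end[j]) - max(df$start[i], df$start[j])
        adj[i, j] <- ov >= min_bp
      }
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      k <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[k])) next
      comp[k] <- cid
      queue <- c(queue, which(adj[k, ] & is.na(comp)))
    }
  }
  pats <- vapply(seq_len(cid), function(cc) {
    stages <- sort(unique(df$stage[comp == cc]))
    paste0(as.integer(1 %in% stages), as.integer(2 %in% stages),
           as.integer(3 %in% stages))
  }, character(1))
  sort(pats)
}

## ---- brute-force SE cutoff oracle ----
## given raw net signals (+ widths for tie order), returns the indices (in
## the given order) labeled SE by a naive scan of the scaled curve.
bf_se_indices <- function(net, width = rep(1L, length(net)),
                          pos = seq_along(net)) {
  n <- length(net)
  if (n < 3L) return(integer(0))
  ord <- order(net, width, pos)
  y <- net[ord] / max(net)
  x <- (seq_len(n) - 1) / (n - 1)
  cut_y <- NA_real_
  for (i in seq_len(n - 1L)) {
    slope <- (y[i + 1] - y[i]) / (x[i + 1] - x[i])
    if (slope > 1 + 1e-9) { cut_y <- y[i]; break }
  }
  if (is.na(cut_y)) return(integer(0))
  which(net / max(net) > cut_y)
}

## ranking fixture: loci of width 1 on chrA at distinct positions, with a
## track whose per-base value equals the requested integer net signal
mk_ranking <- function(nets, labeled = FALSE) {
  n <- length(nets)
  pos <- (seq_len(n) - 1L) * 10L
  loci <- bp("chrA", pos, pos + 1L)
  track <- trk("chrA", pos, pos + 1L, nets)
  r <- rank_loci(loci, track)
  if (labeled) find_cutoff(r) else r
}

## ---- brute-force PWM scan oracle: per-position, per-strand scoring ----
bf_scan <- function(seq, p) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  sm <- p$score_matrix
  w <- ncol(sm)
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- length(chars)
  hits <- list()
  if (L < w) {
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0)))
  }
  for (off in 0:(L - w)) {
    for (str in c("+", "-")) {
      win <- chars[(off + 1):(off + w)]
      if (str == "-") win <- rev(unname(comp[win]))
      sc <- 0
      for (j in seq_len(w)) {
        sc <- sc + if (win[j] %in% rownames(sm)) sm[win[j], j] else -Inf
      }
      if (sc >= p$threshold) {
        hits[[length(hits) + 1L]] <- data.frame(offset = off, strand = str,
                                                score = sc)
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(offset = integer(0), strand = character(0),
               score = numeric(0))
  out[order(out$offset, out$strand), , drop = FALSE]
}

## tiny gene table helper (1-based coordinates)
genes_df <- function(ids, chrom, start, end, strand = "+") {
  gene_annotation(ids, chrom, start, end, strand)
}
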