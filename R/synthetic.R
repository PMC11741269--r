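## Deterministic seeded generators for every pipeline input, with planted
## ground truth. Every generator is a pure function of (seed, parameters):
## the caller's RNG state is never consumed, and one study-level seed fans
## out to per-generator child seeds by the fixed offsets in SEED_OFFSETS.

#' Generate a synthetic genome and gene annotation
#'
#' Genes are placed without overlap on a slot grid (uniformly sampled slots,
#' uniform jitter within the slot), with random strands and widths. Gene ids
#' are assigned in coordinate order.
#'
#' @param seed Integer seed.
#' @param n_chroms Number of chromosomes.
#' @param chrom_len Length of each chromosome (bp).
#' @param n_genes Number of genes.
#' @param gene_width Two-element range of gene body widths.
#' @param min_gap Minimum gap between gene slots.
#' @return List with `genes` (gene annotation data.frame) and `chrom_sizes`
#'   (named vector).
#' @export
gen_genome_and_genes <- function(seed, n_chroms = 4L, chrom_len = 5e6,
                                 n_genes = 300L,
                                 gene_width = c(2000L, 8000L),
                                 min_gap = 2000L) {
  chroms <- sprintf("chr%d", seq_len(n_chroms))
  chrom_sizes <- setNames(rep(chrom_len, n_chroms), chroms)
  slot <- max(gene_width) + min_gap
  per_chrom <- floor(chrom_len / slot)
  capacity <- n_chroms * per_chrom
  if (n_genes > capacity) {
    stopf("cannot place %d genes: capacity %d at this density",
          n_genes, capacity)
  }
  if (n_genes == 0L) {
    return(list(genes = gene_annotation(character(0), character(0),
                                        integer(0), integer(0), character(0)),
                chrom_sizes = chrom_sizes))
  }
  with_seed(child_seed(seed, SEED_OFFSETS[["genome"]]), {
    slots <- sort(sample.int(capacity, n_genes))
    chrom_idx <- (slots - 1L) %/% per_chrom + 1L
    slot_idx <- (slots - 1L) %% per_chrom
    widths <- sample(seq(gene_width[1], gene_width[2], by = 100L), n_genes,
                     replace = TRUE)
    jitter <- floor(runif(n_genes) * (slot - widths - min_gap))
    start <- slot_idx * slot + min_gap / 2 + jitter + 1  # 1-based
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    df <- data.frame(chrom = chroms[chrom_idx], start = as.integer(start),
                     end = as.integer(start + widths - 1L), strand = strand,
                     stringsAsFactors = FALSE)
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    genes <- gene_annotation(
      gene_id = sprintf("g%04d", seq_len(n_genes)),
      chrom = df$chrom, start = df$start, end = df$end, strand = df$strand
    )
    list(genes = genes, chrom_sizes = chrom_sizes)
  })
}

PATTERNS3 <- c("100", "010", "001", "110", "101", "011", "111")

#' Generate three stage-resolved peak sets with planted temporal classes
#'
#' For each of the 7 nonempty stage-membership patterns, exactly
#' `class_counts[pattern]` loci are emitted. A locus present in several
#' stages emits one peak per member stage, each jittered by at most
#' `peak_width / 4`, so the stage peaks of a locus still overlap while
#' distinct loci never touch.
#'
#' @param seed Integer seed.
#' @param class_counts Named integer vector over the 7 patterns
#'   (`"100"`, `"010"`, ..., `"111"`; earliest stage first). Unnamed
#'   vectors of length 7 are taken in that order.
#' @param peak_width Peak width in bp.
#' @param stage_labels Three stage names, early to late.
#' @param chrom_sizes Named chromosome sizes.
#' @return List with `stages` (named list of 3 peak `GRanges`) and `truth`
#'   (data.frame: locus id, BED coordinates, planted pattern).
#' @export
gen_stage_peaks <- function(seed, class_counts, peak_width = 400L,
                            stage_labels = c("stage8", "stage9", "stage10.5"),
                            chrom_sizes) {
  if (is.null(names(class_counts))) names(class_counts) <- PATTERNS3
  stopifnot(setequal(names(class_counts), PATTERNS3))
  class_counts <- class_counts[PATTERNS3]
  n_loci <- sum(class_counts)
  chroms <- names(chrom_sizes)
  slot <- 5L * peak_width
  per_chrom <- floor(chrom_sizes / slot)
  capacity <- sum(per_chrom)
  if (n_loci > capacity) stopf("cannot place %d peak loci without overlap",
                               n_loci)
  empty_stage <- function(lb) peak_set(character(0), 0, 0, label = lb)
  if (n_loci == 0L) {
    return(list(
      stages = setNames(lapply(stage_labels, empty_stage), stage_labels),
      truth = data.frame(locus_id = character(0), chrom = character(0),
                         start = integer(0), end = integer(0),
                         pattern = character(0))
    ))
  }
  with_seed(child_seed(seed, SEED_OFFSETS[["peaks"]]), {
    slots <- sort(sample.int(capacity, n_loci))
    cum <- cumsum(per_chrom)
    chrom_idx <- findInterval(slots - 1L, c(0, cum), rightmost.closed = FALSE)
    slot_idx <- slots - c(0, cum)[chrom_idx] - 1L
    base_start <- slot_idx * slot + 2L * peak_width  # BED start of the locus
    pattern <- rep(PATTERNS3, times = class_counts)
    pattern <- pattern[sample.int(n_loci)]  # shuffle loci over positions
    truth <- data.frame(
      locus_id = sprintf("locus%04d", seq_len(n_loci)),
      chrom = chroms[chrom_idx],
      start = base_start, end = base_start + peak_width,
      pattern = pattern, stringsAsFactors = FALSE
    )
    max_jitter <- floor(peak_width / 4)
    stages <- lapply(1:3, function(st) {
      member <- substr(truth$pattern, st, st) == "1"
      if (!any(member)) return(empty_stage(stage_labels[st]))
      jit <- sample(seq(-max_jitter, max_jitter), sum(member), replace = TRUE)
      s <- truth$start[member] + jit
      peak_set(truth$chrom[member], s, s + peak_width,
               summit = s + floor(peak_width / 2),
               name = paste0(truth$locus_id[member], "_", stage_labels[st]),
               label = stage_labels[st])
    })
    list(stages = setNames(stages, stage_labels), truth = truth)
  })
}

#' Generate an enhancer landscape with planted super-enhancers
#'
#' Emits regular-enhancer peaks (one short peak per RE locus) and `n_se`
#' clusters of closely spaced enhancer peaks spanning about `se_span` bp,
#' together with a coverage track in which SE constituents carry amplitude
#' `se_amp` and RE peaks `re_amp`, plus truncated Gaussian amplitude noise.
#' SE clusters can be anchored near chosen positions (e.g. upstream of
#' genes) so SE-associated genes are known.
#'
#' @param seed Integer seed.
#' @param chrom_sizes Named chromosome sizes.
#' @param n_re Number of regular-enhancer loci.
#' @param n_se Number of super-enhancer clusters.
#' @param se_span Approximate SE cluster span (bp).
#' @param se_constituents Peaks per SE cluster.
#' @param peak_width RE peak width (bp); SE constituents are 2000 bp.
#' @param se_amp,re_amp Per-base signal amplitudes.
#' @param noise_sd SD of the Gaussian amplitude noise (truncated at 0).
#' @param se_anchors Optional data.frame (`chrom`, `pos`) of BED positions
#'   where SE clusters start; defaults to sampled slots.
#' @return List with `peaks` (enhancer peak `GRanges`), `track` (signal
#'   `GRanges`) and `truth` (list: `se_loci`, `re_loci` data.frames with
#'   BED coordinates).
#' @export
gen_signal_with_ses <- function(seed, chrom_sizes, n_re = 200L, n_se = 5L,
                                se_span = 20000L, se_constituents = 5L,
                                peak_width = 1000L, se_amp = 10, re_amp = 1,
                                noise_sd = 0.2, se_anchors = NULL) {
  chroms <- names(chrom_sizes)
  slot <- 2L * se_span
  per_chrom <- floor(chrom_sizes / slot)
  capacity <- sum(per_chrom)
  need_slots <- n_re + if (is.null(se_anchors)) n_se else 0L
  if (need_slots > capacity) stopf("cannot place %d enhancer loci", need_slots)
  if (!is.null(se_anchors) && nrow(se_anchors) != n_se) {
    stopf("se_anchors must have one row per SE cluster")
  }
  with_seed(child_seed(seed, SEED_OFFSETS[["signal"]]), {
    slots <- sort(sample.int(capacity, need_slots))
    cum <- cumsum(per_chrom)
    chrom_idx <- findInterval(slots - 1L, c(0, cum), rightmost.closed = FALSE)
    slot_start <- (slots - c(0, cum)[chrom_idx] - 1L) * slot + se_span / 2
    slot_chrom <- chroms[chrom_idx]
    if (is.null(se_anchors)) {
      se_pick <- if (n_se > 0L) sort(sample.int(need_slots, n_se)) else integer(0)
      se_chrom <- slot_chrom[se_pick]
      se_start <- slot_start[se_pick]
      re_chrom <- slot_chrom[setdiff(seq_len(need_slots), se_pick)]
      re_start <- slot_start[setdiff(seq_len(need_slots), se_pick)]
    } else {
      se_chrom <- se_anchors$chrom
      se_start <- se_anchors$pos
      re_chrom <- slot_chrom
      re_start <- slot_start
    }
    ## RE peaks: one short peak per locus
    pk_chrom <- re_chrom
    pk_start <- re_start
    pk_end <- re_start + peak_width
    pk_amp <- rep(re_amp, length(re_start))
    pk_locus <- if (length(re_start)) sprintf("RE%04d", seq_along(re_start)) else character(0)
    ## SE clusters: se_constituents peaks of 2 kb evenly spaced over se_span
    w_se <- 2000L
    if (n_se > 0L) {
      gap <- floor((se_span - se_constituents * w_se) /
                     max(se_constituents - 1L, 1L))
      offs <- (seq_len(se_constituents) - 1L) * (w_se + gap)
      pk_chrom <- c(pk_chrom, rep(se_chrom, each = se_constituents))
      se_pk_start <- rep(se_start, each = se_constituents) +
        rep(offs, times = n_se)
      pk_start <- c(pk_start, se_pk_start)
      pk_end <- c(pk_end, se_pk_start + w_se)
      pk_amp <- c(pk_amp, rep(se_amp, n_se * se_constituents))
      pk_locus <- c(pk_locus,
                    rep(sprintf("SE%02d", seq_len(n_se)),
                        each = se_constituents))
    }
    peaks <- peak_set(pk_chrom, pk_start, pk_end,
                      summit = floor((pk_start + pk_end) / 2),
                      name = paste0(pk_locus, "_pk"))
    ## signal: 200 bp tiles per peak, amplitude + truncated Gaussian noise
    tile <- 200L
    run_chrom <- character(0); run_start <- numeric(0)
    run_end <- numeric(0); run_val <- numeric(0)
    for (i in seq_along(pk_start)) {
      ts <- seq(pk_start[i], pk_end[i] - 1L, by = tile)
      te <- pmin(ts + tile, pk_end[i])
      v <- pmax(rep(pk_amp[i], length(ts)) +
                  (if (noise_sd > 0) rnorm(length(ts), 0, noise_sd) else 0), 0)
      run_chrom <- c(run_chrom, rep(pk_chrom[i], length(ts)))
      run_start <- c(run_start, ts); run_end <- c(run_end, te)
      run_val <- c(run_val, v)
    }
    track <- GenomicRanges::GRanges(
      run_chrom, IRanges::IRanges(run_start + 1, run_end), score = run_val
    )
    track <- GenomicRanges::sort(track, ignore.strand = TRUE)
    se_loci <- data.frame(
      locus_id = if (n_se > 0L) sprintf("SE%02d", seq_len(n_se)) else character(0),
      chrom = se_chrom, start = se_start,
      end = if (n_se > 0L) se_start + max(offs) + w_se else numeric(0),
      stringsAsFactors = FALSE
    )
    re_loci <- data.frame(locus_id = pk_locus[seq_along(re_start)],
                          chrom = re_chrom, start = re_start,
                          end = re_start + peak_width,
                          stringsAsFactors = FALSE)
    list(peaks = peaks, track = track,
         truth = list(se_loci = se_loci, re_loci = re_loci))
  })
}

#' Generate wild-type and morphant count tables with planted direct targets
#'
#' Counts are negative binomial with gene-level means (variance =
#' mean + dispersion * mean^2). In a factor's morphant, the mean of that
#' factor's planted targets is scaled by `2^(-effect)` for activated
#' targets (knockdown lowers them) and `2^(+effect)` for repressed targets.
#'
#' @param seed Integer seed.
#' @param genes Gene annotation data.frame (the gene universe).
#' @param targets data.frame with columns `gene_id`, `factor` (`"A"`,
#'   `"B"` or `"both"`), `direction` (`"activated"`/`"repressed"`) and
#'   `effect` (true |log2 fold change|).
#' @param n_reps Replicates per condition (>= 2).
#' @param dispersion NB dispersion; 0 gives Poisson counts.
#' @param base_meanlog,base_sdlog Log-normal parameters of gene base means.
#' @return List with count matrices `wt`, `morphant_A`, `morphant_B`
#'   (genes x reps), `base_mean`, and `truth` (the targets table).
#' @export
gen_morphant_counts <- function(seed, genes, targets = NULL, n_reps = 3L,
                                dispersion = 0.05,
                                base_meanlog = log(200), base_sdlog = 1) {
  if (n_reps < 2L) stopf("n_reps must be >= 2")
  ids <- genes$gene_id
  n <- length(ids)
  if (is.null(targets)) {
    targets <- data.frame(gene_id = character(0), factor = character(0),
                          direction = character(0), effect = numeric(0))
  }
  if (!all(targets$gene_id %in% ids)) stopf("targets outside gene universe")
  with_seed(child_seed(seed, SEED_OFFSETS[["counts"]]), {
    base_mean <- setNames(rlnorm(n, base_meanlog, base_sdlog), ids)
    draw <- function(mu) {
      m <- matrix(0, nrow = n, ncol = n_reps,
                  dimnames = list(ids, paste0("rep", seq_len(n_reps))))
      for (j in seq_len(n_reps)) {
        m[, j] <- if (dispersion > 0) {
          rnbinom(n, mu = mu, size = 1 / dispersion)
        } else {
          rpois(n, mu)
        }
      }
      m
    }
    morph_mean <- function(which_factor) {
      mu <- base_mean
      sel <- targets$factor %in% c(which_factor, "both")
      if (any(sel)) {
        sgn <- ifelse(targets$direction[sel] == "activated", -1, 1)
        mu[targets$gene_id[sel]] <- mu[targets$gene_id[sel]] *
          2^(sgn * targets$effect[sel])
      }
      mu
    }
    list(wt = draw(base_mean),
         morphant_A = draw(morph_mean("A")),
         morphant_B = draw(morph_mean("B")),
         base_mean = base_mean, truth = targets)
  })
}

#' Generate a clustered single-nucleus expression matrix
#'
#' Counts are Poisson-lognormal: per gene and cell,
#' `count ~ Poisson(depth * p)`, with `p` proportional to the gene's base
#' rate times `exp(N(0, sigma_g))`. Robust (SE-associated) genes carry a
#' higher base rate (`robust_mean_boost`) and a smaller lognormal sigma
#' (`robust_sigma` vs `base_sigma`), so they come out with elevated mean and
#' depressed coefficient of variation. Two marker genes are planted per
#' cluster (boosted `marker_boost`-fold in their cluster) for z-score tests.
#'
#' @param seed Integer seed.
#' @param genes Gene annotation data.frame (the gene universe).
#' @param clusters data.frame (`cluster`, `proportion`), proportions summing
#'   to 1; default: the 13 cell states of [default_cell_states()], near-equal.
#' @param robust_genes Gene ids planted as robust.
#' @param n_cells Number of cells.
#' @param depth Expected library size per cell.
#' @param base_sigma,robust_sigma Lognormal sigma of background vs robust
#'   genes.
#' @param robust_mean_boost Base-rate multiplier of robust genes.
#' @param marker_boost In-cluster rate multiplier of planted markers.
#' @return List with `mat` (a [labeled_matrix()]) and `truth` (list:
#'   `robust_genes`, `markers` named by cluster, `cluster_table`).
#' @export
gen_sc_matrix <- function(seed, genes, clusters = NULL,
                          robust_genes = character(0), n_cells = 2000L,
                          depth = 2000, base_sigma = 0.8,
                          robust_sigma = 0.25, robust_mean_boost = 4,
                          marker_boost = 8) {
  ids <- genes$gene_id
  n_genes <- length(ids)
  if (is.null(clusters)) {
    cs <- default_cell_states()
    clusters <- data.frame(cluster = cs$cluster,
                           proportion = rep(1 / nrow(cs), nrow(cs)))
  }
  if (abs(sum(clusters$proportion) - 1) > 1e-6) {
    stopf("cluster proportions must sum to 1")
  }
  if (!all(robust_genes %in% ids)) stopf("robust_genes outside gene universe")
  with_seed(child_seed(seed, SEED_OFFSETS[["sc"]]), {
    rate <- setNames(rlnorm(n_genes, 0, 0.5), ids)
    rate[robust_genes] <- rate[robust_genes] * robust_mean_boost
    sigma <- setNames(rep(base_sigma, n_genes), ids)
    sigma[robust_genes] <- robust_sigma
    ## plant 2 markers per cluster from the non-robust pool
    pool <- setdiff(ids, robust_genes)
    n_mark <- min(2L * nrow(clusters), length(pool))
    mark_ids <- if (n_mark > 0) sample(pool, n_mark) else character(0)
    markers <- split(mark_ids,
                     rep(clusters$cluster, length.out = length(mark_ids)))
    if (n_cells == 0L) {
      m <- labeled_matrix(
        matrix(0L, nrow = n_genes, ncol = 0, dimnames = list(ids, NULL)),
        factor(character(0), levels = clusters$cluster)
      )
      return(list(mat = m,
                  truth = list(robust_genes = robust_genes, markers = markers,
                               cluster_table = table(m$clusters))))
    }
    cell_cluster <- sample(clusters$cluster, n_cells, replace = TRUE,
                           prob = clusters$proportion)
    boost <- matrix(1, nrow = n_genes, ncol = nrow(clusters),
                    dimnames = list(ids, clusters$cluster))
    for (k in names(markers)) boost[markers[[k]], k] <- marker_boost
    eps <- matrix(rnorm(n_genes * n_cells, 0, sigma), nrow = n_genes)
    lam <- rate * exp(eps) * boost[, cell_cluster, drop = FALSE]
    lam <- sweep(lam, 2, colSums(lam), "/") * depth
    counts <- matrix(rpois(n_genes * n_cells, lam), nrow = n_genes,
                     dimnames = list(ids, sprintf("cell%05d",
                                                  seq_len(n_cells))))
    m <- labeled_matrix(counts, factor(cell_cluster,
                                       levels = clusters$cluster))
    list(mat = m,
         truth = list(robust_genes = robust_genes, markers = markers,
                      cluster_table = table(m$clusters)))
  })
}

#' Generate factor/coactivator peak sets tied to target genes
#'
#' Places one binding peak of the relevant factor(s) straddling each
#' planted target gene's 5' end (so the peak overlaps the gene body and the
#' nearest-gene assignment is unambiguous); joint targets receive
#' overlapping peaks of both factors plus a coactivator peak (an FSE
#' region). Additional background co-bound and coactivator-only regions are
#' planted away from genes.
#'
#' @param seed Integer seed.
#' @param genes Gene annotation data.frame.
#' @param targets Planted target table (see [gen_morphant_counts()]).
#' @param chrom_sizes Named chromosome sizes.
#' @param peak_width Peak width in bp.
#' @param n_bg_cobound,n_bg_coact_only Background regions: co-bound by both
#'   factors plus coactivator (FSE, not near targets) and coactivator-only.
#' @return List with `tfA`, `tfB`, `coact` peak `GRanges` and `truth`
#'   (data.frame of planted regions: kind, coordinates, gene).
#' @export
gen_factor_peaks <- function(seed, genes, targets, chrom_sizes,
                             peak_width = 400L,
                             n_bg_cobound = 20L, n_bg_coact_only = 20L) {
  with_seed(child_seed(seed, SEED_OFFSETS[["cooccup"]]), {
    gi <- match(targets$gene_id, genes$gene_id)
    ## peak centered on the gene 5' end: overlaps the body, distance 0
    pk_start <- pmax(genes$start[gi] - 1L - peak_width %/% 2L, 0L)
    pk_end <- pk_start + peak_width
    reg <- data.frame(kind = targets$factor, chrom = genes$chrom[gi],
                      start = pk_start, end = pk_end,
                      gene_id = targets$gene_id, stringsAsFactors = FALSE)
    ## background regions in gene-free territory: high coordinates are kept
    ## gene-free by placing past the last gene slot of each chromosome
    n_bg <- n_bg_cobound + n_bg_coact_only
    if (n_bg > 0) {
      bg_chrom <- sample(names(chrom_sizes), n_bg, replace = TRUE)
      ## stack background regions on a fixed grid near the chromosome end
      offs <- ave(seq_len(n_bg), bg_chrom, FUN = seq_along)
      bg_start <- chrom_sizes[bg_chrom] - 40000L - offs * 5000L
      bg_kind <- c(rep("bg_fse", n_bg_cobound),
                   rep("bg_coact", n_bg_coact_only))
      reg <- rbind(reg, data.frame(kind = bg_kind, chrom = bg_chrom,
                                   start = bg_start,
                                   end = bg_start + peak_width,
                                   gene_id = NA_character_,
                                   stringsAsFactors = FALSE))
    }
    jit <- function() sample(seq(-peak_width %/% 4, peak_width %/% 4), 1L)
    mk <- function(sel, label) {
      r <- reg[sel, , drop = FALSE]
      if (!nrow(r)) return(peak_set(character(0), 0, 0, label = label))
      j <- vapply(seq_len(nrow(r)), function(i) jit(), integer(1))
      s <- pmax(r$start + j, 0)
      peak_set(r$chrom, s, s + peak_width,
               summit = s + peak_width %/% 2,
               name = paste0(label, "_", seq_len(nrow(r))), label = label)
    }
    tfA <- mk(reg$kind %in% c("A", "both", "bg_fse"), "tfA")
    tfB <- mk(reg$kind %in% c("B", "both", "bg_fse"), "tfB")
    coact <- mk(reg$kind %in% c("both", "bg_fse", "bg_coact"), "coact")
    list(tfA = tfA, tfB = tfB, coact = coact, truth = reg)
  })
}

#' Generate peak-summit window sequences with planted motif sites
#'
#' Emits one random window of width `2 * flank` per peak (uniform base
#' composition); where a planting row names the peak, the motif's consensus
#' (or its reverse complement) is written at the given summit-relative
#' offset.
#'
#' @param seed Integer seed.
#' @param peaks Peak `GRanges` (names are used as sequence names).
#' @param flank Half-window in bp.
#' @param plant Optional data.frame (`peak`, `consensus`, `offset`,
#'   `strand`): `offset` is the site midpoint relative to the summit.
#' @return Named character vector of window sequences, aligned to `peaks`.
#' @export
gen_window_sequences <- function(seed, peaks, flank = 1000L, plant = NULL) {
  with_seed(child_seed(seed, SEED_OFFSETS[["seqs"]]), {
    n <- length(peaks)
    width <- 2L * flank
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(DNA_BASES, width, replace = TRUE), collapse = "")
    }, character(1))
    names(seqs) <- if (!is.null(mcols(peaks)$name)) mcols(peaks)$name else
      paste0("peak_", seq_len(n))
    if (!is.null(plant) && nrow(plant)) {
      for (i in seq_len(nrow(plant))) {
        j <- match(plant$peak[i], names(seqs))
        if (is.na(j)) next
        site <- toupper(plant$consensus[i])
        if (!is.null(plant$strand) && plant$strand[i] == "-") {
          site <- revcomp(site)
        }
        w <- nchar(site)
        at <- flank + plant$offset[i] - floor(w / 2) + 1L  # 1-based in window
        if (at >= 1L && at + w - 1L <= width) {
          substr(seqs[j], at, at + w - 1L) <- site
        }
      }
    }
    seqs
  })
}
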