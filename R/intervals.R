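## Core interval data model and algebra. Peaks and signal live in GRanges;
## the constructors below convert from the BED convention (0-based half-open)
## used by every on-disk format this package reads and writes.

#' Construct a peak set from BED-convention coordinates
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Numeric vectors, 0-based half-open (BED convention).
#' @param summit Absolute 0-based summit positions, or `NA` where absent.
#' @param score Nonnegative numeric peak scores.
#' @param name Peak names (free text).
#' @param label Optional set-level label (stage/factor), stored in
#'   [S4Vectors::metadata()].
#' @return A [GenomicRanges::GRanges] sorted by (chrom, start), with metadata
#'   columns `summit` (absolute 1-based position, `NA` if absent), `score`
#'   and `name`, deduplicated on (chrom, start, end).
#' @export
peak_set <- function(chrom, start, end, summit = NA_integer_, score = 0,
                     name = NA_character_, label = NULL) {
  n <- if (length(chrom) == 0L || length(start) == 0L || length(end) == 0L)
    0L else max(length(chrom), length(start), length(end))
  if (n == 0L) {
    gr <- GenomicRanges::GRanges()
    mcols(gr)$summit <- integer(0)
    mcols(gr)$score <- numeric(0)
    mcols(gr)$name <- character(0)
    metadata(gr)$label <- label
    return(gr)
  }
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  if (any(start < 0)) stopf("negative start coordinate")
  bad <- which(start >= end)
  if (length(bad)) stopf("invalid interval: start >= end at record %d", bad[1])
  summit <- rep_len(as.numeric(summit), n)
  ok <- !is.na(summit)
  if (any(ok & (summit < start | summit >= end))) {
    stopf("summit outside its interval")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1, end = end),
    summit = ifelse(is.na(summit), NA_integer_, as.integer(summit + 1)),
    score = rep_len(as.numeric(score), n),
    name = rep_len(as.character(name), n)
  )
  GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevels(gr))
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  dup <- duplicated(paste(as.character(seqnames(gr)), start(gr), end(gr)))
  gr <- gr[!dup]
  metadata(gr)$label <- label
  gr
}

#' Read peaks from BED or narrowPeak
#'
#' Parses BED3/BED6 or ENCODE narrowPeak (BED6+4). narrowPeak column 10 is
#' the summit offset from the region start; an offset of -1 means the summit
#' is absent. Records are sorted by (chrom, start) and deduplicated on
#' (chrom, start, end).
#'
#' @param path File path.
#' @param dialect `"bed"` or `"narrowPeak"`.
#' @param label Optional set label.
#' @return A peak `GRanges` (see [peak_set()]).
#' @export
read_peaks <- function(path, dialect = c("bed", "narrowPeak"), label = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(peak_set(character(0), 0, 0, label = label))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  min_cols <- if (dialect == "narrowPeak") 10L else 3L
  bad <- which(nf < min_cols)
  if (length(bad)) {
    stopf("parse error at line %d of %s: expected >= %d tab-separated columns",
          lineno[bad[1]], path, min_cols)
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  chrom <- col(1)
  start <- suppressWarnings(as.numeric(col(2)))
  end <- suppressWarnings(as.numeric(col(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stopf("parse error at line %d of %s: non-numeric coordinates",
          lineno[bad[1]], path)
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stopf("validation error at line %d of %s: start >= end",
          lineno[bad[1]], path)
  }
  name <- if (all(nf >= 4L)) col(4) else NA_character_
  score <- if (all(nf >= 5L)) suppressWarnings(as.numeric(col(5))) else 0
  score[is.na(score)] <- 0
  summit <- NA_real_
  if (dialect == "narrowPeak") {
    off <- suppressWarnings(as.numeric(col(10)))
    bad <- which(is.na(off))
    if (length(bad)) {
      stopf("parse error at line %d of %s: non-numeric summit offset",
            lineno[bad[1]], path)
    }
    summit <- ifelse(off < 0, NA_real_, start + off)
  }
  peak_set(chrom, start, end, summit = summit, score = score, name = name,
           label = label)
}

#' Write a peak set (or any GRanges) as BED6
#'
#' Emits 0-based half-open coordinates in deterministic order
#' (chrom lexicographic, then start). Strand is written as `.` unless set.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param name_col Metadata column used for the BED name field (default
#'   `"name"`; missing values become `"."`).
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path, name_col = "name") {
  if (length(gr)) {
    ord <- order(as.character(seqnames(gr)), start(gr), end(gr))
    gr <- gr[ord]
  }
  nm <- if (name_col %in% names(mcols(gr))) {
    as.character(mcols(gr)[[name_col]])
  } else {
    rep(NA_character_, length(gr))
  }
  nm[is.na(nm)] <- "."
  sc <- if ("score" %in% names(mcols(gr))) mcols(gr)$score else rep(0, length(gr))
  sc[is.na(sc)] <- 0
  str <- as.character(strand(gr))
  str[str == "*"] <- "."
  out <- paste(as.character(seqnames(gr)), format(start(gr) - 1, scientific = FALSE, trim = TRUE),
               format(end(gr), scientific = FALSE, trim = TRUE), nm,
               format(sc, scientific = FALSE, trim = TRUE), str, sep = "\t")
  writeLines(out, path)
  invisible(path)
}

#' Do two intervals overlap by at least `min_bp` bases?
#'
#' Half-open interval arithmetic: `[100,300)` and `[300,400)` share no base.
#' Symmetric in its two arguments.
#'
#' @param a,b Single-range `GRanges` (or peak sets of length 1).
#' @param min_bp Minimum shared bases (>= 1).
#' @return Logical scalar.
#' @export
overlaps_bp <- function(a, b, min_bp = 1L) {
  if (!is_count(min_bp, min = 1)) stopf("min_bp must be a positive integer")
  stopifnot(length(a) == 1L, length(b) == 1L)
  if (as.character(seqnames(a)) != as.character(seqnames(b))) return(FALSE)
  ov <- min(end(a), end(b)) - max(start(a), start(b)) + 1L
  ov >= min_bp
}

#' Merge peaks separated by at most `max_gap` bases
#'
#' Output intervals are pairwise separated by more than `max_gap`; the union
#' of input bases is preserved, and the operation is idempotent. This is also
#' the stitching primitive used by super-enhancer calling.
#'
#' @param peaks A peak `GRanges`.
#' @param max_gap Nonnegative integer gap (BED-convention bp between
#'   intervals) at or below which neighbours merge.
#' @return A `GRanges` of merged loci with metadata column `n_constituents`.
#' @export
merge_peaks <- function(peaks, max_gap = 0L) {
  if (!is_count(max_gap)) stopf("max_gap must be a nonnegative integer")
  if (!length(peaks)) return(peaks[, character(0)])
  red <- GenomicRanges::reduce(peaks, min.gapwidth = max_gap + 1L,
                               with.revmap = TRUE, ignore.strand = TRUE)
  mcols(red)$n_constituents <- lengths(mcols(red)$revmap)
  mcols(red)$revmap <- NULL
  red
}

#' Read a bedGraph signal track
#'
#' @param path bedGraph file path.
#' @return A `GRanges` with metadata column `score` (the per-base value of
#'   each run), sorted, non-overlapping runs.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  if (any(!is.finite(mcols(gr)$score)) || any(mcols(gr)$score < 0)) {
    stopf("signal track values must be finite and nonnegative")
  }
  gr
}

#' Write a signal track as bedGraph
#' @param track Signal `GRanges` with a `score` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  ord <- order(as.character(seqnames(track)), start(track))
  track <- track[ord]
  out <- paste(as.character(seqnames(track)),
               format(start(track) - 1, scientific = FALSE, trim = TRUE),
               format(end(track), scientific = FALSE, trim = TRUE),
               format(mcols(track)$score, scientific = FALSE, trim = TRUE),
               sep = "\t")
  writeLines(out, path)
  invisible(path)
}

#' Sum per-base signal within intervals
#'
#' For each query interval, sums value x covered-width over all track runs
#' intersecting it; bases not covered by any run contribute 0. Additive over
#' any partition of the interval.
#'
#' @param track Signal `GRanges` with `score`.
#' @param intervals Query `GRanges`.
#' @return Numeric vector, one sum per query interval.
#' @export
window_sum <- function(track, intervals) {
  out <- numeric(length(intervals))
  if (!length(track) || !length(intervals)) return(out)
  hits <- GenomicRanges::findOverlaps(intervals, track, ignore.strand = TRUE)
  if (!length(hits)) return(out)
  q <- queryHits(hits); s <- subjectHits(hits)
  w <- pmin(end(intervals)[q], end(track)[s]) -
    pmax(start(intervals)[q], start(track)[s]) + 1
  contrib <- w * mcols(track)$score[s]
  agg <- tapply(contrib, q, sum)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

anchor_positions <- function(regions) {
  if (!length(regions)) return(integer(0))
  a <- if ("summit" %in% names(mcols(regions))) mcols(regions)$summit else
    rep(NA_integer_, length(regions))
  mid <- floor((start(regions) - 1 + end(regions)) / 2) + 1L  # midpoint, 1-based
  ifelse(is.na(a), mid, a)
}

#' Binned signal matrix around region anchors
#'
#' Each region is anchored on its summit (midpoint when the summit is
#' absent); the window `[anchor - flank, anchor + flank)` is cut into
#' fixed-width bins and the per-bin [window_sum()] recorded. Windows running
#' off the chromosome start are padded with zeros, never truncated.
#'
#' @param track Signal `GRanges`.
#' @param regions Peak `GRanges`.
#' @param flank Half-window in bp; must be divisible by `bin`.
#' @param bin Bin width in bp.
#' @return A list with `profile` (regions x bins matrix) and `means`
#'   (column mean vector for metaplots).
#' @export
aggregate_profile <- function(track, regions, flank = 25000L, bin = 100L) {
  if (flank %% bin != 0) stopf("flank must be divisible by bin")
  n_bins <- as.integer(2 * flank / bin)
  n <- length(regions)
  prof <- matrix(0, nrow = n, ncol = n_bins)
  if (n == 0L) return(list(profile = prof, means = numeric(n_bins)))
  anchors <- anchor_positions(regions)
  chroms <- as.character(seqnames(regions))
  ## all bins for all regions in one GRanges; starts below 1 clip harmlessly
  ## (no signal exists there), preserving the zero-padding contract
  bin_start <- rep(anchors, each = n_bins) - flank +
    rep(seq_len(n_bins) - 1L, times = n) * bin
  bin_end <- bin_start + bin - 1L
  valid <- bin_end >= 1L
  bins <- GenomicRanges::GRanges(
    rep(chroms, each = n_bins)[valid],
    IRanges::IRanges(pmax(bin_start[valid], 1L), bin_end[valid])
  )
  sums <- numeric(n * n_bins)
  sums[valid] <- window_sum(track, bins)
  prof <- matrix(sums, nrow = n, ncol = n_bins, byrow = TRUE)
  rownames(prof) <- if (!is.null(mcols(regions)$name)) mcols(regions)$name
  list(profile = prof, means = colMeans(prof))
}

#' Read gene models from GFF3
#'
#' Keeps `gene` features only. GFF3 1-based inclusive coordinates map
#' directly onto the internal convention. The TSS is strand-aware: the gene
#' start on plus, the gene end on minus.
#'
#' @param path GFF3 file path.
#' @return A data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss` (all coordinates 1-based inclusive).
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[mcols(gr)$type == "gene"]
  id <- mcols(gr)$ID
  if (is.null(id)) id <- mcols(gr)$gene_id
  if (is.null(id)) id <- mcols(gr)$Name
  if (is.null(id) && length(gr)) stopf("GFF3 gene features lack ID attributes")
  gene_annotation(
    gene_id = as.character(id),
    chrom = as.character(seqnames(gr)),
    start = start(gr),
    end = end(gr),
    strand = as.character(strand(gr))
  )
}

#' Construct a gene annotation table
#'
#' @param gene_id Unique gene identifiers.
#' @param chrom Chromosome names.
#' @param start,end 1-based inclusive gene body coordinates.
#' @param strand `"+"` or `"-"`.
#' @return A `data.frame` with a strand-aware `tss` column.
#' @export
gene_annotation <- function(gene_id, chrom, start, end, strand) {
  if (anyDuplicated(gene_id)) stopf("gene ids must be unique")
  if (length(gene_id) && any(start > end)) stopf("gene start > end")
  df <- data.frame(
    gene_id = as.character(gene_id), chrom = as.character(chrom),
    start = as.integer(start), end = as.integer(end),
    strand = as.character(strand), stringsAsFactors = FALSE
  )
  df$tss <- ifelse(df$strand == "-", df$end, df$start)
  df
}

#' Gene bodies as GRanges
#' @param genes A gene annotation data.frame (see [gene_annotation()]).
#' @return `GRanges` named by gene id.
#' @export
genes_as_granges <- function(genes) {
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand
  )
  names(gr) <- genes$gene_id
  gr
}

#' Write a gene annotation as GFF3
#' @param genes Gene annotation data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  ord <- order(genes$chrom, genes$start)
  g <- genes[ord, , drop = FALSE]
  lines <- c("##gff-version 3",
             paste(g$chrom, "crmscape", "gene", g$start, g$end, ".",
                   g$strand, ".", paste0("ID=", g$gene_id), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
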