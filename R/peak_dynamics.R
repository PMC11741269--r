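## Temporal occupancy classification across three stages, and
## TF/TF/coactivator co-occupancy calling.

## Single-linkage clustering of peaks from several sets: peaks landing in the
## same component if connected by a chain of pairwise overlaps >= min_bp.
cluster_peak_sets <- function(sets, min_bp = 1L) {
  stopifnot(length(sets) >= 1L)
  all_peaks <- suppressWarnings(do.call(c, lapply(sets, function(g) {
    GenomicRanges::granges(g)
  })))
  origin <- rep(seq_along(sets), lengths(sets))
  within_idx <- unlist(lapply(sets, function(g) seq_len(length(g))),
                       use.names = FALSE)
  n <- length(all_peaks)
  if (n == 0L) {
    return(list(peaks = all_peaks, origin = origin, within = within_idx,
                component = integer(0)))
  }
  hits <- GenomicRanges::findOverlaps(all_peaks, all_peaks,
                                      minoverlap = as.integer(min_bp),
                                      ignore.strand = TRUE)
  comp <- union_find_components(n, queryHits(hits), subjectHits(hits))
  list(peaks = all_peaks, origin = origin, within = within_idx,
       component = comp)
}

#' Default Roman-numeral display map for temporal classes
#'
#' The canonical class identity is the stage-membership pattern itself (a
#' 3-character bit string, earliest stage first). Roman numerals are a
#' figure-level presentation convention that differs between published
#' factors, so the mapping is a replaceable table. The default follows the
#' convention in which stage-unique patterns take I, III and VI, pairwise
#' shared patterns II, IV and V, and the persistent pattern VII.
#'
#' @return Named character vector: pattern -> Roman numeral.
#' @export
temporal_class_map <- function() {
  c("100" = "I", "110" = "II", "010" = "III", "011" = "IV",
    "101" = "V", "001" = "VI", "111" = "VII")
}

#' Classify peaks by temporal occupancy across three stages
#'
#' Peaks from the three stage-resolved sets are single-linkage clustered by
#' overlap; each cluster (locus) receives the membership pattern of the
#' stages contributing peaks to it. The seven nonempty stage subsets are the
#' seven temporal classes. Every input peak contributes to exactly one locus.
#'
#' @param stage1,stage2,stage3 Peak `GRanges`, ordered early to late.
#' @param min_bp Minimum pairwise overlap (bp) linking two peaks.
#' @param class_map Pattern -> display label map; see [temporal_class_map()].
#' @return An object of class `temporal_classes`: a list with `loci`
#'   (`GRanges` spanning each cluster, with `pattern`, `class` and per-stage
#'   contributing-peak counts), `stage_counts` (input sizes) and
#'   `stage_labels`.
#' @export
temporal_classify <- function(stage1, stage2, stage3, min_bp = 1L,
                              class_map = temporal_class_map()) {
  sets <- list(stage1, stage2, stage3)
  labels <- vapply(seq_along(sets), function(i) {
    lb <- metadata(sets[[i]])$label
    if (is.null(lb)) paste0("stage", i) else lb
  }, character(1))
  cl <- cluster_peak_sets(sets, min_bp = min_bp)
  if (!length(cl$peaks)) {
    loci <- GenomicRanges::GRanges()
    mcols(loci)$pattern <- character(0)
    mcols(loci)$class <- character(0)
  } else {
    comp_ids <- sort(unique(cl$component))
    chrom <- as.character(seqnames(cl$peaks))
    loci_df <- data.frame(comp = cl$component, chrom = chrom,
                          start = start(cl$peaks), end = end(cl$peaks),
                          origin = cl$origin)
    agg_start <- tapply(loci_df$start, loci_df$comp, min)
    agg_end <- tapply(loci_df$end, loci_df$comp, max)
    agg_chrom <- tapply(loci_df$chrom, loci_df$comp, `[`, 1)
    n_by <- function(stage) {
      as.integer(tapply(loci_df$origin == stage, loci_df$comp, sum))
    }
    n1 <- n_by(1); n2 <- n_by(2); n3 <- n_by(3)
    pattern <- paste0(as.integer(n1 > 0), as.integer(n2 > 0),
                      as.integer(n3 > 0))
    loci <- GenomicRanges::GRanges(
      as.character(agg_chrom),
      IRanges::IRanges(as.integer(agg_start), as.integer(agg_end))
    )
    mcols(loci)$pattern <- pattern
    mcols(loci)$class <- unname(class_map[pattern])
    mcols(loci)$n_stage1 <- n1
    mcols(loci)$n_stage2 <- n2
    mcols(loci)$n_stage3 <- n3
    ord <- order(as.character(seqnames(loci)), start(loci))
    loci <- loci[ord]
  }
  structure(
    list(loci = loci,
         stage_counts = setNames(lengths(sets), labels),
         stage_labels = labels,
         min_bp = as.integer(min_bp)),
    class = "temporal_classes"
  )
}

#' @export
print.temporal_classes <- function(x, ...) {
  cat("Temporal occupancy classification (", length(x$loci), " loci)\n",
      sep = "")
  cat("Stages:", paste(x$stage_labels, collapse = ", "), "\n")
  print(table(mcols(x$loci)$class))
  invisible(x)
}

#' Per-class locus counts
#' @param x A `temporal_classes` object.
#' @return Named integer vector of locus counts per class label.
#' @export
class_counts <- function(x) {
  stopifnot(inherits(x, "temporal_classes"))
  tab <- table(mcols(x$loci)$class)
  setNames(as.integer(tab), names(tab))
}

#' Call TF/TF/coactivator co-occupied regions
#'
#' Regions are maximal unions of mutually overlapping peaks from the two
#' transcription factors and the coactivator (single linkage); each region
#' is flagged for the inputs that contributed. Regions carrying all three
#' flags are FSE regions (factor A + factor B + coactivator).
#'
#' @param tfA,tfB,coact Peak `GRanges` for the two TFs and the coactivator.
#' @param min_bp Minimum pairwise overlap in bp.
#' @return `GRanges` of regions with logical metadata columns `has_A`,
#'   `has_B`, `has_coact`, `fse`, and per-input contributing counts.
#' @export
co_occupancy <- function(tfA, tfB, coact, min_bp = 1L) {
  cl <- cluster_peak_sets(list(tfA, tfB, coact), min_bp = min_bp)
  if (!length(cl$peaks)) {
    out <- GenomicRanges::GRanges()
    mcols(out)$has_A <- logical(0)
    mcols(out)$has_B <- logical(0)
    mcols(out)$has_coact <- logical(0)
    mcols(out)$fse <- logical(0)
    return(out)
  }
  comp <- cl$component
  chrom <- as.character(seqnames(cl$peaks))
  agg_start <- tapply(start(cl$peaks), comp, min)
  agg_end <- tapply(end(cl$peaks), comp, max)
  agg_chrom <- tapply(chrom, comp, `[`, 1)
  has <- function(k) as.logical(tapply(cl$origin == k, comp, any))
  out <- GenomicRanges::GRanges(
    as.character(agg_chrom),
    IRanges::IRanges(as.integer(agg_start), as.integer(agg_end))
  )
  mcols(out)$has_A <- has(1)
  mcols(out)$has_B <- has(2)
  mcols(out)$has_coact <- has(3)
  mcols(out)$fse <- mcols(out)$has_A & mcols(out)$has_B & mcols(out)$has_coact
  ord <- order(as.character(seqnames(out)), start(out))
  out[ord]
}

#' Mean signal per temporal class in anchor-centered windows
#'
#' For each class and each named track, the mean [window_sum()] over windows
#' of total width `window` centered on each locus midpoint.
#'
#' @param assignment A `temporal_classes` object.
#' @param tracks Named list of signal `GRanges`.
#' @param window Total window width in bp (an even number).
#' @return Matrix of class x track mean signal.
#' @export
class_signal_summary <- function(assignment, tracks, window = 2000L) {
  stopifnot(inherits(assignment, "temporal_classes"))
  loci <- assignment$loci
  classes <- sort(unique(mcols(loci)$class))
  out <- matrix(0, nrow = length(classes), ncol = length(tracks),
                dimnames = list(classes, names(tracks)))
  if (!length(tracks) || !length(loci)) return(out)
  half <- window / 2
  anchors <- anchor_positions(loci)
  win <- GenomicRanges::GRanges(
    as.character(seqnames(loci)),
    IRanges::IRanges(pmax(1, anchors - half + 1), anchors + half)
  )
  for (j in seq_along(tracks)) {
    sums <- window_sum(tracks[[j]], win)
    m <- tapply(sums, mcols(loci)$class, mean)
    out[names(m), j] <- as.numeric(m)
  }
  out
}

#' Percentage of a subset over a total
#'
#' @param subset_count,total_count Nonnegative integers with
#'   `subset_count <= total_count`, `total_count > 0`.
#' @return List with `percent` (unrounded) and `rounded` (nearest integer).
#' @export
percent_overlap <- function(subset_count, total_count) {
  if (!is_count(total_count) || total_count == 0) {
    stopf("total_count must be a positive integer")
  }
  if (!is_count(subset_count) || subset_count > total_count) {
    stopf("subset_count must be an integer in [0, total_count]")
  }
  p <- 100 * subset_count / total_count
  list(percent = p, rounded = as.integer(round(p)))
}
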