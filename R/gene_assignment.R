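## Zygotic/localized gene selection, peak-to-gene assignment, a simple
## differential-expression caller for closed-loop synthetic testing, and
## direct-target calling from morphant DE + binding windows.

#' Select zygotically expressed genes from a timecourse
#'
#' A gene is zygotic when its pre-ZGA (0 hpf) abundance is at most
#' `maternal_max` and its maximum later-timepoint log2 ratio over the 0 hpf
#' value (with pseudocount) reaches `min_zygotic_lfc`.
#'
#' @param tc Matrix of TPM-like abundances, genes x timepoints; the first
#'   column is the 0 hpf (pre-ZGA) timepoint.
#' @param maternal_max Maximum 0 hpf abundance tolerated.
#' @param min_zygotic_lfc Minimum log2 increase over 0 hpf.
#' @param pseudocount Added to both sides of the ratio.
#' @return Character vector of retained gene ids (rownames of `tc`).
#' @export
select_zygotic <- function(tc, maternal_max = 5, min_zygotic_lfc = 1,
                           pseudocount = 1) {
  stopifnot(is.matrix(tc), ncol(tc) >= 2L)
  if (any(tc < 0)) stopf("abundances must be nonnegative")
  base <- tc[, 1]
  later <- tc[, -1, drop = FALSE]
  max_lfc <- apply(log2((later + pseudocount) / (base + pseudocount)), 1, max)
  keep <- base <= maternal_max & max_lfc >= min_zygotic_lfc
  rownames(tc)[keep]
}

#' Select tissue-localized genes from a two-tissue DE table
#'
#' Filters genes with at least `fold`-fold enrichment in either tissue, ranks
#' them by adjusted p-value (ascending), and truncates to the top `top_n`.
#'
#' @param de_tissue A DE data.frame with columns `gene`, `log2FC`, `padj`
#'   (see [simple_de()]), comparing the two tissues.
#' @param fold Minimum fold enrichment (absolute, either direction).
#' @param top_n Number of genes retained.
#' @return Character vector of gene ids, best-ranked first.
#' @export
select_localized <- function(de_tissue, fold = 2, top_n = 250L) {
  if (!nrow(de_tissue)) return(character(0))
  pass <- de_tissue[!is.na(de_tissue$log2FC) & !is.na(de_tissue$padj) &
                      abs(de_tissue$log2FC) >= log2(fold), , drop = FALSE]
  pass <- pass[order(pass$padj, pass$pvalue, pass$gene), , drop = FALSE]
  if (nrow(pass) < top_n) {
    warnf("only %d genes pass the %g-fold filter (top_n = %d requested)",
          nrow(pass), fold, top_n)
  }
  head(pass$gene, top_n)
}

#' Assign peaks to their nearest gene within a window
#'
#' Distance is 0 when the peak overlaps the gene body, otherwise the bp gap
#' between the peak edge and the nearest gene-body edge. Peaks farther than
#' `window` from every gene are unassigned (`NA`). Ties are broken by
#' smaller distance, then lexicographically smaller gene id.
#'
#' @param peaks Peak `GRanges`.
#' @param genes Gene annotation data.frame (see [gene_annotation()]).
#' @param window Maximum assignment distance in bp.
#' @return data.frame with one row per peak: `peak_id` (peak name, or its
#'   index when unnamed), `gene_id` (`NA` if unassigned), `distance`.
#' @export
assign_peaks_to_genes <- function(peaks, genes, window = 20000L) {
  if (!is_count(window)) stopf("window must be a nonnegative integer")
  peak_id <- if (!is.null(mcols(peaks)$name) &&
                 !anyNA(mcols(peaks)$name)) {
    as.character(mcols(peaks)$name)
  } else {
    paste0("peak_", seq_len(length(peaks)))
  }
  out <- data.frame(peak_id = peak_id, gene_id = NA_character_,
                    distance = NA_integer_, stringsAsFactors = FALSE)
  if (!length(peaks) || !nrow(genes)) return(out)
  ggr <- genes_as_granges(genes)
  hits <- GenomicRanges::findOverlaps(peaks, ggr, maxgap = as.integer(window),
                                      ignore.strand = TRUE)
  if (!length(hits)) return(out)
  q <- queryHits(hits); s <- subjectHits(hits)
  d <- GenomicRanges::distance(peaks[q], ggr[s], ignore.strand = TRUE)
  cand <- data.frame(q = q, gene = names(ggr)[s], d = as.integer(d))
  cand <- cand[cand$d <= window, , drop = FALSE]
  if (!nrow(cand)) return(out)
  cand <- cand[order(cand$q, cand$d, cand$gene), , drop = FALSE]
  best <- cand[!duplicated(cand$q), , drop = FALSE]
  out$gene_id[best$q] <- best$gene
  out$distance[best$q] <- best$d
  out
}

## Median-of-ratios size factors (the standard count-normalization scheme
## for RNA-seq libraries).
estimate_size_factors <- function(counts) {
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (!any(use)) stopf("no gene with all-positive counts; cannot normalize")
  apply(counts, 2, function(cnts) {
    exp(median(log(cnts[use]) - loggeo[use]))
  })
}

#' Simple differential-expression caller
#'
#' Normalizes libraries by median-of-ratios size factors, computes
#' `log2FC = log2((mean_treat + pc) / (mean_ctrl + pc))` on normalized
#' counts, tests each gene with a two-sample t-test on
#' `log2(normalized + pc)` under the standard RNA-seq assumption of a
#' shared per-gene variance across conditions (the pooled test is exactly
#' calibrated at small replicate numbers, where the unequal-variance
#' approximation is conservative), and adjusts p-values by
#' Benjamini-Hochberg. Intended for closed-loop synthetic testing;
#' externally produced DE tables in the same column layout are accepted
#' everywhere downstream.
#'
#' @param counts_treat,counts_ctrl Count matrices (genes x replicates, >= 2
#'   replicates each) sharing rownames.
#' @param pseudocount Pseudocount on normalized counts.
#' @param size_factors Optional numeric vector of length
#'   `ncol(counts_treat) + ncol(counts_ctrl)` (treatment columns first)
#'   overriding estimation, e.g. `rep(1, 4)` for pre-normalized tables.
#' @return data.frame: `gene`, `baseMean`, `log2FC` (treatment over
#'   control), `pvalue`, `padj`.
#' @export
simple_de <- function(counts_treat, counts_ctrl, pseudocount = 1,
                      size_factors = NULL) {
  stopifnot(is.matrix(counts_treat), is.matrix(counts_ctrl))
  if (ncol(counts_treat) < 2L || ncol(counts_ctrl) < 2L) {
    stopf("at least 2 replicates per group are required")
  }
  if (!identical(rownames(counts_treat), rownames(counts_ctrl))) {
    stopf("treatment and control tables must share the same gene universe")
  }
  if (sum(counts_treat) == 0 || sum(counts_ctrl) == 0) {
    stopf("a group has zero total counts")
  }
  all_counts <- cbind(counts_treat, counts_ctrl)
  sf <- if (is.null(size_factors)) estimate_size_factors(all_counts) else
    as.numeric(size_factors)
  norm <- sweep(all_counts, 2, sf, "/")
  nt <- ncol(counts_treat)
  norm_t <- norm[, seq_len(nt), drop = FALSE]
  norm_c <- norm[, -seq_len(nt), drop = FALSE]
  lfc <- log2((rowMeans(norm_t) + pseudocount) /
                (rowMeans(norm_c) + pseudocount))
  lt <- log2(norm_t + pseudocount)
  lc <- log2(norm_c + pseudocount)
  pvals <- vapply(seq_len(nrow(norm)), function(i) {
    a <- lt[i, ]; b <- lc[i, ]
    if (var(a) < 1e-12 && var(b) < 1e-12) {
      return(if (abs(mean(a) - mean(b)) < 1e-12) 1 else 0)
    }
    t.test(a, b, var.equal = TRUE)$p.value
  }, numeric(1))
  data.frame(
    gene = rownames(norm),
    baseMean = rowMeans(norm),
    log2FC = lfc,
    pvalue = pvals,
    padj = p.adjust(pvals, method = "BH"),
    stringsAsFactors = FALSE
  )
}

## Direct-target rule for one factor: fold + significance + a binding site
## of that factor within the window.
factor_targets <- function(de, assign, fold, padj_max) {
  bound <- unique(assign$gene_id[!is.na(assign$gene_id)])
  pass <- !is.na(de$log2FC) & !is.na(de$padj) &
    abs(de$log2FC) >= log2(fold) & de$padj <= padj_max &
    de$gene %in% bound
  de[pass, , drop = FALSE]
}

nearest_support <- function(genes, assign) {
  a <- assign[!is.na(assign$gene_id) & assign$gene_id %in% genes, , drop = FALSE]
  a <- a[order(a$gene_id, a$distance, a$peak_id), , drop = FALSE]
  a[!duplicated(a$gene_id), , drop = FALSE]
}

#' Call direct target genes of two factors from morphant DE
#'
#' A gene is a direct target of a factor when it changes at least
#' `fold`-fold in that factor's morphant (at `padj <= padj_max`) and has a
#' binding site of that factor within the assignment window. Direction
#' follows the fold-change sign: down in the morphant means activated by
#' the factor, up means repressed. Genes passing for both factors are
#' joint targets; the joint / A-only / B-only partition is disjoint.
#'
#' @param deA,deB DE data.frames (see [simple_de()]) for the two morphants,
#'   indexed by the same gene universe.
#' @param assignA,assignB Peak-gene maps from [assign_peaks_to_genes()] for
#'   the two factors' peaks.
#' @param fold Minimum fold change.
#' @param padj_max Adjusted-p cutoff.
#' @return An object of class `target_calls`: list with `calls` (one row per
#'   target gene: attribution, per-factor direction/lfc/padj, supporting
#'   peak and distance) and `counts` (attribution x direction table).
#' @export
call_direct_targets <- function(deA, deB, assignA, assignB, fold = 2,
                                padj_max = 0.05) {
  if (!setequal(deA$gene, deB$gene)) {
    stopf("DE tables must share the same gene universe")
  }
  tA <- factor_targets(deA, assignA, fold, padj_max)
  tB <- factor_targets(deB, assignB, fold, padj_max)
  joint <- intersect(tA$gene, tB$gene)
  only_A <- setdiff(tA$gene, joint)
  only_B <- setdiff(tB$gene, joint)
  all_genes <- c(joint, only_A, only_B)
  attribution <- c(rep("joint", length(joint)), rep("A_only", length(only_A)),
                   rep("B_only", length(only_B)))
  dirn <- function(lfc) ifelse(lfc < 0, "activated", "repressed")
  rowA <- deA[match(all_genes, deA$gene), ]
  rowB <- deB[match(all_genes, deB$gene), ]
  supA <- nearest_support(all_genes, assignA)
  supB <- nearest_support(all_genes, assignB)
  iA <- match(all_genes, supA$gene_id)
  iB <- match(all_genes, supB$gene_id)
  calls <- data.frame(
    gene = all_genes,
    attribution = attribution,
    lfc_A = rowA$log2FC, padj_A = rowA$padj,
    lfc_B = rowB$log2FC, padj_B = rowB$padj,
    direction_A = ifelse(attribution %in% c("joint", "A_only"),
                         dirn(rowA$log2FC), NA_character_),
    direction_B = ifelse(attribution %in% c("joint", "B_only"),
                         dirn(rowB$log2FC), NA_character_),
    peak_A = supA$peak_id[iA], distance_A = supA$distance[iA],
    peak_B = supB$peak_id[iB], distance_B = supB$distance[iB],
    stringsAsFactors = FALSE
  )
  if (nrow(calls)) {
    calls <- calls[order(calls$attribution, calls$gene), , drop = FALSE]
    rownames(calls) <- NULL
  }
  direction <- ifelse(calls$attribution == "B_only", calls$direction_B,
               ifelse(calls$attribution == "A_only", calls$direction_A,
               ifelse(calls$direction_A == calls$direction_B,
                      calls$direction_A, "mixed")))
  counts <- table(
    attribution = factor(calls$attribution,
                         levels = c("joint", "A_only", "B_only")),
    direction = factor(direction,
                       levels = c("activated", "repressed", "mixed"))
  )
  structure(list(calls = calls, counts = counts,
                 fold = fold, padj_max = padj_max),
            class = "target_calls")
}

#' @export
print.target_calls <- function(x, ...) {
  cat("Direct target calls (fold >= ", x$fold, ", padj <= ", x$padj_max,
      "): ", nrow(x$calls), " genes\n", sep = "")
  print(x$counts)
  invisible(x)
}
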