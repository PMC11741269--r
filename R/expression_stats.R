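## qPCR formulas, single-nucleus QC, cluster z-score localization,
## coefficient-of-variation statistics and SE/RE robustness contrasts.

#' ChIP-qPCR percent input
#'
#' `Input % = 100 / 2^(Cp[ChIP] - (Cp[Input] - log2(dilution_factor)))`.
#' The dilution factor corrects the input Cp for the fraction of chromatin
#' carried into the input reaction.
#'
#' @param cp_chip,cp_input Crossing-point values (vectors recycle).
#' @param dilution_factor Input dilution factor (>= 1).
#' @return Percent input (numeric).
#' @export
percent_input <- function(cp_chip, cp_input, dilution_factor = 1) {
  if (any(dilution_factor < 1)) stopf("dilution_factor must be >= 1")
  if (any(c(cp_chip, cp_input) <= 0)) stopf("Cp values must be positive")
  100 / 2^(cp_chip - (cp_input - log2(dilution_factor)))
}

#' Delta-delta-Cp fold change
#'
#' `2^-((Cp_target - Cp_ref)_treat - (Cp_target - Cp_ref)_ctrl)`. With
#' replicate vectors, per-replicate treatment delta-Cp values are compared
#' against the mean control delta-Cp; the mean, SD and a two-tailed Welch
#' t-test p-value on the delta-Cp values are returned.
#'
#' @param treat_target,treat_ref Treatment Cp values (target and reference
#'   gene), replicate-matched vectors.
#' @param ctrl_target,ctrl_ref Control Cp values.
#' @return List with `fold_change` (mean over replicates), `sd`, `p_value`
#'   (NA with a single replicate) and `per_replicate` fold changes.
#' @export
ddcp_fold_change <- function(treat_target, treat_ref, ctrl_target, ctrl_ref) {
  if (length(treat_target) != length(treat_ref) ||
      length(ctrl_target) != length(ctrl_ref)) {
    stopf("target and reference Cp vectors must be replicate-matched")
  }
  d_treat <- treat_target - treat_ref
  d_ctrl <- ctrl_target - ctrl_ref
  ddcp <- d_treat - mean(d_ctrl)
  fc <- 2^(-ddcp)
  p <- if (length(d_treat) >= 2L && length(d_ctrl) >= 2L &&
           (var(d_treat) > 1e-12 || var(d_ctrl) > 1e-12)) {
    t.test(d_treat, d_ctrl)$p.value
  } else {
    NA_real_
  }
  list(fold_change = mean(fc),
       sd = if (length(fc) >= 2L) sd(fc) else NA_real_,
       p_value = p,
       per_replicate = fc)
}

#' Construct a labeled expression matrix
#'
#' @param counts Genes x cells count matrix (base or [Matrix::Matrix]).
#' @param clusters Per-cell cluster labels (length `ncol(counts)`).
#' @return An object of class `labeled_matrix`: list with `counts`,
#'   `clusters` (factor) and `detected` (per-cell detected-gene counts).
#' @export
labeled_matrix <- function(counts, clusters) {
  if (length(clusters) != ncol(counts)) {
    stopf("one cluster label per cell is required")
  }
  if (is.null(rownames(counts)) && nrow(counts) > 0L) {
    rownames(counts) <- paste0("gene_", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts)) && ncol(counts) > 0L) {
    colnames(counts) <- paste0("cell_", seq_len(ncol(counts)))
  }
  structure(
    list(counts = counts, clusters = factor(clusters),
         detected = Matrix::colSums(counts > 0)),
    class = "labeled_matrix"
  )
}

#' @export
print.labeled_matrix <- function(x, ...) {
  cat("Labeled expression matrix:", nrow(x$counts), "genes x",
      ncol(x$counts), "cells,", nlevels(x$clusters), "clusters\n")
  invisible(x)
}

#' Filter cells by detected-gene count
#'
#' Removes cells detecting fewer than `min_genes_per_cell` genes, then drops
#' genes detected in zero remaining cells.
#'
#' @param mat A `labeled_matrix`.
#' @param min_genes_per_cell Detected-gene cutoff.
#' @return A filtered `labeled_matrix`.
#' @export
qc_filter <- function(mat, min_genes_per_cell = 1500L) {
  stopifnot(inherits(mat, "labeled_matrix"))
  keep_cells <- mat$detected >= min_genes_per_cell
  if (!any(keep_cells)) stopf("QC removed every cell")
  counts <- mat$counts[, keep_cells, drop = FALSE]
  keep_genes <- Matrix::rowSums(counts > 0) > 0
  labeled_matrix(counts[keep_genes, , drop = FALSE],
                 droplevels(mat$clusters[keep_cells]))
}

## Per-cell depth scaling to the median depth; log1p optionally on top.
normalize_expression <- function(mat, log1p = TRUE) {
  depth <- Matrix::colSums(mat$counts)
  depth[depth == 0] <- 1
  target <- median(depth)
  norm <- sweep(as.matrix(mat$counts), 2, depth / target, "/")
  if (log1p) log1p(norm) else norm
}

#' Cluster z-score localization of genes
#'
#' Per gene, cluster means of depth-normalized log1p expression are z-scored
#' across clusters (sample-SD convention); the gene-set score is the mean z
#' per cluster. Genes absent from the matrix are skipped with a warning.
#'
#' @param mat A `labeled_matrix` with >= 2 clusters.
#' @param gene_set Character vector of gene ids (default: all genes).
#' @return List with `z` (genes x clusters z-score matrix), `cluster_means`
#'   (raw cluster means) and `set_score` (mean z per cluster).
#' @export
zscore_localization <- function(mat, gene_set = NULL) {
  stopifnot(inherits(mat, "labeled_matrix"))
  if (nlevels(mat$clusters) < 2L) stopf("at least 2 clusters are required")
  if (is.null(gene_set)) gene_set <- rownames(mat$counts)
  missing <- setdiff(gene_set, rownames(mat$counts))
  if (length(missing)) {
    warnf("%d gene(s) absent from the matrix were skipped", length(missing))
    gene_set <- setdiff(gene_set, missing)
  }
  norm <- normalize_expression(mat, log1p = TRUE)[gene_set, , drop = FALSE]
  cl <- mat$clusters
  means <- vapply(levels(cl), function(k) {
    rowMeans(norm[, cl == k, drop = FALSE])
  }, numeric(length(gene_set)))
  if (length(gene_set) == 1L) means <- matrix(means, nrow = 1,
                                              dimnames = list(gene_set,
                                                              levels(cl)))
  mu <- rowMeans(means)
  s <- apply(means, 1, sd)  # sample SD across clusters
  z <- (means - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  list(z = z, cluster_means = means, set_score = colMeans(z))
}

#' Coefficient of variation per gene
#'
#' COV = sample SD / mean of depth-normalized (linear, not log) expression
#' across all retained cells; scale-invariant per gene. Genes with mean
#' below `min_mean` are excluded.
#'
#' @param mat A `labeled_matrix`.
#' @param min_mean Minimum normalized mean expression.
#' @return data.frame: `gene`, `mean`, `sd`, `cov`.
#' @export
cov_per_gene <- function(mat, min_mean = 0.01) {
  stopifnot(inherits(mat, "labeled_matrix"))
  if (!(min_mean > 0)) stopf("min_mean must be > 0")
  norm <- normalize_expression(mat, log1p = FALSE)
  mu <- rowMeans(norm)
  sdev <- apply(norm, 1, sd)
  keep <- mu >= min_mean
  data.frame(gene = rownames(norm)[keep], mean = mu[keep], sd = sdev[keep],
             cov = sdev[keep] / mu[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Contrast expression level and noise between gene groups
#'
#' Summarizes mean expression and mean COV per named gene group (e.g.
#' SE-associated targets / all SE / RE / no-enhancer) and runs pairwise
#' two-sided Mann-Whitney tests on both quantities with BH adjustment.
#' Empty groups are excluded with a warning.
#'
#' @param cov_table Output of [cov_per_gene()].
#' @param groups Named list of gene-id vectors.
#' @return List with `summary` (per-group n, mean expression, mean/median
#'   COV) and `tests` (pairwise comparisons; NULL with < 2 groups).
#' @export
robustness_contrast <- function(cov_table, groups) {
  sub <- lapply(groups, function(g) {
    cov_table[cov_table$gene %in% g, , drop = FALSE]
  })
  empty <- vapply(sub, nrow, integer(1)) == 0
  if (any(empty)) {
    warnf("empty group(s) excluded: %s",
          paste(names(sub)[empty], collapse = ", "))
    sub <- sub[!empty]
  }
  if (!length(sub)) stopf("no non-empty groups")
  summary_df <- do.call(rbind, lapply(names(sub), function(nm) {
    s <- sub[[nm]]
    data.frame(group = nm, n = nrow(s), mean_expression = mean(s$mean),
               mean_cov = mean(s$cov), median_cov = median(s$cov),
               stringsAsFactors = FALSE)
  }))
  tests <- NULL
  if (length(sub) >= 2L) {
    pairs <- utils::combn(names(sub), 2, simplify = FALSE)
    tests <- do.call(rbind, lapply(pairs, function(pr) {
      a <- sub[[pr[1]]]; b <- sub[[pr[2]]]
      p_cov <- suppressWarnings(wilcox.test(a$cov, b$cov)$p.value)
      p_expr <- suppressWarnings(wilcox.test(a$mean, b$mean)$p.value)
      data.frame(group_a = pr[1], group_b = pr[2],
                 p_cov = p_cov, p_expression = p_expr,
                 stringsAsFactors = FALSE)
    }))
    tests$padj_cov <- p.adjust(tests$p_cov, method = "BH")
    tests$padj_expression <- p.adjust(tests$p_expression, method = "BH")
  }
  list(summary = summary_df, tests = tests)
}

#' Link genes to SE vs RE loci
#'
#' A gene joins the SE set when any SE locus lies within `window` bp of its
#' gene body (edge-to-edge distance, 0 when overlapping), else the RE set by
#' the same rule, else the no-enhancer set. SE takes precedence over RE.
#'
#' @param ranking A labeled `enhancer_ranking` (see [find_cutoff()]).
#' @param genes Gene annotation data.frame.
#' @param window Linking distance in bp.
#' @return List of gene-id vectors: `se`, `re`, `none`.
#' @export
se_gene_linking <- function(ranking, genes, window = 20000L) {
  stopifnot(inherits(ranking, "enhancer_ranking"))
  if (all(is.na(ranking$label))) stopf("ranking must be labeled; run find_cutoff()")
  gr <- ranking_as_granges(ranking)
  ggr <- genes_as_granges(genes)
  near <- function(loci) {
    if (!length(loci)) return(logical(length(ggr)))
    hits <- GenomicRanges::findOverlaps(ggr, loci,
                                        maxgap = as.integer(window),
                                        ignore.strand = TRUE)
    q <- queryHits(hits)
    d <- GenomicRanges::distance(ggr[q], loci[subjectHits(hits)],
                                 ignore.strand = TRUE)
    out <- logical(length(ggr))
    out[unique(q[d <= window])] <- TRUE
    out
  }
  near_se <- near(gr[ranking$label == "SE"])
  near_re <- near(gr[ranking$label == "RE"])
  list(se = genes$gene_id[near_se],
       re = genes$gene_id[!near_se & near_re],
       none = genes$gene_id[!near_se & !near_re])
}

#' Read a MatrixMarket expression matrix with sidecars
#'
#' @param mtx_path MatrixMarket triplet file (genes x cells).
#' @param genes_path,cells_path One-id-per-line sidecar files.
#' @param clusters_path Two-column TSV (cell, cluster) with header.
#' @return A `labeled_matrix`.
#' @export
read_expression_mtx <- function(mtx_path, genes_path, cells_path,
                                clusters_path) {
  counts <- Matrix::readMM(mtx_path)
  rownames(counts) <- readLines(genes_path)
  colnames(counts) <- readLines(cells_path)
  cl <- read_tsv(clusters_path)
  labeled_matrix(counts, cl$cluster[match(colnames(counts), cl$cell)])
}

#' Write a labeled expression matrix as MatrixMarket plus sidecars
#' @param mat A `labeled_matrix`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return The directory, invisibly.
#' @export
write_expression_mtx <- function(mat, dir, prefix = "matrix") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(Matrix::Matrix(mat$counts, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, paste0(prefix, ".mtx")))
  writeLines(rownames(mat$counts), file.path(dir, paste0(prefix, "_genes.tsv")))
  writeLines(colnames(mat$counts), file.path(dir, paste0(prefix, "_cells.tsv")))
  write_tsv(data.frame(cell = colnames(mat$counts),
                       cluster = as.character(mat$clusters)),
            file.path(dir, paste0(prefix, "_clusters.tsv")))
  invisible(dir)
}

#' Reference cell-state table for the early gastrula
#'
#' The 13 defined cell states of the early gastrula embryo grouped by germ
#' layer: 5 ectodermal (inner neural plate, inner neural plate border, inner
#' non-neural ectoderm, outer neural ectoderm, outer non-neural ectoderm),
#' 4 mesodermal and 4 endodermal states. Used as the default cluster
#' vocabulary of the single-nucleus generator.
#'
#' @return data.frame with columns `cluster` and `germ_layer`.
#' @export
default_cell_states <- function() {
  data.frame(
    cluster = c("INP", "INPB", "INNE", "ONE", "ONNE",
                "dorsal_mesoderm", "ventral_mesoderm", "paraxial_mesoderm",
                "lateral_mesoderm",
                "anterior_endoderm", "posterior_endoderm", "deep_endoderm",
                "surface_endoderm"),
    germ_layer = c(rep("ectoderm", 5), rep("mesoderm", 4),
                   rep("endoderm", 4)),
    stringsAsFactors = FALSE
  )
}
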