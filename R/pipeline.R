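## Config-driven orchestration: synthetic study simulation, stage execution
## in dependency order, deterministic outputs, and a machine-readable report.

default_config <- function() {
  list(
    seed = 1L,
    out_dir = "crmscape_out",
    synthetic = list(
      n_chroms = 4L, chrom_len = 5e6, n_genes = 300L,
      class_counts = c("100" = 40L, "010" = 15L, "001" = 20L, "110" = 15L,
                       "101" = 10L, "011" = 25L, "111" = 35L),
      peak_width = 400L,
      stage_labels = c("stage8", "stage9", "stage10.5"),
      n_targets_A = 10L, n_targets_B = 15L, n_targets_joint = 5L,
      target_effect = 2, n_reps = 4L, dispersion = 0.001,
      base_meanlog = log(2000), base_sdlog = 0.5,
      n_re = 200L, n_se = 5L, se_span = 20000L, se_amp = 10, re_amp = 1,
      noise_sd = 0, n_cells = 800L, sc_depth = 2000
    ),
    params = list(
      min_bp = 1L, window = 20000L, fold = 2, padj = 0.05,
      stitch_gap = 12500L, tss_exclusion = 2500L, qc_min_genes = 50L,
      flank = 1000L, bin = 20L, class_window = 2000L
    )
  )
}

check_range <- function(errors, cfg, key, min = NULL, integer = FALSE) {
  val <- cfg[[key]]
  if (!is.numeric(val) || anyNA(val)) {
    c(errors, sprintf("params.%s: must be numeric", key))
  } else if (!is.null(min) && any(val < min)) {
    c(errors, sprintf("params.%s: must be >= %s (got %s)", key, min,
                      paste(val, collapse = ",")))
  } else if (integer && any(val != trunc(val))) {
    c(errors, sprintf("params.%s: must be an integer", key))
  } else {
    errors
  }
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML (or JSON) configuration, fills defaults, rejects unknown
#' keys and reports every violation at once rather than stopping at the
#' first.
#'
#' @param path_or_list Config file path, or an already-parsed list.
#' @return List with `config` (normalized, `NULL` when invalid) and
#'   `errors` (character vector of key-path-qualified messages).
#' @export
validate_config <- function(path_or_list) {
  cfg <- if (is.character(path_or_list)) {
    parsed <- yaml::read_yaml(path_or_list)
    if (is.null(parsed)) list() else parsed
  } else if (is.null(path_or_list)) {
    list()
  } else {
    path_or_list
  }
  def <- default_config()
  errors <- character(0)
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown)) {
    errors <- c(errors, sprintf("unknown top-level key: %s", unknown))
  }
  for (section in c("synthetic", "params")) {
    bad <- setdiff(names(cfg[[section]]), names(def[[section]]))
    if (length(bad)) {
      errors <- c(errors, sprintf("unknown key: %s.%s", section, bad))
    }
  }
  merged <- def
  for (k in intersect(names(cfg), names(def))) {
    if (is.list(def[[k]])) {
      for (k2 in intersect(names(cfg[[k]]), names(def[[k]]))) {
        merged[[k]][[k2]] <- cfg[[k]][[k2]]
      }
    } else {
      merged[[k]] <- cfg[[k]]
    }
  }
  if (!"synthetic" %in% names(cfg)) {
    errors <- c(errors,
                "synthetic: a synthetic-generation block is required")
  }
  p <- merged$params
  errors <- check_range(errors, p, "min_bp", min = 1, integer = TRUE)
  errors <- check_range(errors, p, "window", min = 0, integer = TRUE)
  errors <- check_range(errors, p, "fold", min = 1)
  errors <- check_range(errors, p, "padj", min = 0)
  if (is.numeric(p$padj) && !anyNA(p$padj) && any(p$padj > 1)) {
    errors <- c(errors, "params.padj: must be <= 1")
  }
  errors <- check_range(errors, p, "stitch_gap", min = 0, integer = TRUE)
  errors <- check_range(errors, p, "tss_exclusion", min = 0, integer = TRUE)
  errors <- check_range(errors, p, "qc_min_genes", min = 0, integer = TRUE)
  errors <- check_range(errors, p, "flank", min = 1, integer = TRUE)
  errors <- check_range(errors, p, "bin", min = 1, integer = TRUE)
  if (is.numeric(p$flank) && is.numeric(p$bin) && !anyNA(c(p$flank, p$bin)) &&
      p$bin >= 1 && p$flank %% p$bin != 0) {
    errors <- c(errors, "params.flank: must be divisible by params.bin")
  }
  if (!is_count(merged$seed, min = 0)) {
    errors <- c(errors, "seed: must be a nonnegative integer")
  }
  cc <- merged$synthetic$class_counts
  if (!is.null(names(cc)) && !setequal(names(cc), PATTERNS3)) {
    errors <- c(errors,
                "synthetic.class_counts: names must be the 7 stage patterns")
  }
  list(config = if (length(errors)) NULL else merged, errors = errors)
}

#' Simulate a complete synthetic study with planted ground truth
#'
#' Fans one seed out to every generator and wires their outputs together:
#' genes, stage-resolved TF peaks with planted temporal classes, factor and
#' coactivator peak sets tied to planted direct-target genes, an enhancer
#' landscape with planted super-enhancers anchored near genes (whose
#' neighbours become the planted robust gene set), morphant count tables,
#' a clustered single-nucleus matrix, and motif-planted summit windows.
#'
#' @param seed Integer seed.
#' @param synthetic The `synthetic` block of a validated config.
#' @param params The `params` block of a validated config.
#' @return List of all inputs plus a `truth` record.
#' @export
simulate_study <- function(seed, synthetic = default_config()$synthetic,
                           params = default_config()$params) {
  sy <- synthetic
  genome <- gen_genome_and_genes(seed, n_chroms = sy$n_chroms,
                                 chrom_len = sy$chrom_len,
                                 n_genes = sy$n_genes)
  genes <- genome$genes
  cc <- sy$class_counts
  if (is.null(names(cc))) names(cc) <- PATTERNS3
  cc_int <- setNames(as.integer(unlist(cc[PATTERNS3])), PATTERNS3)
  stage <- gen_stage_peaks(seed, cc_int, peak_width = sy$peak_width,
                           stage_labels = sy$stage_labels,
                           chrom_sizes = genome$chrom_sizes)
  ## planted direct targets: deterministic pick of the first genes, split
  ## activated/repressed 70/30 within each attribution
  n_t <- sy$n_targets_A + sy$n_targets_B + sy$n_targets_joint
  if (n_t > nrow(genes)) stopf("more targets than genes")
  tgt_genes <- genes$gene_id[seq_len(n_t)]
  fac <- c(rep("A", sy$n_targets_A), rep("B", sy$n_targets_B),
           rep("both", sy$n_targets_joint))
  dir_split <- function(n) c(rep("activated", ceiling(0.7 * n)),
                             rep("repressed", n - ceiling(0.7 * n)))
  targets <- data.frame(
    gene_id = tgt_genes, factor = fac,
    direction = c(dir_split(sy$n_targets_A), dir_split(sy$n_targets_B),
                  dir_split(sy$n_targets_joint)),
    effect = sy$target_effect, stringsAsFactors = FALSE
  )
  fpeaks <- gen_factor_peaks(seed, genes, targets, genome$chrom_sizes)
  ## enhancer landscape with planted SEs on a separated grid; the last n_se
  ## genes are then relocated just downstream of the SE loci so the planted
  ## robust gene set is SE-associated by construction
  n_se <- sy$n_se
  enh <- gen_signal_with_ses(seed, genome$chrom_sizes, n_re = sy$n_re,
                             n_se = n_se, se_span = sy$se_span,
                             se_amp = sy$se_amp, re_amp = sy$re_amp,
                             noise_sd = sy$noise_sd)
  se_genes <- if (n_se > 0) utils::tail(genes$gene_id, n_se) else character(0)
  if (n_se > 0) {
    gi <- match(se_genes, genes$gene_id)
    new_start <- as.integer(enh$truth$se_loci$end + 2000L)
    genes$chrom[gi] <- enh$truth$se_loci$chrom
    genes$start[gi] <- new_start
    genes$end[gi] <- new_start + 3999L
    genes$strand[gi] <- "+"
    genes$tss[gi] <- new_start
  }
  counts <- gen_morphant_counts(seed, genes, targets, n_reps = sy$n_reps,
                                dispersion = sy$dispersion,
                                base_meanlog = sy$base_meanlog,
                                base_sdlog = sy$base_sdlog)
  sc <- gen_sc_matrix(seed, genes, robust_genes = se_genes,
                      n_cells = sy$n_cells, depth = sy$sc_depth)
  ## motif windows over the latest stage's peaks, planting a Fox-like site
  ## in every peak and a Sox-like site in a deterministic half
  st3 <- stage$stages[[3]]
  fox <- "TGTTTGTTT"
  sox <- "AACAATGG"
  nm <- mcols(st3)$name
  plant <- rbind(
    if (length(st3)) data.frame(peak = nm, consensus = fox, offset = 0L,
                                strand = "+"),
    if (length(st3) >= 2) data.frame(
      peak = nm[seq_len(floor(length(st3) / 2))],
      consensus = sox, offset = 120L, strand = "-"
    )
  )
  seqs <- gen_window_sequences(seed, st3, flank = params$flank, plant = plant)
  list(
    genes = genes, chrom_sizes = genome$chrom_sizes,
    stage_peaks = stage$stages,
    factor_peaks = fpeaks[c("tfA", "tfB", "coact")],
    enhancer_peaks = enh$peaks, signal = enh$track,
    counts = counts, sc = sc$mat,
    motif_windows = seqs,
    motif_pwms = list(fox = pwm_from_consensus("fox", fox),
                      sox = pwm_from_consensus("sox", sox)),
    truth = list(
      stage_classes = stage$truth,
      targets = targets,
      factor_regions = fpeaks$truth,
      se_loci = enh$truth$se_loci, re_loci = enh$truth$re_loci,
      robust_genes = se_genes,
      sc = sc$truth,
      seed = seed, synthetic = sy
    )
  )
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full pipeline on a synthetic study
#'
#' Executes the stages in dependency order - interval generation, temporal
#' classification, co-occupancy, super-enhancer calling, direct-target
#' calling, motif histograms, single-nucleus statistics - writing stage
#' outputs (BED/TSV/bedGraph/MTX), a JSON report with recomputed
#' cross-stage consistency counts, and an md5 MANIFEST. Reruns with the
#' same config are byte-identical.
#'
#' @param config A config list (validated with [validate_config()]) or a
#'   config file path.
#' @return The report, invisibly; outputs under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  v <- validate_config(config)
  if (length(v$errors)) {
    stopf("invalid config:\n%s", paste("-", v$errors, collapse = "\n"))
  }
  cfg <- v$config
  p <- cfg$params
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  report <- list(parameters = p, seed = cfg$seed, stages = list())
  t_all <- proc.time()[["elapsed"]]

  sim <- simulate_study(cfg$seed, cfg$synthetic, p)
  write_gff3(sim$genes, file.path(out, "genes.gff3"))
  for (nm in names(sim$stage_peaks)) {
    write_bed(sim$stage_peaks[[nm]], file.path(out, paste0("peaks_", nm,
                                                           ".bed")))
  }
  write_bedgraph(sim$signal, file.path(out, "h3k27ac.bedGraph"))
  report$stages$simulate <- list(
    n_genes = nrow(sim$genes),
    n_stage_peaks = as.list(setNames(lengths(sim$stage_peaks),
                                     names(sim$stage_peaks)))
  )

  ## temporal classification
  cls <- temporal_classify(sim$stage_peaks[[1]], sim$stage_peaks[[2]],
                           sim$stage_peaks[[3]], min_bp = p$min_bp)
  loci_out <- cls$loci
  mcols(loci_out)$name <- paste0("class_", mcols(loci_out)$class)
  write_bed(loci_out, file.path(out, "temporal_classes.bed"))
  write_tsv(data.frame(class = names(class_counts(cls)),
                       n_loci = as.integer(class_counts(cls))),
            file.path(out, "temporal_class_counts.tsv"))
  report$stages$classify <- list(
    n_loci = length(cls$loci),
    class_counts = as.list(class_counts(cls)),
    partition_ok = all(
      vapply(1:3, function(i) {
        sum(mcols(cls$loci)[[paste0("n_stage", i)]]) ==
          length(sim$stage_peaks[[i]])
      }, logical(1))
    )
  )

  ## co-occupancy / FSE
  co <- co_occupancy(sim$factor_peaks$tfA, sim$factor_peaks$tfB,
                     sim$factor_peaks$coact, min_bp = p$min_bp)
  fse <- co[mcols(co)$fse]
  mcols(fse)$name <- paste0("FSE_", seq_len(length(fse)))
  write_bed(fse, file.path(out, "fse_regions.bed"))
  report$stages$co_occupancy <- list(
    n_regions = length(co), n_fse = length(fse),
    n_cobound_AB = sum(mcols(co)$has_A & mcols(co)$has_B)
  )

  ## super-enhancers
  loci <- stitch(sim$enhancer_peaks, stitch_gap = p$stitch_gap)
  ranking <- find_cutoff(rank_loci(loci, sim$signal))
  write_tsv(as.data.frame(ranking), file.path(out, "enhancer_ranking.tsv"))
  write_bed(ranking_as_granges(ranking), file.path(out, "enhancers.bed"))
  n_se_called <- sum(ranking$label == "SE")
  report$stages$super_enhancers <- list(
    n_stitched = nrow(ranking), n_se = n_se_called,
    n_re = sum(ranking$label == "RE"),
    se_plus_re_equals_total = n_se_called +
      sum(ranking$label == "RE") == nrow(ranking)
  )

  ## direct targets
  deA <- simple_de(sim$counts$morphant_A, sim$counts$wt)
  deB <- simple_de(sim$counts$morphant_B, sim$counts$wt)
  write_tsv(deA, file.path(out, "de_morphant_A.tsv"))
  write_tsv(deB, file.path(out, "de_morphant_B.tsv"))
  asA <- assign_peaks_to_genes(sim$factor_peaks$tfA, sim$genes,
                               window = p$window)
  asB <- assign_peaks_to_genes(sim$factor_peaks$tfB, sim$genes,
                               window = p$window)
  tc <- call_direct_targets(deA, deB, asA, asB, fold = p$fold,
                            padj_max = p$padj)
  write_tsv(tc$calls, file.path(out, "direct_targets.tsv"))
  report$stages$targets <- list(
    n_targets = nrow(tc$calls),
    counts = as.list(setNames(as.integer(rowSums(tc$counts)),
                              rownames(tc$counts)))
  )

  ## motif histograms over the latest-stage peaks
  st3 <- sim$stage_peaks[[3]]
  hist <- summit_histogram(st3, sim$motif_windows, sim$motif_pwms,
                           flank = p$flank, bin = p$bin)
  write_tsv(data.frame(bin_start = head(hist$breaks, -1),
                       as.data.frame(hist$counts)),
            file.path(out, "motif_histogram.tsv"))
  combo <- combinatorial_content(st3, sim$motif_windows,
                                 sim$motif_pwms[[1]], sim$motif_pwms[[2]],
                                 flank = p$flank)
  write_tsv(data.frame(category = names(combo), proportion = as.numeric(combo)),
            file.path(out, "motif_content.tsv"))
  report$stages$motifs <- list(n_hits = as.list(hist$n_hits),
                               content = as.list(combo))

  ## single-nucleus statistics
  mat <- qc_filter(sim$sc, min_genes_per_cell = p$qc_min_genes)
  write_expression_mtx(mat, out, prefix = "sc_counts")
  cov_tab <- cov_per_gene(mat)
  write_tsv(cov_tab, file.path(out, "cov_per_gene.tsv"))
  linking <- se_gene_linking(ranking, sim$genes, window = p$window)
  rc <- robustness_contrast(cov_tab,
                            list(se = linking$se, re = linking$re,
                                 none = linking$none))
  write_tsv(rc$summary, file.path(out, "robustness_summary.tsv"))
  zl <- zscore_localization(mat, sim$truth$robust_genes)
  write_tsv(data.frame(cluster = names(zl$set_score),
                       mean_z = as.numeric(zl$set_score)),
            file.path(out, "se_gene_zscores.tsv"))
  report$stages$expression <- list(
    n_cells_pass_qc = ncol(mat$counts),
    n_genes_cov = nrow(cov_tab),
    n_se_genes = length(linking$se), n_re_genes = length(linking$re)
  )

  report$wall_time_s <- round(proc.time()[["elapsed"]] - t_all, 3)
  report$versions <- list(crmscape = as.character(utils::packageVersion("crmscape")),
                          R = paste(R.version$major, R.version$minor,
                                    sep = "."))
  write_json_report(report, file.path(out, "report.json"))
  ## MANIFEST over data outputs (the report carries timing, so it is listed
  ## but not checksummed)
  files <- sort(setdiff(list.files(out, recursive = TRUE), "MANIFEST"))
  sums <- vapply(files, function(f) {
    if (f == "report.json") "-" else unname(tools::md5sum(file.path(out, f)))
  }, character(1))
  writeLines(paste(sums, files, sep = "  "), file.path(out, "MANIFEST"))
  invisible(report)
}
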