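## PWM scanning around peak summits: positional occurrence histograms and
## combinatorial motif-content proportions.

DNA_BASES <- c("A", "C", "G", "T")

#' Build a PWM from per-position base probabilities
#'
#' @param name Motif name.
#' @param mat 4 x width matrix of probabilities, rows A, C, G, T; each
#'   column must sum to 1 (tolerance 1e-9).
#' @param background Background base frequencies (default uniform).
#' @param threshold Log2-odds hit threshold; default 80% of the motif's
#'   maximal achievable score.
#' @return An object of class `pwm` with the log2-odds `score_matrix`.
#' @export
pwm <- function(name, mat, background = rep(0.25, 4), threshold = NULL) {
  stopifnot(is.matrix(mat), nrow(mat) == 4L)
  if (any(abs(colSums(mat) - 1) > 1e-9)) {
    stopf("PWM columns must sum to 1")
  }
  rownames(mat) <- DNA_BASES
  background <- background / sum(background)
  score_matrix <- log2(mat / background)
  max_score <- sum(apply(score_matrix, 2, max))
  if (is.null(threshold)) threshold <- 0.8 * max_score
  if (!is.finite(threshold)) stopf("threshold must be finite")
  structure(list(name = name, prob = mat, background = background,
                 score_matrix = score_matrix, max_score = max_score,
                 threshold = threshold),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$name, "- width", ncol(x$prob), "- threshold",
      signif(x$threshold, 4), "of max", signif(x$max_score, 4), "\n")
  invisible(x)
}

#' Build a PWM from a consensus string
#'
#' Each consensus base receives probability `1 - 3 * mismatch`; the other
#' three bases `mismatch` each. Convenient for synthetic fixtures.
#'
#' @param name Motif name.
#' @param consensus DNA string over A/C/G/T.
#' @param mismatch Per-base mismatch probability.
#' @param ... Passed to [pwm()].
#' @return A `pwm`.
#' @export
pwm_from_consensus <- function(name, consensus, mismatch = 0.01, ...) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  if (!all(bases %in% DNA_BASES)) stopf("consensus must be over A/C/G/T")
  mat <- matrix(mismatch, nrow = 4, ncol = length(bases),
                dimnames = list(DNA_BASES, NULL))
  for (j in seq_along(bases)) mat[bases[j], j] <- 1 - 3 * mismatch
  pwm(name, mat, ...)
}

#' Read PWMs from a JASPAR-style plain-text file
#'
#' Expects records of a `>name` header followed by four lines
#' `A [ counts... ]` (or bare numbers) in A, C, G, T order; counts are
#' column-normalized to probabilities with a small pseudocount.
#'
#' @param path File path.
#' @param pseudocount Added to every count before normalization.
#' @param ... Passed to [pwm()].
#' @return Named list of `pwm` objects.
#' @export
read_jaspar <- function(path, pseudocount = 0.5, ...) {
  lines <- readLines(path)
  starts <- grep("^>", lines)
  if (!length(starts)) stopf("no JASPAR records in %s", path)
  out <- list()
  for (s in starts) {
    name <- sub("^>\\s*", "", lines[s])
    name <- strsplit(name, "\\s+")[[1]][1]
    rows <- lapply(lines[s + 1:4], function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("[][]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    mat <- do.call(rbind, rows) + pseudocount
    mat <- sweep(mat, 2, colSums(mat), "/")
    out[[name]] <- pwm(name, mat, ...)
  }
  out
}

seq_to_index <- function(s) {
  v <- match(strsplit(toupper(s), "")[[1]], DNA_BASES)  # N and others -> NA
  v
}

revcomp <- function(s) {
  chartr("ACGTacgtN", "TGCAtgcaN", paste(rev(strsplit(s, "")[[1]]),
                                         collapse = ""))
}

scan_one_strand <- function(idx, sm) {
  w <- ncol(sm)
  L <- length(idx)
  if (L < w) return(numeric(0))
  n_off <- L - w + 1L
  scores <- numeric(n_off)
  for (j in seq_len(w)) {
    b <- idx[j:(j + n_off - 1L)]
    col <- sm[, j]
    sc <- col[b]
    sc[is.na(b)] <- -Inf  # N never matches
    scores <- scores + sc
  }
  scores
}

#' Scan a sequence with a PWM on both strands
#'
#' Positions scoring at least the PWM's log2-odds threshold are hits.
#' Offsets are 0-based from the sequence start and always refer to the
#' plus-strand coordinates of the matched window; `N` bases score `-Inf`.
#'
#' @param seq DNA string over A/C/G/T/N (character scalar or
#'   [Biostrings::DNAString]).
#' @param p A `pwm`.
#' @return data.frame: `offset`, `strand`, `score`; empty when the sequence
#'   is shorter than the motif or nothing passes the threshold.
#' @export
scan_pwm <- function(seq, p) {
  stopifnot(inherits(p, "pwm"))
  seq <- as.character(seq)
  sm <- p$score_matrix
  w <- ncol(sm)
  empty <- data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0))
  if (nchar(seq) < w) return(empty)
  fwd <- scan_one_strand(seq_to_index(seq), sm)
  rev_scores <- scan_one_strand(seq_to_index(revcomp(seq)), sm)
  L <- nchar(seq)
  hits_f <- which(fwd >= p$threshold)
  hits_r <- which(rev_scores >= p$threshold)
  out <- rbind(
    data.frame(offset = hits_f - 1L, strand = rep("+", length(hits_f)),
               score = fwd[hits_f]),
    data.frame(offset = L - w - (hits_r - 1L), strand = rep("-", length(hits_r)),
               score = rev_scores[hits_r])
  )
  out[order(out$offset, out$strand), , drop = FALSE]
}

## Extract per-peak summit windows [summit - flank, summit + flank) from
## chromosome sequences, or accept precomputed per-peak windows (one
## sequence of width 2 * flank per peak, e.g. from gen_window_sequences()).
peak_windows <- function(peaks, genome_seqs, flank) {
  n <- length(peaks)
  win_width <- 2L * flank
  seq_chr <- as.character(genome_seqs)
  if (length(seq_chr) == n && all(nchar(seq_chr) == win_width)) {
    return(seq_chr)
  }
  if (!is.null(names(genome_seqs)) &&
      all(as.character(seqnames(peaks)) %in% names(genome_seqs))) {
    anchors <- anchor_positions(peaks)
    no_summit <- is.na(mcols(peaks)$summit)
    if (!is.null(mcols(peaks)$summit) && any(no_summit)) {
      message(sum(no_summit), " peak(s) without summit: midpoint used")
    }
    vapply(seq_len(n), function(i) {
      chrom_seq <- as.character(genome_seqs[[as.character(seqnames(peaks))[i]]])
      s <- anchors[i] - flank
      e <- anchors[i] + flank - 1L
      left_pad <- max(0L, 1L - s)
      s <- max(1L, s)
      e <- min(nchar(chrom_seq), e)
      paste0(strrep("N", left_pad), substr(chrom_seq, s, e))
    }, character(1))
  } else {
    stopf("genome_seqs must be named by chromosome and cover all peaks")
  }
}

#' Positional motif histogram around peak summits
#'
#' Scans the `[summit - flank, summit + flank)` window of each peak with
#' each PWM and bins hit midpoints by their offset from the summit
#' (`2 * flank / bin` bins; 100 at the defaults). Peaks without a summit
#' use their midpoint (with a message).
#'
#' @param peaks Peak `GRanges`.
#' @param genome_seqs Named chromosome sequences ([Biostrings::DNAStringSet]
#'   or named character vector) covering the peaks' chromosomes.
#' @param pwms Named list of `pwm` objects (a single `pwm` is accepted).
#' @param flank Half-window in bp; must be divisible by `bin`.
#' @param bin Bin width in bp.
#' @return An object of class `motif_histogram`: list with `breaks` (bin
#'   edges, summit-relative), `counts` (bins x motifs), `presence`
#'   (peaks x motifs logical) and `n_hits` per motif.
#' @export
summit_histogram <- function(peaks, genome_seqs, pwms, flank = 1000L,
                             bin = 20L) {
  if (flank %% bin != 0) stopf("flank must be divisible by bin")
  if (inherits(pwms, "pwm")) pwms <- setNames(list(pwms), pwms$name)
  n_bins <- as.integer(2 * flank / bin)
  breaks <- seq(-flank, flank, by = bin)
  wins <- peak_windows(peaks, genome_seqs, flank)
  counts <- matrix(0L, nrow = n_bins, ncol = length(pwms),
                   dimnames = list(NULL, names(pwms)))
  presence <- matrix(FALSE, nrow = length(peaks), ncol = length(pwms),
                     dimnames = list(NULL, names(pwms)))
  for (m in seq_along(pwms)) {
    w <- ncol(pwms[[m]]$prob)
    for (i in seq_along(wins)) {
      hits <- scan_pwm(wins[i], pwms[[m]])
      if (!nrow(hits)) next
      presence[i, m] <- TRUE
      ## midpoint offset from summit: window starts at summit - flank
      mid <- hits$offset + w / 2 - flank
      b <- pmin(pmax(floor((mid + flank) / bin) + 1L, 1L), n_bins)
      tb <- table(b)
      counts[as.integer(names(tb)), m] <- counts[as.integer(names(tb)), m] +
        as.integer(tb)
    }
  }
  structure(list(breaks = breaks, counts = counts, presence = presence,
                 n_hits = colSums(counts), flank = flank, bin = bin),
            class = "motif_histogram")
}

#' @export
print.motif_histogram <- function(x, ...) {
  cat("Motif histogram:", nrow(x$counts), "bins of", x$bin, "bp;",
      "hits:", paste(names(x$n_hits), x$n_hits, collapse = ", "), "\n")
  invisible(x)
}

#' Combinatorial motif content of peaks
#'
#' Per-peak presence of two motifs within `flank` bp of the summit, reported
#' as four disjoint proportions summing to 1.
#'
#' @param peaks Peak `GRanges`.
#' @param genome_seqs Named chromosome sequences.
#' @param pwmA,pwmB Two `pwm` objects.
#' @param flank Half-window in bp.
#' @return Named numeric vector: `both`, `A_only`, `B_only`, `neither`.
#' @export
combinatorial_content <- function(peaks, genome_seqs, pwmA, pwmB,
                                  flank = 1000L) {
  h <- summit_histogram(peaks, genome_seqs,
                        setNames(list(pwmA, pwmB), c("A", "B")),
                        flank = flank, bin = flank)
  a <- h$presence[, "A"]; b <- h$presence[, "B"]
  n <- length(peaks)
  if (n == 0L) return(c(both = NaN, A_only = NaN, B_only = NaN,
                        neither = NaN))
  c(both = sum(a & b) / n, A_only = sum(a & !b) / n,
    B_only = sum(!a & b) / n, neither = sum(!a & !b) / n)
}

#' Read sequences from FASTA
#' @param path FASTA file path.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)
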