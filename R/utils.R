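## Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so
#' generators are pure functions of their seed and never perturb user code.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## One global seed fans out to per-generator child seeds by fixed offsets,
## kept inside 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% (.Machine$integer.max - 1L)) + 1L
}

SEED_OFFSETS <- c(
  genome   = 11L,
  peaks    = 23L,
  cooccup  = 31L,
  signal   = 37L,
  counts   = 41L,
  sc       = 53L,
  seqs     = 61L
)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= min && x == trunc(x)
}

#' Write a data frame as TSV with deterministic formatting
#' @param df A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @keywords internal
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

## Union-find over 1..n used for single-linkage clustering of overlapping
## peaks; path-halving keeps it near-linear at our scales.
union_find_components <- function(n, edges_from, edges_to) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(edges_from)) {
    ra <- find(edges_from[k])
    rb <- find(edges_to[k])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
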