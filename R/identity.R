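# Pairwise whole-genome nucleotide percent identity.
#
# Identity convention (documented; the denominator matters): identical
# columns / alignment columns after stripping terminal-gap columns; internal
# gap columns count as mismatches. Scoring: match +1, mismatch -1, gap open
# -5, gap extend -1 (a gap of length k costs 5 + k).

NT_SCORE <- list(match = 1, mismatch = -1, gap_open = 5, gap_extend = 1)

# Full affine-gap global alignment of two DNA strings -> (matches, cols).
dp_counts <- function(a, b, trim_terminal = TRUE) {
  v <- .nw_counts(a, b, match = NT_SCORE$match, mismatch = NT_SCORE$mismatch,
                  gap_open = NT_SCORE$gap_open,
                  gap_extend = NT_SCORE$gap_extend,
                  trim_terminal = trim_terminal)
  c(matches = v[["matches"]], cols = v[["cols"]])
}

#' Global nucleotide percent identity of two sequences
#'
#' For sequences up to `max_dp` bases an affine-gap global alignment is
#' computed directly. Longer pairs are handled by exact k-mer anchor
#' chaining: maximal runs of shared unique k-mers are chained collinearly,
#' inter-anchor blocks are aligned by dynamic programming (very long
#' low-similarity blocks are length-weighted from proportionally sampled
#' sub-blocks), and identity is pooled over all columns.
#'
#' @param seq_a,seq_b DNA strings (non-empty).
#' @param method `"auto"` (DP when both sequences fit `max_dp`), `"dp"`, or
#'   `"anchored"`.
#' @param max_dp size limit for the direct dynamic-programming route.
#' @return percent identity in `[0, 100]`.
#' @export
global_identity <- function(seq_a, seq_b, method = c("auto", "dp", "anchored"),
                            max_dp = 10000L) {
  method <- match.arg(method)
  if (!nzchar(seq_a) || !nzchar(seq_b)) abort("sequences must be non-empty.")
  use_dp <- switch(method,
                   dp = TRUE,
                   anchored = FALSE,
                   auto = max(nchar(seq_a), nchar(seq_b)) <= max_dp)
  cnt <- if (use_dp) dp_counts(seq_a, seq_b) else anchored_counts(seq_a, seq_b)
  if (cnt[["cols"]] == 0) return(0)
  unname(100 * cnt[["matches"]] / cnt[["cols"]])
}

# ---- anchor chaining ---------------------------------------------------

# Maximal collinear runs of k-mers occurring exactly once in each sequence.
anchor_segments <- function(a, b, k) {
  ka <- seq_kmers(a, k); kb <- seq_kmers(b, k)
  ua <- !(duplicated(ka) | duplicated(ka, fromLast = TRUE)) & !str_detect(ka, "N")
  ub <- !(duplicated(kb) | duplicated(kb, fromLast = TRUE)) & !str_detect(kb, "N")
  common <- intersect(ka[ua], kb[ub])
  if (!length(common)) return(NULL)
  ia <- match(common, ka); ja <- match(common, kb)
  o <- order(ia); ia <- ia[o]; ja <- ja[o]
  new_run <- c(TRUE, !(diff(ia) == 1L & diff(ja) == 1L))
  run <- cumsum(new_run)
  segs <- tibble(a_start = tapply(ia, run, min)[unique(run)],
                 b_start = tapply(ja, run, min)[unique(run)],
                 len = tapply(ia, run, length)[unique(run)] + k - 1L)
  segs$a_end <- segs$a_start + segs$len - 1L
  segs$b_end <- segs$b_start + segs$len - 1L
  segs
}

# Highest-coverage strictly collinear chain of anchor segments (weighted LIS).
chain_segments <- function(segs, max_segs = 1000L) {
  segs <- segs[order(-segs$len), ]
  segs <- head(segs, max_segs)
  segs <- segs[order(segs$a_start, segs$b_start), ]
  m <- nrow(segs)
  best <- numeric(m); prev <- integer(m)
  for (i in seq_len(m)) {
    compat <- segs$a_end < segs$a_start[i] & segs$b_end < segs$b_start[i] &
      seq_len(m) < i
    w <- if (any(compat)) which.max(ifelse(compat, best, -Inf)) else 0L
    base <- if (w > 0L && compat[w]) best[w] else 0
    best[i] <- base + segs$len[i]
    prev[i] <- if (w > 0L && compat[w]) w else 0L
  }
  path <- integer(0); i <- which.max(best)
  while (i > 0L) { path <- c(i, path); i <- prev[i] }
  segs[path, ]
}

# (matches, cols) for an inter-anchor block, chunking/sampling huge blocks.
# Blocks above `sample_above` are length-weighted estimates from evenly
# spaced sub-blocks (documented approximation; such blocks arise only
# between genomes with no usable anchors, i.e. with little or no homology).
block_counts <- function(a, b, block_max = 3000L, chunk = 1000L,
                         sample_above = 6000L, max_chunks = 3L) {
  la <- nchar(a); lb <- nchar(b)
  if (la == 0L && lb == 0L) return(c(matches = 0, cols = 0))
  if (la == 0L || lb == 0L) return(c(matches = 0, cols = max(la, lb)))
  if (max(la, lb) <= block_max) return(dp_counts(a, b, trim_terminal = FALSE))
  n_chunks <- ceiling(max(la, lb) / chunk)
  ba <- round(seq(0L, la, length.out = n_chunks + 1L))
  bb <- round(seq(0L, lb, length.out = n_chunks + 1L))
  take <- if (max(la, lb) > sample_above && n_chunks > max_chunks) {
    unique(round(seq(1L, n_chunks, length.out = max_chunks)))
  } else {
    seq_len(n_chunks)
  }
  tot <- c(matches = 0, cols = 0)
  for (ci in take) {
    sub_a <- substring(a, ba[ci] + 1L, ba[ci + 1L])
    sub_b <- substring(b, bb[ci] + 1L, bb[ci + 1L])
    tot <- tot + block_counts(sub_a, sub_b, block_max = max(block_max, chunk),
                              chunk = chunk)
  }
  tot * (n_chunks / length(take))
}

anchored_counts <- function(a, b) {
  segs <- NULL
  for (k in c(16L, 11L)) {
    segs <- anchor_segments(a, b, k)
    if (!is.null(segs) && nrow(segs) > 0L) break
  }
  if (is.null(segs) || nrow(segs) == 0L) {
    return(block_counts(a, b))
  }
  chain <- chain_segments(segs)
  # spurious chains of isolated random k-mer hits scatter across all
  # diagonals; keep the chain only if it is diagonal-coherent and covers a
  # non-trivial fraction of the shorter sequence, else fall back to the
  # chunked estimate
  diag <- chain$a_start - chain$b_start
  med <- stats::median(rep(diag, chain$len))
  keep <- abs(diag - med) <= 0.1 * min(nchar(a), nchar(b)) + 100
  chain <- chain[keep, , drop = FALSE]
  if (nrow(chain) == 0L ||
      sum(chain$len) < max(200, 0.02 * min(nchar(a), nchar(b)))) {
    return(block_counts(a, b))
  }
  tot <- c(matches = sum(chain$len), cols = sum(chain$len))
  # inter-anchor blocks
  for (i in seq_len(nrow(chain) - 1L)) {
    sub_a <- substring(a, chain$a_end[i] + 1L, chain$a_start[i + 1L] - 1L)
    sub_b <- substring(b, chain$b_end[i] + 1L, chain$b_start[i + 1L] - 1L)
    tot <- tot + block_counts(sub_a, sub_b)
  }
  # flanks: aligned only when both sequences have residual sequence there;
  # a one-sided flank is a terminal gap and is stripped by convention.
  lead_a <- substring(a, 1L, chain$a_start[1L] - 1L)
  lead_b <- substring(b, 1L, chain$b_start[1L] - 1L)
  if (nzchar(lead_a) && nzchar(lead_b)) tot <- tot + block_counts(lead_a, lead_b)
  tail_a <- substring(a, chain$a_end[nrow(chain)] + 1L, nchar(a))
  tail_b <- substring(b, chain$b_end[nrow(chain)] + 1L, nchar(b))
  if (nzchar(tail_a) && nzchar(tail_b)) tot <- tot + block_counts(tail_a, tail_b)
  tot
}

#' Pairwise identity matrix for a genome collection
#'
#' @param genomes genome tibble (>= 2 rows).
#' @param ... passed to [global_identity()].
#' @return an `identity_matrix`: symmetric numeric matrix (percent) with
#'   genome ids as dimnames and 100 on the diagonal.
#' @export
identity_matrix <- function(genomes, ...) {
  n <- nrow(genomes)
  if (n < 2L) abort("need at least 2 genomes.")
  ids <- genomes$genome_id
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      v <- global_identity(genomes$sequence[i], genomes$sequence[j], ...)
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  structure(m, class = c("identity_matrix", "matrix"))
}

#' @export
tidy.identity_matrix <- function(x, ...) {
  ids <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble(genome_a = ids[idx[, 1]], genome_b = ids[idx[, 2]],
         identity_pct = x[idx])
}

#' Write an identity matrix as TSV (1 decimal place)
#'
#' Writing, re-reading and re-writing the file reproduces it byte for byte.
#'
#' @param m `identity_matrix`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_identity_tsv <- function(m, path) {
  df <- as_tibble(round(unclass(m), 1), rownames = "genome_id")
  write_tsv_with_header(df, path, params = NT_SCORE)
}

#' Read an identity matrix written by [write_identity_tsv()]
#'
#' @param path TSV path.
#' @return an `identity_matrix`.
#' @export
read_identity_tsv <- function(path) {
  df <- read_tsv_quiet(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$genome_id
  structure(m, class = c("identity_matrix", "matrix"))
}
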