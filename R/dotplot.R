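# Sliding-window exact-match dot plots.

#' Exact sliding-window matches between two sequences
#'
#' Marks every position pair `(i, j)` (0-based) where the length-`window`
#' words `A[i..i+window-1]` and `B[j..j+window-1]` are identical. Windows
#' containing `N` never match. With `include_revcomp = TRUE` a second hit set
#' against the reverse complement of B is computed; its `j` coordinates are
#' reported on the forward axis of B (position of the window's leftmost
#' forward-strand base).
#'
#' @param seq_a,seq_b DNA strings.
#' @param window word length in bp.
#' @param include_revcomp also search the reverse complement of `seq_b`.
#' @return an object of class `dot_matches`: list with `seq_a_id`, `seq_b_id`,
#'   `window`, and `hits`, a tibble of `i`, `j`, `strand` (`+`/`-`).
#' @export
window_matches <- function(seq_a, seq_b, window = 10L,
                           include_revcomp = FALSE) {
  if (window < 1L) abort("`window` must be >= 1.")
  if (nchar(seq_a) < window || nchar(seq_b) < window) {
    abort("`window` is longer than one of the sequences.")
  }
  fwd <- kmer_hits(seq_a, seq_b, window)
  hits <- tibble(i = fwd$i, j = fwd$j, strand = rep("+", length(fwd$i)))
  if (include_revcomp) {
    rc <- kmer_hits(seq_a, revcomp(seq_b), window)
    # map revcomp coordinate back onto the forward axis of B
    jf <- nchar(seq_b) - window - rc$j
    hits <- bind_rows(hits,
                      tibble(i = rc$i, j = jf, strand = rep("-", length(rc$i))))
  }
  structure(list(seq_a_id = attr(seq_a, "id") %||% "A",
                 seq_b_id = attr(seq_b, "id") %||% "B",
                 window = as.integer(window),
                 len_a = nchar(seq_a), len_b = nchar(seq_b),
                 hits = hits),
            class = "dot_matches")
}

# Index all windows of b, look up windows of a; N-containing windows dropped.
kmer_hits <- function(a, b, k) {
  ka <- seq_kmers(a, k)
  kb <- seq_kmers(b, k)
  ok_a <- which(!str_detect(ka, "N"))
  ok_b <- which(!str_detect(kb, "N"))
  if (!length(ok_a) || !length(ok_b)) return(list(i = integer(0), j = integer(0)))
  idx <- split(ok_b - 1L, kb[ok_b])          # word -> 0-based positions in b
  m <- idx[ka[ok_a]]
  n_each <- lengths(m)
  keep <- n_each > 0L
  list(i = rep(ok_a[keep] - 1L, n_each[keep]),
       j = as.integer(unlist(m[keep], use.names = FALSE)))
}

#' @export
print.dot_matches <- function(x, ...) {
  cat(sprintf("<dot_matches> %s vs %s, window %d: %d forward, %d revcomp hits\n",
              x$seq_a_id, x$seq_b_id, x$window,
              sum(x$hits$strand == "+"), sum(x$hits$strand == "-")))
  invisible(x)
}

#' @export
tidy.dot_matches <- function(x, ...) x$hits

#' Dot plot of a genome collection against itself
#'
#' Concatenates the genomes in the given order, computes sliding-window
#' matches of the concatenation against itself and draws the classic square
#' dot-plot matrix with genome boundaries; cluster spans can be labelled
#' along the top axis.
#'
#' @param genomes genome tibble (plot order = row order).
#' @param window word length in bp.
#' @param include_revcomp also plot reverse-complement matches.
#' @param cluster_labels optional named character vector genome_id -> label
#'   (e.g. cluster letters) drawn at the top axis.
#' @param max_points hit sets larger than this are thinned deterministically
#'   (every k-th point) to keep rendering tractable.
#' @return a ggplot object.
#' @export
plot_dotplot <- function(genomes, window = 10L, include_revcomp = FALSE,
                         cluster_labels = NULL, max_points = 500000L) {
  concat <- paste(genomes$sequence, collapse = "")
  dm <- window_matches(concat, concat, window = window,
                       include_revcomp = include_revcomp)
  hits <- dm$hits
  if (nrow(hits) > max_points) {
    hits <- hits[seq(1L, nrow(hits), by = ceiling(nrow(hits) / max_points)), ]
  }
  bounds <- cumsum(as.numeric(genomes$length))
  mids <- bounds - genomes$length / 2
  p <- ggplot(hits, aes(x = .data$i, y = .data$j)) +
    geom_point(aes(colour = .data$strand), size = 0.1, shape = 15) +
    scale_colour_manual(values = c(`+` = "black", `-` = "red"),
                        guide = "none") +
    geom_vline(xintercept = head(bounds, -1), linewidth = 0.1,
               colour = "grey60") +
    geom_hline(yintercept = head(bounds, -1), linewidth = 0.1,
               colour = "grey60") +
    scale_y_reverse() +
    coord_fixed() +
    labs(x = NULL, y = NULL) +
    theme_minimal()
  if (!is.null(cluster_labels)) {
    lab <- tibble(x = mids,
                  label = unname(cluster_labels[genomes$genome_id]))
    lab <- lab[!is.na(lab$label), ]
    runs <- lab %>% group_by(.data$label) %>%
      summarise(x = mean(.data$x), .groups = "drop")
    p <- p + annotate("text", x = runs$x, y = -0.01 * max(bounds),
                      label = runs$label, size = 3)
  }
  p
}

#' Write dot-plot hit pairs to TSV
#'
#' @param matches a `dot_matches` object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_dot_matches <- function(matches, path) {
  write_tsv_with_header(matches$hits, path,
                        params = list(window = matches$window,
                                      seq_a = matches$seq_a_id,
                                      seq_b = matches$seq_b_id))
}
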