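# Nei-Gojobori (1986) codon-based estimation of nucleotide diversity at
# synonymous and non-synonymous sites within ORF families, and the paired
# cross-family test for purifying selection.

# ---- codon machinery ---------------------------------------------------

.ng_cache <- new.env(parent = emptyenv())

genetic_code11 <- function() Biostrings::getGeneticCode("11")

sense_codons <- function() {
  gc <- genetic_code11()
  names(gc)[gc != "*"]
}

codon_neighbors <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (p in 1:3) {
    for (b in setdiff(DNA_BASES, ch[p])) {
      nb <- ch; nb[p] <- b
      out <- c(out, paste(nb, collapse = ""))
    }
  }
  out
}

#' Synonymous and non-synonymous site counts of a codon
#'
#' Each of the three positions contributes `f/3` synonymous sites, where `f`
#' is the number of its three single-nucleotide alternatives that preserve
#' the encoded amino acid (genetic code 11). Changes creating a stop codon
#' count as non-synonymous, so `s + n == 3` exactly for every sense codon.
#'
#' @param codon a 3-letter sense codon.
#' @return named numeric vector `c(s = ..., n = ...)`.
#' @export
ng_codon_sites <- function(codon) {
  gc <- genetic_code11()
  if (!codon %in% sense_codons()) {
    abort(sprintf("'%s' is not a sense codon of genetic code 11.", codon))
  }
  nb <- codon_neighbors(codon)
  syn <- sum(gc[nb] == gc[codon] & gc[nb] != "*") / 3
  c(s = syn, n = 3 - syn)
}

# Pathway enumeration between two sense codons: average synonymous and
# non-synonymous difference counts over all orderings of the changed
# positions, excluding pathways passing through stop codons (all pathways
# used if every one is blocked).
ng_codon_pair <- function(c1, c2) {
  gc <- genetic_code11()
  ch1 <- strsplit(c1, "")[[1]]; ch2 <- strsplit(c2, "")[[1]]
  diffs <- which(ch1 != ch2)
  k <- length(diffs)
  if (k == 0L) return(c(sd = 0, nd = 0))
  orders <- if (k == 1L) list(diffs) else
    lapply(combinat_perms(k), function(p) diffs[p])
  paths <- list()
  for (ord in orders) {
    cur <- ch1
    sd <- 0; nd <- 0; blocked <- FALSE
    for (p in ord) {
      prv <- paste(cur, collapse = "")
      cur[p] <- ch2[p]
      nxt <- paste(cur, collapse = "")
      if (gc[nxt] == "*") { blocked <- TRUE; break }
      if (gc[nxt] == gc[prv]) sd <- sd + 1 else nd <- nd + 1
    }
    if (!blocked) paths[[length(paths) + 1L]] <- c(sd = sd, nd = nd)
  }
  if (!length(paths)) {
    # all pathways traverse a stop; fall back to counting stop steps as
    # non-synonymous over all orderings
    for (ord in orders) {
      cur <- ch1
      sd <- 0; nd <- 0
      for (p in ord) {
        prv <- paste(cur, collapse = "")
        cur[p] <- ch2[p]
        nxt <- paste(cur, collapse = "")
        if (gc[nxt] != "*" && gc[prv] != "*" && gc[nxt] == gc[prv]) {
          sd <- sd + 1
        } else {
          nd <- nd + 1
        }
      }
      paths[[length(paths) + 1L]] <- c(sd = sd, nd = nd)
    }
  }
  colMeans(do.call(rbind, paths))
}

combinat_perms <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  rec <- function(prefix, rest) {
    if (!length(rest)) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (i in seq_along(rest)) rec(c(prefix, rest[i]), rest[-i])
  }
  rec(integer(0), seq_len(k))
  out
}

# Lazily built lookup tables: per-codon site counts and 61x61 pairwise
# Sd/Nd matrices, used to vectorise family-level computation.
ng_tables <- function() {
  if (!is.null(.ng_cache$tables)) return(.ng_cache$tables)
  cods <- sense_codons()
  s_sites <- vapply(cods, function(cd) ng_codon_sites(cd)[["s"]], numeric(1))
  nc <- length(cods)
  SD <- matrix(0, nc, nc, dimnames = list(cods, cods))
  ND <- SD
  for (i in seq_len(nc)) {
    for (j in i:nc) {
      v <- ng_codon_pair(cods[i], cods[j])
      SD[i, j] <- v[["sd"]]; SD[j, i] <- v[["sd"]]
      ND[i, j] <- v[["nd"]]; ND[j, i] <- v[["nd"]]
    }
  }
  .ng_cache$tables <- list(codons = cods, s_sites = s_sites, SD = SD, ND = ND)
  .ng_cache$tables
}

# ---- codon alignments --------------------------------------------------

#' Construct a codon alignment from equal-length in-frame sequences
#'
#' Validates that all sequences have the same length divisible by 3, that
#' gaps (`-`) occur only in whole-codon units, and that no sequence contains
#' an internal stop codon. Codon columns containing a gap in any sequence
#' are dropped (complete deletion) unless `complete_deletion = FALSE`, in
#' which case gapped columns are retained and excluded pair-by-pair later.
#'
#' @param seqs named character vector of aligned nucleotide sequences.
#' @param family_id identifier carried through to results.
#' @param complete_deletion drop codon columns with any gap.
#' @return an object of class `codon_alignment`.
#' @export
codon_alignment <- function(seqs, family_id = "family",
                            complete_deletion = TRUE) {
  if (length(seqs) < 2L) abort("need at least 2 sequences.")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) abort("sequences must have equal length.")
  if (lens[1] %% 3L != 0L) abort("alignment length must be divisible by 3.")
  cod <- do.call(rbind, lapply(seqs, split_codons))
  has_gap <- grepl("-", cod)
  if (any(has_gap & !cod %in% "---")) {
    abort("gaps must occur in whole-codon units.")
  }
  gcode <- genetic_code11()
  n_cod <- ncol(cod)
  is_stop <- matrix(cod %in% names(gcode)[gcode == "*"], nrow = nrow(cod))
  if (n_cod > 1L && any(is_stop[, -n_cod])) {
    abort("internal stop codon in alignment.")
  }
  if (n_cod > 0L && any(is_stop[, n_cod])) {
    cod <- cod[, -n_cod, drop = FALSE]   # trim terminal stop column
  }
  if (complete_deletion) {
    keep <- colSums(matrix(cod %in% "---", nrow = nrow(cod))) == 0L
    cod <- cod[, keep, drop = FALSE]
  }
  structure(list(family_id = family_id, codons = cod,
                 n_sequences = nrow(cod), n_codons = ncol(cod),
                 complete_deletion = complete_deletion),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %s: %d sequences x %d codons\n",
              x$family_id, x$n_sequences, x$n_codons))
  invisible(x)
}

#' Codon-align a family of coding sequences via their proteins
#'
#' Sequences are translated (genetic code 11), the proteins aligned with
#' MAFFT, and the protein alignment back-translated so that gaps fall on
#' codon boundaries. Sequences whose length is not divisible by 3 or that
#' contain internal stops are excluded with a warning; if fewer than
#' `min_members` usable sequences remain, `NULL` is returned with a warning.
#'
#' @param seqs named character vector of coding nucleotide sequences
#'   (terminal stop codons are trimmed if present).
#' @param family_id identifier carried through to results.
#' @param min_members minimum usable sequences.
#' @param complete_deletion passed to [codon_alignment()].
#' @return a `codon_alignment`, or `NULL` if the family is unusable.
#' @export
codon_align <- function(seqs, family_id = "family", min_members = 2L,
                        complete_deletion = TRUE) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  gcode <- genetic_code11()
  usable <- rep(TRUE, length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    if (nchar(s) %% 3L != 0L) { usable[i] <- FALSE; next }
    cods <- split_codons(s)
    if (length(cods) && gcode[cods[length(cods)]] %in% "*") {
      cods <- cods[-length(cods)]
      seqs[i] <- paste(cods, collapse = "")
    }
    aa <- gcode[cods]
    if (anyNA(aa) || any(aa == "*")) usable[i] <- FALSE
  }
  if (any(!usable)) {
    warn(sprintf("excluding %d sequence(s): internal stops or frame problems.",
                 sum(!usable)))
  }
  seqs <- seqs[usable]
  if (length(seqs) < min_members) {
    warn(sprintf("family %s has fewer than %d usable members; skipped.",
                 family_id, min_members))
    return(NULL)
  }
  prots <- translate11(seqs)
  if (length(unique(nchar(seqs))) == 1L && length(unique(prots)) == 1L) {
    aligned <- seqs   # identical proteins: alignment is the input
  } else {
    aln <- mafft_align(setNames(prots, names(seqs)))
    aligned <- vapply(names(seqs), function(nm) {
      backtranslate(aln[[nm]], seqs[[nm]])
    }, character(1))
  }
  codon_alignment(aligned, family_id = family_id,
                  complete_deletion = complete_deletion)
}

mafft_align <- function(prots) {
  if (Sys.which("mafft") == "") {
    abort("mafft not found on PATH; needed for protein alignment.")
  }
  fin <- tempfile(fileext = ".faa"); fout <- tempfile(fileext = ".afa")
  on.exit(unlink(c(fin, fout)))
  writeLines(paste0(">", names(prots), "\n", unname(prots)), fin)
  status <- system2("mafft", c("--auto", "--quiet", "--amino", fin),
                    stdout = fout, stderr = FALSE)
  if (status != 0L) abort("mafft failed.")
  aln <- Biostrings::readAAStringSet(fout)
  setNames(as.character(aln), sub("\\s.*$", "", names(aln)))
}

backtranslate <- function(aligned_prot, nt) {
  cods <- split_codons(nt)
  chars <- strsplit(aligned_prot, "")[[1]]
  out <- character(length(chars))
  k <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "-") {
      out[i] <- "---"
    } else {
      k <- k + 1L
      out[i] <- cods[k]
    }
  }
  if (k != length(cods)) abort("back-translation length mismatch.")
  paste(out, collapse = "")
}

# ---- diversity ---------------------------------------------------------

#' Proportions of synonymous and non-synonymous differences for one pair
#'
#' Nei-Gojobori proportions for two gap-free, equal-length, in-frame
#' sequences: `S` and `N` are the mean synonymous/non-synonymous site counts
#' of the two sequences; codons differing at several positions average their
#' difference counts over all substitution orderings, excluding pathways
#' through stop codons. Proportions are uncorrected by default; set
#' `jukes_cantor = TRUE` for the Jukes-Cantor multiple-hit correction.
#'
#' @param seq_a,seq_b aligned gap-free codon sequences.
#' @param jukes_cantor apply the Jukes-Cantor correction.
#' @return named vector `c(pn = ..., ps = ...)`.
#' @export
pairwise_pn_ps <- function(seq_a, seq_b, jukes_cantor = FALSE) {
  if (nchar(seq_a) != nchar(seq_b)) abort("sequences must have equal length.")
  if (nchar(seq_a) %% 3L != 0L) abort("length must be divisible by 3.")
  pair_pn_ps_codons(split_codons(seq_a), split_codons(seq_b), jukes_cantor)
}

pair_pn_ps_codons <- function(ca, cb, jukes_cantor = FALSE) {
  tab <- ng_tables()
  ia <- match(ca, tab$codons); ib <- match(cb, tab$codons)
  ok <- !is.na(ia) & !is.na(ib)
  if (!any(ok)) abort("no comparable (sense) codons.")
  ia <- ia[ok]; ib <- ib[ok]
  S <- (sum(tab$s_sites[ia]) + sum(tab$s_sites[ib])) / 2
  N <- 3 * length(ia) - S
  idx <- cbind(ia, ib)
  Sd <- sum(tab$SD[idx]); Nd <- sum(tab$ND[idx])
  pn <- if (N > 0) Nd / N else NaN
  ps <- if (S > 0) Sd / S else NaN
  if (jukes_cantor) {
    jc <- function(p) {
      if (p >= 0.75) abort("proportion too large for Jukes-Cantor correction.")
      -0.75 * log(1 - 4 * p / 3)
    }
    pn <- jc(pn); ps <- jc(ps)
  }
  c(pn = pn, ps = ps)
}

#' Within-family nucleotide diversity at non-synonymous and synonymous sites
#'
#' piN (piS) is the average of the pairwise non-synonymous (synonymous)
#' difference proportions over all unordered sequence pairs of the family,
#' duplicate sequences included. The ratio is reported only when piS > 0.
#'
#' @param alignment a `codon_alignment`.
#' @param jukes_cantor apply the Jukes-Cantor correction pairwise.
#' @return one-row tibble: `family_id`, `n_members`, `n_codons`, `pi_n`,
#'   `pi_s`, `ratio` (`NA` when piS == 0).
#' @export
family_diversity <- function(alignment, jukes_cantor = FALSE) {
  stopifnot(inherits(alignment, "codon_alignment"))
  cod <- alignment$codons
  if (!alignment$complete_deletion && any(cod %in% "---")) {
    abort("pairwise-deletion alignments: drop gapped columns per pair first.")
  }
  n <- nrow(cod)
  pn_sum <- 0; ps_sum <- 0; n_pairs <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      v <- pair_pn_ps_codons(cod[i, ], cod[j, ], jukes_cantor)
      pn_sum <- pn_sum + v[["pn"]]; ps_sum <- ps_sum + v[["ps"]]
      n_pairs <- n_pairs + 1L
    }
  }
  pi_n <- pn_sum / n_pairs; pi_s <- ps_sum / n_pairs
  tibble(family_id = alignment$family_id, n_members = n,
         n_codons = alignment$n_codons, pi_n = pi_n, pi_s = pi_s,
         ratio = if (is.finite(pi_s) && pi_s > 0) pi_n / pi_s else NA_real_)
}

#' Cross-family paired test for purifying selection
#'
#' Paired Wilcoxon signed-rank test of piN against piS across families
#' (zero differences dropped; exact distribution when 25 or fewer non-zero
#' pairs and no ties, otherwise the normal approximation with continuity
#' correction). The default one-sided alternative `"less"` asks whether piN
#' is systematically below piS, the signature of purifying selection.
#'
#' @param summaries tibble of [family_diversity()] rows.
#' @param alternative `"less"`, `"two.sided"` or `"greater"` (piN vs piS).
#' @param min_families minimum number of families with defined piN and piS.
#' @return object of class `selection_test`: list with `n_families`,
#'   `statistic` (signed-rank V), `p_value`, `n_ratio_lt_1`,
#'   `fraction_in_0_to_0.5`, `alternative`.
#' @export
selection_test <- function(summaries, alternative = "less",
                           min_families = 5L) {
  ok <- !is.na(summaries$pi_n) & !is.na(summaries$pi_s)
  df <- summaries[ok, ]
  if (nrow(df) < min_families) {
    abort(sprintf("need at least %d families with defined piN and piS.",
                  min_families))
  }
  d <- df$pi_n - df$pi_s
  nz <- d != 0
  if (!any(nz)) abort("piN equals piS in every family; test undefined.")
  n <- sum(nz)
  exact <- n <= 25L && !any(duplicated(abs(d[nz])))
  ht <- suppressWarnings(wilcox.test(df$pi_n, df$pi_s, paired = TRUE,
                                     alternative = alternative,
                                     exact = exact, correct = TRUE))
  ratios <- df$ratio[!is.na(df$ratio)]
  structure(list(n_families = nrow(df),
                 n_nonzero = n,
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 n_ratio_lt_1 = sum(ratios < 1),
                 fraction_in_0_to_0.5 = if (length(ratios))
                   mean(ratios >= 0 & ratios <= 0.5) else NA_real_,
                 alternative = alternative),
            class = "selection_test")
}

#' @export
print.selection_test <- function(x, ...) {
  cat(sprintf(paste0("<selection_test> %d families, V = %g, p = %.3g ",
                     "(alternative: piN %s piS)\n"),
              x$n_families, x$statistic, x$p_value,
              switch(x$alternative, less = "<", greater = ">", "!=")))
  cat(sprintf("  ratios < 1: %d; fraction of ratios in [0, 0.5]: %.3f\n",
              x$n_ratio_lt_1, x$fraction_in_0_to_0.5))
  invisible(x)
}

#' @export
tidy.selection_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         n_families = x$n_families, n_ratio_lt_1 = x$n_ratio_lt_1,
         fraction_in_0_to_0.5 = x$fraction_in_0_to_0.5,
         alternative = x$alternative)
}

#' @export
glance.selection_test <- function(x, ...) tidy(x)

#' Write per-family diversity table as TSV
#' @param summaries tibble of [family_diversity()] rows.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_diversity <- function(summaries, path) {
  write_tsv_with_header(summaries, path)
}

#' Histogram of piN/piS ratios across families
#'
#' Families with undefined ratio (piS == 0) are excluded.
#'
#' @param summaries tibble of [family_diversity()] rows.
#' @param binwidth ratio bin width.
#' @return a ggplot object.
#' @export
plot_ratio_histogram <- function(summaries, binwidth = 0.1) {
  df <- summaries[!is.na(summaries$ratio), ]
  ggplot(df, aes(x = .data$ratio)) +
    geom_histogram(binwidth = binwidth, boundary = 0, fill = "grey30") +
    geom_vline(xintercept = 1, linetype = "dashed", colour = "red") +
    labs(x = expression(pi[N] / pi[S]), y = "families") +
    theme_classic()
}
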