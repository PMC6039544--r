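# CRISPR spacer (protospacer) search against phage genomes, with relaxed
# short-query alignment parameters, and host-species classification of hits.

# Ungapped Karlin-Altschul parameters for +1/-1 nucleotide scoring; e-values
# are documented approximations (acceptance rests on alignment-score and
# planted-locus agreement, not NCBI e-value replication).
KA_NT <- list(lambda = 1.33, K = 0.621)

#' Read spacers with their species-of-origin sidecar
#'
#' @param fasta spacer FASTA path.
#' @param sidecar TSV with columns `spacer_id`, `source_species`.
#' @return tibble `spacer_id`, `source_species`, `length`, `sequence`.
#' @export
read_spacers <- function(fasta, sidecar) {
  sp <- read_genome_fasta(fasta)
  meta <- read_tsv_quiet(sidecar)
  if (!all(c("spacer_id", "source_species") %in% names(meta))) {
    abort("sidecar must have columns spacer_id, source_species.")
  }
  out <- tibble(spacer_id = sp$genome_id, length = sp$length,
                sequence = sp$sequence) %>%
    left_join(meta, by = "spacer_id")
  if (anyNA(out$source_species)) {
    abort("sidecar is missing source_species for some spacers.")
  }
  select(out, "spacer_id", "source_species", "length", "sequence")
}

#' Search spacers against genomes
#'
#' Short-query nucleotide search tuned for 25-75 bp spacers: for each
#' (spacer, genome, strand), candidate strands containing an exact
#' `word_size` seed are scored by Smith-Waterman local alignment with
#' match +1, mismatch -1 and affine gaps (open 10, extend 2); a hit is
#' reported when its Karlin-Altschul e-value (search space = spacer length x
#' total genome length) is at most `max_evalue`. No low-complexity (dust)
#' filtering is applied. By default the single best hit per (spacer, genome,
#' strand) is kept; `count_all = TRUE` iteratively masks each hit and
#' re-searches to enumerate non-overlapping hits.
#'
#' @param spacers tibble from [read_spacers()] (needs `spacer_id`,
#'   `sequence`).
#' @param genomes genome tibble.
#' @param max_evalue e-value ceiling for reporting.
#' @param word_size exact-seed length required for a strand to be scored.
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param match,mismatch match reward and mismatch penalty (positive).
#' @param count_all enumerate non-overlapping hits instead of one best.
#' @return tibble `spacer_id`, `genome_id`, `strand`, `start`, `end`
#'   (0-based half-open on the forward genome axis), `score`, `evalue`.
#' @export
search_spacers <- function(spacers, genomes, max_evalue = 0.3, word_size = 7L,
                           gap_open = 10, gap_extend = 2, mismatch = 1,
                           match = 1, count_all = FALSE) {
  if (!nrow(spacers) || !nrow(genomes)) {
    abort("spacers and genomes must be non-empty.")
  }
  if (any(word_size > nchar(spacers$sequence))) {
    abort("`word_size` exceeds a spacer length.")
  }
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = -mismatch, baseOnly = FALSE)
  n_total <- sum(genomes$length)
  res <- list()
  for (g in seq_len(nrow(genomes))) {
    gseq <- genomes$sequence[g]
    L <- nchar(gseq)
    for (strand in c("+", "-")) {
      sseq <- if (strand == "+") gseq else revcomp(gseq)
      gwords <- unique(seq_kmers(sseq, word_size))
      seeded <- which(map_lgl(spacers$sequence, function(sp) {
        any(seq_kmers(sp, word_size) %in% gwords)
      }))
      if (!length(seeded)) next
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(spacers$sequence[seeded]),
        Biostrings::DNAString(sseq),
        substitutionMatrix = submat, gapOpening = gap_open,
        gapExtension = gap_extend, type = "local")
      sc <- Biostrings::score(al)
      st <- Biostrings::start(Biostrings::subject(al))
      en <- Biostrings::end(Biostrings::subject(al))
      ev <- KA_NT$K * nchar(spacers$sequence[seeded]) * n_total *
        exp(-KA_NT$lambda * sc)
      keep <- which(ev <= max_evalue & sc > 0)
      for (q in keep) {
        s <- seeded[q]
        hits <- tibble(s_start = st[q], s_end = en[q], score = sc[q])
        if (count_all) {
          more <- local_hits(spacers$sequence[s], sseq, submat, gap_open,
                             gap_extend, count_all = TRUE,
                             skip_first = hits)
          hits <- bind_rows(hits, more)
          hev <- KA_NT$K * nchar(spacers$sequence[s]) * n_total *
            exp(-KA_NT$lambda * hits$score)
          hits <- hits[hev <= max_evalue, ]
        }
        hev <- KA_NT$K * nchar(spacers$sequence[s]) * n_total *
          exp(-KA_NT$lambda * hits$score)
        start <- if (strand == "+") hits$s_start - 1L else L - hits$s_end
        end <- if (strand == "+") hits$s_end else L - hits$s_start + 1L
        res[[length(res) + 1L]] <- tibble(
          spacer_id = spacers$spacer_id[s], genome_id = genomes$genome_id[g],
          strand = strand, start = as.integer(start), end = as.integer(end),
          score = hits$score, evalue = hev)
      }
    }
  }
  out <- bind_rows(res)
  if (!nrow(out)) {
    return(tibble(spacer_id = character(0), genome_id = character(0),
                  strand = character(0), start = integer(0), end = integer(0),
                  score = numeric(0), evalue = numeric(0)))
  }
  arrange(out, .data$spacer_id, .data$genome_id, .data$strand, .data$start)
}

# Best (or all non-overlapping) local alignments of `sp` in strand sequence.
# `skip_first`: a best hit already computed; it is masked before iterating.
local_hits <- function(sp, sseq, submat, gap_open, gap_extend,
                       count_all = FALSE, max_iter = 20L, skip_first = NULL) {
  out <- tibble(s_start = integer(0), s_end = integer(0), score = numeric(0))
  cur <- sseq
  if (!is.null(skip_first)) {
    substr(cur, skip_first$s_start[1], skip_first$s_end[1]) <-
      paste(rep("N", skip_first$s_end[1] - skip_first$s_start[1] + 1L),
            collapse = "")
  }
  for (it in seq_len(if (count_all) max_iter else 1L)) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(sp), Biostrings::DNAString(cur),
      substitutionMatrix = submat, gapOpening = gap_open,
      gapExtension = gap_extend, type = "local")
    sc <- Biostrings::score(al)
    if (sc <= 0) break
    rng <- Biostrings::subject(al)
    st <- Biostrings::start(rng); en <- Biostrings::end(rng)
    out <- bind_rows(out, tibble(s_start = st, s_end = en, score = sc))
    if (!count_all) break
    substr(cur, st, en) <- paste(rep("N", en - st + 1L), collapse = "")
  }
  out
}

normalize_species <- function(x) {
  map_chr(str_split(str_squish(x), " "), function(w) {
    paste(head(w, 2), collapse = " ")
  })
}

#' Classify spacer hits by host species and aggregate per cluster
#'
#' Each hit is labelled by comparing the spacer's species of origin to the
#' phage's recorded host species at the "Genus species" level (strain
#' suffixes ignored). Counts are aggregated per genome cluster, with
#' singletons pooled under `SINGLETON`.
#'
#' @param hits tibble from [search_spacers()].
#' @param spacers tibble with `spacer_id`, `source_species`.
#' @param hosts tibble `genome_id`, `host_species`.
#' @param assignment `cluster_assignment`.
#' @return tibble `cluster`, `hits_to_original_host`, `hits_to_other_species`,
#'   `total`; hits on genomes lacking host metadata are excluded with a
#'   warning and counted in attribute `n_excluded`.
#' @export
classify_hits <- function(hits, spacers, hosts, assignment) {
  df <- hits %>%
    left_join(select(spacers, "spacer_id", "source_species"), by = "spacer_id") %>%
    left_join(hosts, by = "genome_id") %>%
    left_join(assignment$membership, by = "genome_id")
  n_excl <- sum(is.na(df$host_species))
  if (n_excl > 0L) {
    warn(sprintf("%d hit(s) excluded: no host metadata for their genome.",
                 n_excl))
    df <- df[!is.na(df$host_species), ]
  }
  df <- df %>%
    mutate(same = normalize_species(.data$source_species) ==
             normalize_species(.data$host_species))
  clusters <- assignment$membership %>% distinct(.data$cluster)
  out <- df %>%
    group_by(.data$cluster) %>%
    summarise(hits_to_original_host = sum(.data$same),
              hits_to_other_species = sum(!.data$same),
              .groups = "drop") %>%
    right_join(clusters, by = "cluster") %>%
    mutate(across(c("hits_to_original_host", "hits_to_other_species"),
                  ~ ifelse(is.na(.x), 0L, .x)),
           total = .data$hits_to_original_host + .data$hits_to_other_species) %>%
    arrange(.data$cluster)
  attr(out, "n_excluded") <- n_excl
  out
}

#' Write spacer hits as TSV
#' @param hits tibble from [search_spacers()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_spacer_hits <- function(hits, path) {
  out <- hits
  out$evalue <- signif(out$evalue, 4)
  write_tsv_with_header(out, path)
}
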