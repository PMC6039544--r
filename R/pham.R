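# Protein family ("pham") assignment: dual-threshold pairwise similarity
# links resolved into families by single-linkage (connected components).

# Ungapped Karlin-Altschul parameters for BLOSUM62; e-values are documented
# approximations (family membership is threshold-based, not tail-calibrated).
KA_PROT <- list(lambda = 0.3176, K = 0.134)
PROT_GAP <- list(global_open = 10, global_extend = 1,
                 local_open = 11, local_extend = 1)

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

assert_protein <- function(x, ids = NULL) {
  bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", x)
  if (any(bad)) {
    who <- if (is.null(ids)) which(bad) else ids[bad]
    abort(sprintf("protein sequence(s) outside the 20-letter alphabet + X: %s",
                  paste(head(who, 5), collapse = ", ")))
  }
  invisible(x)
}

#' Pairwise protein similarity links
#'
#' Computes, for candidate protein pairs, global percent identity (affine-gap
#' global alignment, BLOSUM62) and the e-value of the best local alignment
#' (Smith-Waterman, BLOSUM62, gap open 11 / extend 1; ungapped
#' Karlin-Altschul statistics with search space m x n where n is the total
#' residue count of the protein set). A link is emitted when either
#' `global identity >= identity_threshold` (inclusive) or
#' `e-value <= evalue_threshold` (inclusive).
#'
#' `prefilter_k > 0` restricts evaluation to pairs sharing at least one
#' amino-acid k-mer — a speed heuristic for large runs that cannot drop pairs
#' passing either threshold in practice, since both demand substantial exact
#' conservation; `0` evaluates every pair.
#'
#' @param orfs tibble with `orf_id` and `aa_seq`.
#' @param identity_threshold percent identity threshold (inclusive).
#' @param evalue_threshold local-alignment e-value threshold (inclusive).
#' @param prefilter_k shared k-mer prefilter length, 0 to disable.
#' @return tibble of links: `orf_a`, `orf_b`, `global_identity_pct`,
#'   `local_score`, `local_evalue`, with the search-space size recorded in
#'   attribute `search_n`.
#' @export
protein_pairwise <- function(orfs, identity_threshold = 35,
                             evalue_threshold = 1e-50, prefilter_k = 0L) {
  if (nrow(orfs) < 2L) abort("need at least 2 proteins.")
  if (identity_threshold < 0 || identity_threshold > 100) {
    abort("`identity_threshold` must be in [0, 100].")
  }
  ids <- orfs$orf_id
  seqs <- orfs$aa_seq
  assert_protein(seqs, ids)
  n_total <- sum(nchar(seqs))
  pairs <- candidate_pairs(seqs, prefilter_k)
  if (!nrow(pairs)) {
    return(empty_links(n_total))
  }
  sub <- blosum62()
  alphabet <- rownames(sub)
  aa <- Biostrings::AAStringSet(seqs)
  # global identity per pair via the compiled affine aligner
  gid <- map_dbl(seq_len(nrow(pairs)), function(q) {
    cnt <- .nw_matrix_counts(seqs[pairs$i[q]], seqs[pairs$j[q]], sub,
                             alphabet, PROT_GAP$global_open,
                             PROT_GAP$global_extend, TRUE)
    if (cnt[["cols"]] == 0) 0 else 100 * cnt[["matches"]] / cnt[["cols"]]
  })
  # best local score per pair, batched per subject (score only: fast path)
  sc <- numeric(nrow(pairs))
  for (j in unique(pairs$j)) {
    rows <- which(pairs$j == j)
    sc[rows] <- Biostrings::pairwiseAlignment(
      aa[pairs$i[rows]], aa[[j]], substitutionMatrix = sub, type = "local",
      gapOpening = PROT_GAP$local_open, gapExtension = PROT_GAP$local_extend,
      scoreOnly = TRUE)
  }
  ev <- KA_PROT$K * nchar(seqs[pairs$i]) * n_total * exp(-KA_PROT$lambda * sc)
  links <- tibble(orf_a = ids[pairs$i], orf_b = ids[pairs$j],
                  global_identity_pct = gid,
                  local_score = sc, local_evalue = ev)
  links <- links[links$global_identity_pct >= identity_threshold |
                   links$local_evalue <= evalue_threshold, ]
  attr(links, "search_n") <- n_total
  links
}

empty_links <- function(n_total) {
  structure(tibble(orf_a = character(0), orf_b = character(0),
                   global_identity_pct = numeric(0),
                   local_score = numeric(0), local_evalue = numeric(0)),
            search_n = n_total)
}

# All unordered pairs (i < j), optionally restricted to pairs sharing a k-mer.
candidate_pairs <- function(seqs, prefilter_k) {
  n <- length(seqs)
  if (prefilter_k <= 0L) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    return(tibble(i = idx[, 1], j = idx[, 2]))
  }
  km_df <- tibble(
    s = rep(seq_len(n), times = map_dbl(seqs, ~ length(unique(seq_kmers(.x, prefilter_k))))),
    km = unlist(lapply(seqs, function(x) unique(seq_kmers(x, prefilter_k))))
  )
  joined <- inner_join(km_df, km_df, by = "km", relationship = "many-to-many")
  joined %>%
    filter(.data$s.x < .data$s.y) %>%
    distinct(.data$s.x, .data$s.y) %>%
    transmute(i = .data$s.x, j = .data$s.y)
}

#' Resolve similarity links into phams by single linkage
#'
#' Phams are the connected components of the link graph; proteins with no
#' link become singleton phams. Pham ids are assigned deterministically in
#' order of each component's smallest member `orf_id`.
#'
#' @param links tibble from [protein_pairwise()].
#' @param orf_universe character vector of all `orf_id`s to partition.
#' @return tibble `orf_id`, `pham_id` (integer), one row per ORF.
#' @export
build_phams <- function(links, orf_universe) {
  orf_universe <- sort(unique(orf_universe))
  stray <- setdiff(c(links$orf_a, links$orf_b), orf_universe)
  if (length(stray)) {
    abort(sprintf("links reference ORFs outside the universe: %s",
                  paste(head(stray, 5), collapse = ", ")))
  }
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = links$orf_a, to = links$orf_b),
    directed = FALSE,
    vertices = data.frame(name = orf_universe))
  comp <- igraph::components(g)$membership
  first_member <- tapply(names(comp), comp, min)
  new_id <- setNames(rank(first_member, ties.method = "first"),
                     names(first_member))
  tibble(orf_id = orf_universe,
         pham_id = as.integer(new_id[as.character(comp[orf_universe])]))
}

#' Strict ORF families for evolutionary analysis
#'
#' Same construction as ordinary phams but at a stricter identity threshold,
#' keeping only families with at least `min_members` members — the kind of
#' well-aligned, well-populated family on which within-family diversity can
#' be estimated.
#'
#' @inheritParams protein_pairwise
#' @param min_members smallest family size retained.
#' @return tibble `orf_id`, `pham_id` restricted to retained families.
#' @export
strict_families <- function(orfs, identity_threshold = 50,
                            evalue_threshold = 1e-50, min_members = 15L,
                            prefilter_k = 0L) {
  links <- protein_pairwise(orfs, identity_threshold = identity_threshold,
                            evalue_threshold = evalue_threshold,
                            prefilter_k = prefilter_k)
  phams <- build_phams(links, orfs$orf_id)
  keep <- phams %>% count(.data$pham_id) %>% filter(.data$n >= min_members)
  phams %>% filter(.data$pham_id %in% keep$pham_id)
}

#' Family-size histogram
#'
#' @param phams tibble `orf_id`, `pham_id`.
#' @return tibble `size`, `n_families`, ascending in `size`; the counts sum
#'   to the number of phams and `sum(size * n_families)` to the ORF count.
#' @export
family_size_histogram <- function(phams) {
  if (!nrow(phams)) return(tibble(size = integer(0), n_families = integer(0)))
  phams %>%
    count(.data$pham_id, name = "size") %>%
    count(.data$size, name = "n_families") %>%
    arrange(.data$size)
}

#' Write pham membership as TSV
#' @param phams tibble `orf_id`, `pham_id`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_phams <- function(phams, path) write_tsv_with_header(phams, path)

#' Read pham membership written by [write_phams()]
#' @param path TSV path.
#' @return tibble `orf_id`, `pham_id`.
#' @export
read_phams <- function(path) read_tsv_quiet(path)
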