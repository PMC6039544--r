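# Genome cluster / singleton assignment from nucleotide identity and shared
# protein families.

#' Number of protein families shared by two genomes
#'
#' Counts distinct phams with at least one member ORF in each genome,
#' regardless of how many member ORFs each genome contributes.
#'
#' @param genome_a,genome_b genome ids.
#' @param pham_membership tibble with `orf_id`, `genome_id`, `pham_id` (join
#'   pham assignment onto the ORF table to produce it).
#' @return integer count (0, with a warning, for a genome with no ORFs).
#' @export
shared_pham_count <- function(genome_a, genome_b, pham_membership) {
  pa <- unique(pham_membership$pham_id[pham_membership$genome_id == genome_a])
  pb <- unique(pham_membership$pham_id[pham_membership$genome_id == genome_b])
  if (!length(pa) || !length(pb)) {
    warn(sprintf("genome %s has no ORFs assigned to phams",
                 if (!length(pa)) genome_a else genome_b))
    return(0L)
  }
  length(intersect(pa, pb))
}

#' Pairwise shared-pham count matrix
#'
#' @param genome_ids genome ids defining row/column order.
#' @param pham_membership as in [shared_pham_count()].
#' @return symmetric integer matrix; the diagonal holds each genome's own
#'   distinct pham count.
#' @export
shared_pham_matrix <- function(genome_ids, pham_membership) {
  sets <- lapply(genome_ids, function(g) {
    unique(pham_membership$pham_id[pham_membership$genome_id == g])
  })
  n <- length(genome_ids)
  m <- matrix(0L, n, n, dimnames = list(genome_ids, genome_ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      v <- length(intersect(sets[[i]], sets[[j]]))
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  m
}

#' Assign genomes to clusters and singletons
#'
#' A pair of genomes is linked when its nucleotide identity is strictly above
#' `id_threshold` AND its shared-pham count strictly above `pham_threshold`
#' (so 45.0% identity or exactly 20 shared families do not qualify). Under
#' the default single linkage, clusters are the connected components of the
#' link graph with at least `min_size` members; `"complete"` linkage instead
#' requires every within-cluster pair to qualify. All remaining genomes are
#' singletons. Clusters are lettered by decreasing size (largest = `A`), ties
#' broken by smallest member id.
#'
#' @param identity `identity_matrix` (percent).
#' @param shared symmetric shared-pham count matrix over the same genomes.
#' @param id_threshold percent identity threshold (exclusive).
#' @param pham_threshold shared-family threshold (exclusive).
#' @param min_size minimum cluster size.
#' @param linkage `"single"` (default) or `"complete"`.
#' @return a `cluster_assignment`: list with `membership` (tibble
#'   `genome_id`, `cluster`; singletons get `"SINGLETON"`), `evidence`
#'   (qualifying edges within clusters with identity and shared counts) and
#'   `params`.
#' @export
assign_clusters <- function(identity, shared, id_threshold = 45,
                            pham_threshold = 20, min_size = 3L,
                            linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  if (id_threshold < 0 || id_threshold > 100) {
    abort("`id_threshold` must be in [0, 100].")
  }
  ids <- rownames(identity)
  if (!identical(sort(ids), sort(rownames(shared)))) {
    abort("identity and shared-pham matrices cover different genome sets.")
  }
  shared <- shared[ids, ids]
  pass <- unclass(identity) > id_threshold & shared > pham_threshold
  diag(pass) <- TRUE
  d <- stats::as.dist(1 - pass)
  hc <- stats::hclust(d, method = if (linkage == "single") "single" else
    "complete")
  comp <- stats::cutree(hc, h = 0.5)
  sizes <- table(comp)
  keep <- as.integer(names(sizes)[sizes >= min_size])
  membership <- setNames(rep("SINGLETON", length(ids)), ids)
  if (length(keep)) {
    first_member <- tapply(ids, comp, min)
    ord <- keep[order(-sizes[as.character(keep)],
                      first_member[as.character(keep)])]
    for (k in seq_along(ord)) {
      membership[comp == ord[k]] <- cluster_letter(k)
    }
  }
  edges <- which(pass & upper.tri(pass), arr.ind = TRUE)
  evidence <- tibble(genome_a = ids[edges[, 1]], genome_b = ids[edges[, 2]],
                     identity_pct = unclass(identity)[edges],
                     shared_phams = shared[edges]) %>%
    filter(membership[.data$genome_a] != "SINGLETON",
           membership[.data$genome_a] == membership[.data$genome_b])
  structure(list(
    membership = tibble(genome_id = ids, cluster = unname(membership)),
    evidence = evidence,
    params = list(id_threshold = id_threshold,
                  pham_threshold = pham_threshold,
                  min_size = min_size, linkage = linkage)),
    class = "cluster_assignment")
}

# A, B, ..., Z, AA, AB, ... (sequential letters; no letters are skipped)
cluster_letter <- function(k) {
  if (k <= 26L) return(LETTERS[k])
  paste0(LETTERS[(k - 1L) %/% 26L], LETTERS[(k - 1L) %% 26L + 1L])
}

#' @export
print.cluster_assignment <- function(x, ...) {
  tab <- table(x$membership$cluster)
  n_clu <- sum(names(tab) != "SINGLETON")
  n_sing <- sum(x$membership$cluster == "SINGLETON")
  cat(sprintf("<cluster_assignment> %d genomes: %d cluster(s), %d singleton(s)\n",
              nrow(x$membership), n_clu, n_sing))
  invisible(x)
}

#' @export
tidy.cluster_assignment <- function(x, ...) x$membership

#' @export
glance.cluster_assignment <- function(x, ...) {
  cl <- x$membership$cluster
  tibble(n_genomes = length(cl),
         n_clusters = length(unique(cl[cl != "SINGLETON"])),
         n_clustered = sum(cl != "SINGLETON"),
         n_singletons = sum(cl == "SINGLETON"))
}

#' Per-cluster summary table
#'
#' Mean and sample standard deviation (n - 1) of ORF count, ORF density,
#' genome size and GC% per cluster, plus the set of host species and a
#' multi-host flag. Singletons are excluded; list them via
#' `tidy(assignment)`.
#'
#' @param assignment `cluster_assignment`.
#' @param stats tibble from [genome_stats()].
#' @param hosts optional tibble `genome_id`, `host_species`.
#' @return a tibble, one row per cluster, ordered by cluster letter.
#' @export
cluster_summary <- function(assignment, stats, hosts = NULL) {
  mem <- assignment$membership %>% filter(.data$cluster != "SINGLETON")
  df <- mem %>% inner_join(stats, by = "genome_id")
  if (!is.null(hosts)) df <- df %>% left_join(hosts, by = "genome_id")
  else df$host_species <- NA_character_
  df %>%
    group_by(.data$cluster) %>%
    summarise(
      n_members = n(),
      multi_host = length(unique(na.omit(.data$host_species))) > 1L,
      host_species = paste(sort(unique(na.omit(.data$host_species))),
                           collapse = "; "),
      orf_count_mean = mean(.data$orf_count),
      orf_count_sd = sd(.data$orf_count),
      orfs_per_kb_mean = mean(.data$orfs_per_kb),
      orfs_per_kb_sd = sd(.data$orfs_per_kb),
      size_bp_mean = mean(.data$size_bp),
      size_bp_sd = sd(.data$size_bp),
      gc_percent_mean = mean(.data$gc_percent),
      gc_percent_sd = sd(.data$gc_percent),
      .groups = "drop") %>%
    arrange(.data$cluster)
}

#' Write cluster membership as TSV
#' @param assignment `cluster_assignment`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_clusters <- function(assignment, path) {
  mem <- assignment$membership
  sizes <- mem %>% count(.data$cluster, name = "n_members")
  out <- mem %>% left_join(sizes, by = "cluster") %>%
    mutate(n_members = ifelse(.data$cluster == "SINGLETON", 1L,
                              .data$n_members))
  write_tsv_with_header(out, path, params = assignment$params[1:3])
}
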