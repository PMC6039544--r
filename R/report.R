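# Run configuration, the chained pipeline, and summary reports.

#' Pipeline run configuration
#'
#' Defaults are the canonical thresholds of the analysis: genome clustering
#' at >45% nucleotide identity, >20 shared families, >=3 members; pham
#' assignment at >=35% amino-acid identity or e-value <=1e-50 (50% and >=15
#' members for the strict evolutionary-analysis families); spacer search at
#' e-value <=0.3, word size 7, gap open 10 / extend 2, mismatch 1.
#'
#' @param id_threshold,pham_threshold,min_cluster_size genome clustering.
#' @param pham_identity,strict_identity,evalue_threshold,strict_min_members
#'   pham assignment.
#' @param spacer_max_evalue,spacer_word_size spacer search.
#' @param orf_min_len minimal ORF length (bp).
#' @param prefilter_k shared amino-acid k-mer prefilter for the pairwise
#'   protein stage (0 disables; the pipeline default 5 trades exhaustiveness
#'   for speed on large runs).
#' @param seed seed for any randomised stage.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(id_threshold = 45, pham_threshold = 20,
                       min_cluster_size = 3L, pham_identity = 35,
                       strict_identity = 50, evalue_threshold = 1e-50,
                       strict_min_members = 15L, spacer_max_evalue = 0.3,
                       spacer_word_size = 7L, orf_min_len = 300L,
                       prefilter_k = 5L, seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

write_run_config <- function(config, path) {
  writeLines(c(output_header(),
               paste(names(config), unlist(config), sep = "=")), path)
  invisible(path)
}

#' Run the full comparative pipeline
#'
#' Chains ORF calling, per-genome statistics, pairwise identity, pham
#' assignment, genome clustering, optional spacer search/classification and
#' the strict-family piN/piS analysis, writing each result table into
#' `out_dir` under fixed filenames (`stats.tsv`, `identity.tsv`,
#' `phams.tsv`, `clusters.tsv`, `spacer_hits.tsv`, `diversity.tsv`,
#' `resolved_config`).
#'
#' @param genomes genome tibble.
#' @param hosts optional tibble `genome_id`, `host_species`.
#' @param spacers optional spacer tibble (see [read_spacers()]).
#' @param config a [run_config()].
#' @param out_dir optional output directory; `NULL` skips file output.
#' @param quiet suppress progress messages.
#' @return list with `orfs`, `stats`, `identity`, `phams`, `links`,
#'   `assignment`, `summary`, and when inputs allow, `spacer_hits`,
#'   `spacer_classes`, `diversity`, `selection`.
#' @export
run_pipeline <- function(genomes, hosts = NULL, spacers = NULL,
                         config = run_config(), out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  stage <- function(what) {
    say("[%5.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"), what)
  }

  stage("calling ORFs")
  orfs <- call_orfs(genomes, min_len = config$orf_min_len)
  stats_tbl <- genome_stats(genomes, orfs)

  stage("pairwise nucleotide identity")
  idm <- identity_matrix(genomes)

  stage("pairwise protein comparison")
  links <- protein_pairwise(orfs, identity_threshold = config$pham_identity,
                            evalue_threshold = config$evalue_threshold,
                            prefilter_k = config$prefilter_k)
  phams <- build_phams(links, orfs$orf_id)
  membership <- orfs %>% select("orf_id", "genome_id") %>%
    inner_join(phams, by = "orf_id")

  stage("genome clustering")
  shared <- shared_pham_matrix(genomes$genome_id, membership)
  assignment <- assign_clusters(idm, shared,
                                id_threshold = config$id_threshold,
                                pham_threshold = config$pham_threshold,
                                min_size = config$min_cluster_size)
  summary_tbl <- cluster_summary(assignment, stats_tbl, hosts)

  out <- list(orfs = orfs, stats = stats_tbl, identity = idm,
              phams = phams, links = links, assignment = assignment,
              summary = summary_tbl)

  if (!is.null(spacers) && nrow(spacers)) {
    stage("spacer search")
    out$spacer_hits <- search_spacers(spacers, genomes,
                                      max_evalue = config$spacer_max_evalue,
                                      word_size = config$spacer_word_size)
    if (!is.null(hosts)) {
      out$spacer_classes <- classify_hits(out$spacer_hits, spacers, hosts,
                                          assignment)
    }
  }

  stage("strict families and diversity")
  if (config$strict_identity >= config$pham_identity) {
    # the strict link set is a subset of the links already computed
    strict_links <- links[links$global_identity_pct >= config$strict_identity |
                            links$local_evalue <= config$evalue_threshold, ]
    strict_all <- build_phams(strict_links, orfs$orf_id)
    keep <- strict_all %>% count(.data$pham_id) %>%
      filter(.data$n >= config$strict_min_members)
    strict <- strict_all %>% filter(.data$pham_id %in% keep$pham_id)
  } else {
    strict <- strict_families(orfs,
                              identity_threshold = config$strict_identity,
                              evalue_threshold = config$evalue_threshold,
                              min_members = config$strict_min_members,
                              prefilter_k = config$prefilter_k)
  }
  if (nrow(strict)) {
    fams <- split(strict$orf_id, strict$pham_id)
    seq_of <- setNames(orfs$nt_seq, orfs$orf_id)
    div <- imap(fams, function(members, fid) {
      aln <- codon_align(seq_of[members], family_id = paste0("fam", fid),
                         min_members = config$strict_min_members)
      if (is.null(aln)) NULL else family_diversity(aln)
    })
    out$diversity <- bind_rows(div)
    if (nrow(out$diversity) >= 5L) {
      out$selection <- selection_test(out$diversity)
    }
  } else {
    out$diversity <- tibble(family_id = character(0), n_members = integer(0),
                            n_codons = integer(0), pi_n = numeric(0),
                            pi_s = numeric(0), ratio = numeric(0))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_genome_stats(stats_tbl, file.path(out_dir, "stats.tsv"))
    write_identity_tsv(idm, file.path(out_dir, "identity.tsv"))
    write_phams(phams, file.path(out_dir, "phams.tsv"))
    write_clusters(assignment, file.path(out_dir, "clusters.tsv"))
    write_diversity(out$diversity, file.path(out_dir, "diversity.tsv"))
    if (!is.null(out$spacer_hits)) {
      write_spacer_hits(out$spacer_hits, file.path(out_dir, "spacer_hits.tsv"))
    }
    write_run_config(config, file.path(out_dir, "resolved_config"))
  }
  stage("done")
  out
}

#' ORF count vs genome size correlation report
#'
#' Ordinary least squares of predicted ORF count on genome size.
#'
#' @param stats tibble from [genome_stats()] (>= 3 genomes).
#' @return object of class `correlation_report`: list with `r_squared`,
#'   `p_value`, `slope`, `intercept`, `n`.
#' @export
correlation_report <- function(stats) {
  if (nrow(stats) < 3L) abort("need at least 3 genomes.")
  if (sd(stats$size_bp) == 0) abort("genome size is constant; R^2 undefined.")
  fit <- lm(orf_count ~ size_bp, data = stats)
  sm <- summary(fit)
  structure(list(r_squared = sm$r.squared,
                 p_value = sm$coefficients["size_bp", "Pr(>|t|)"],
                 slope = unname(stats::coef(fit)["size_bp"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 n = nrow(stats)),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> ORF count ~ genome size: R^2 = %.3f, p = %.3g (n = %d)\n",
              x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' @export
tidy.correlation_report <- function(x, ...) {
  tibble(r_squared = x$r_squared, p_value = x$p_value, slope = x$slope,
         intercept = x$intercept, n = x$n)
}

#' @export
glance.correlation_report <- function(x, ...) tidy(x)

#' Rank-ordered genome property plots and the size~ORF scatter
#'
#' @param stats tibble from [genome_stats()].
#' @return a patchwork-free list of three ggplot objects: `size_rank`,
#'   `gc_rank`, `orf_vs_size`.
#' @export
plot_genome_overview <- function(stats) {
  ranked <- function(col, ylab) {
    df <- stats %>% arrange(desc(.data[[col]])) %>%
      mutate(rank = row_number())
    ggplot(df, aes(x = .data$rank, y = .data[[col]])) +
      geom_point(size = 0.8) +
      labs(x = "genome rank", y = ylab) +
      theme_classic()
  }
  scatter <- ggplot(stats, aes(x = .data$size_bp, y = .data$orf_count)) +
    geom_point(size = 0.8) +
    geom_smooth(method = "lm", formula = y ~ x, colour = "steelblue") +
    labs(x = "genome size (bp)", y = "predicted ORFs") +
    theme_classic()
  list(size_rank = ranked("size_bp", "genome size (bp)"),
       gc_rank = ranked("gc_percent", "G+C (%)"),
       orf_vs_size = scatter)
}

#' Bar chart of family sizes
#'
#' @param histogram tibble from [family_size_histogram()].
#' @return a ggplot object.
#' @export
plot_family_sizes <- function(histogram) {
  ggplot(histogram, aes(x = .data$size, y = .data$n_families)) +
    geom_col(fill = "grey30") +
    labs(x = "family size (members)", y = "families") +
    theme_classic()
}

#' Per-cluster spacer-hit classification bars
#'
#' @param classes tibble from [classify_hits()].
#' @return a ggplot object.
#' @export
plot_spacer_classification <- function(classes) {
  df <- classes %>%
    pivot_longer(c("hits_to_original_host", "hits_to_other_species"),
                 names_to = "class", values_to = "hits") %>%
    mutate(class = ifelse(.data$class == "hits_to_original_host",
                          "original host", "other species"))
  ggplot(df, aes(x = .data$cluster, y = .data$hits, fill = .data$class)) +
    geom_col(position = "dodge") +
    scale_fill_manual(values = c(`original host` = "grey20",
                                 `other species` = "indianred")) +
    labs(x = NULL, y = "spacer hits", fill = NULL) +
    theme_classic()
}
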