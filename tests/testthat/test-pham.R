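# Pairwise protein similarity and pham construction.

prot_tbl <- function(seqs, ids = NULL) {
  tibble::tibble(orf_id = ids %||% sprintf("orf%03d", seq_along(seqs)),
                 aa_seq = seqs)
}

test_that("identical proteins link; random proteins do not", {
  set.seed(31)
  p <- random_protein_str(100)
  links <- protein_pairwise(prot_tbl(c(p, p)))
  expect_equal(nrow(links), 1L)
  expect_equal(links$global_identity_pct, 100)
  expect_lt(links$local_evalue, 1e-50)

  r1 <- random_protein_str(100); r2 <- random_protein_str(100)
  expect_equal(nrow(protein_pairwise(prot_tbl(c(r1, r2)))), 0L)

  expect_error(protein_pairwise(prot_tbl(c("ACDEFB", "ACDEFG"))), "alphabet")
})

test_that("global identity and local score agree with brute-force DP", {
  set.seed(32)
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B62 <- e$BLOSUM62
  subfun <- function(x, y) B62[x, y]
  for (rep in 1:3) {
    a <- random_protein_str(80)
    b <- if (rep < 3) {
      # partially related: keep a conserved core
      paste0(random_protein_str(15), substr(a, 20, 70), random_protein_str(10))
    } else {
      random_protein_str(75)
    }
    links <- protein_pairwise(prot_tbl(c(a, b)), identity_threshold = 0,
                              evalue_threshold = Inf)
    sw <- oracle_sw(a, b, subfun, open = 11, ext = 1)
    expect_equal(links$local_score, sw$score)
    # global route: the optimal score is unique even when the optimal
    # path (hence identity) is not; identities from alternate optimal
    # paths can differ by a few columns of terminal-gap placement
    nw <- oracle_nw(a, b, open = 10, ext = 1, subfun = subfun)
    got <- phagecompare:::.nw_matrix_counts(
      a, b, phagecompare:::blosum62(),
      rownames(phagecompare:::blosum62()), 10, 1, TRUE)
    expect_equal(got[["score"]], nw$score)
    expect_lt(abs(links$global_identity_pct -
                    100 * nw$matches / nw$cols), 8)
  }
})

test_that("the 35% identity threshold is inclusive", {
  # 20 residues, 7 identities (35.0%), mismatches with positive BLOSUM62
  # scores so the optimal global alignment is gapless
  a <- "WWWWWWWKKKKKKKKKKKKK"
  b <- "WWWWWWWRRRRRRRRRRRRR"
  links <- protein_pairwise(prot_tbl(c(a, b)), identity_threshold = 35)
  expect_equal(nrow(links), 1L)
  expect_equal(links$global_identity_pct, 35)
  links2 <- protein_pairwise(prot_tbl(c(a, b)), identity_threshold = 35.1)
  expect_equal(nrow(links2), 0L)
})

test_that("single-linkage phams equal union-find components", {
  u <- sprintf("o%02d", 1:5)
  links <- tibble::tibble(orf_a = c("o01", "o02"), orf_b = c("o02", "o03"),
                          global_identity_pct = 50, local_score = 0,
                          local_evalue = 1)
  ph <- build_phams(links, u)
  expect_equal(ph$pham_id[ph$orf_id %in% c("o01", "o02", "o03")],
               rep(1L, 3))
  expect_equal(sort(unique(ph$pham_id)), 1:3)

  ph0 <- build_phams(links[0, ], u)
  expect_equal(ph0$pham_id, 1:5)

  set.seed(33)
  for (rep in 1:50) {
    n <- sample(5:25, 1)
    ids <- sprintf("x%03d", 1:n)
    n_edges <- sample(0:(2 * n), 1)
    edges <- matrix(sample(n, 2 * n_edges, replace = TRUE), ncol = 2)
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    lk <- tibble::tibble(orf_a = ids[edges[, 1]], orf_b = ids[edges[, 2]],
                         global_identity_pct = 99, local_score = 0,
                         local_evalue = 1)
    got <- build_phams(lk, ids)
    ref <- oracle_union_find(n, edges)
    # same partition: equal label co-membership
    expect_equal(outer(got$pham_id, got$pham_id, "=="),
                 outer(ref, ref, "=="), ignore_attr = TRUE)
  }
})

test_that("phams partition the ORF universe and are order-invariant", {
  sim <- simulate_genome_set(sim_config(seed = 35, n_clusters = 2,
                                        members_per_cluster = 3,
                                        n_singletons = 1,
                                        n_gene_modules = 8L))
  orfs <- call_orfs(sim$genomes)
  links <- protein_pairwise(orfs, prefilter_k = 4L)
  ph <- build_phams(links, orfs$orf_id)
  expect_setequal(ph$orf_id, orfs$orf_id)
  expect_equal(anyDuplicated(ph$orf_id), 0L)
  hist <- family_size_histogram(ph)
  expect_equal(sum(hist$size * hist$n_families), nrow(orfs))
  expect_equal(sum(hist$n_families), length(unique(ph$pham_id)))
  expect_equal(nrow(family_size_histogram(ph[0, ])), 0L)

  shuf <- orfs[sample(nrow(orfs)), ]
  ph2 <- build_phams(protein_pairwise(shuf, prefilter_k = 4L), shuf$orf_id)
  expect_equal(ph[order(ph$orf_id), ], ph2[order(ph2$orf_id), ],
               ignore_attr = TRUE)
})

test_that("stricter thresholds refine the pham partition", {
  sim <- simulate_genome_set(sim_config(seed = 36, n_clusters = 2,
                                        members_per_cluster = 3,
                                        n_singletons = 0,
                                        n_gene_modules = 6L))
  orfs <- call_orfs(sim$genomes)
  loose <- build_phams(protein_pairwise(orfs, identity_threshold = 35),
                       orfs$orf_id)
  strict <- build_phams(protein_pairwise(orfs, identity_threshold = 50),
                        orfs$orf_id)
  # every strict pham lies within one loose pham
  loose_of <- setNames(loose$pham_id, loose$orf_id)
  per_strict <- tapply(loose_of[strict$orf_id], strict$pham_id,
                       function(x) length(unique(x)))
  expect_true(all(per_strict == 1L))

  fams <- strict_families(orfs, min_members = 3L)
  sizes <- table(fams$pham_id)
  expect_true(all(sizes >= 3L))
})

test_that("the k-mer prefilter does not change the link set here", {
  sim <- simulate_genome_set(sim_config(seed = 37, n_clusters = 1,
                                        members_per_cluster = 3,
                                        n_singletons = 1,
                                        n_gene_modules = 5L))
  orfs <- call_orfs(sim$genomes)
  full <- protein_pairwise(orfs, prefilter_k = 0L)
  fast <- protein_pairwise(orfs, prefilter_k = 5L)
  key <- function(x) paste(pmin(x$orf_a, x$orf_b), pmax(x$orf_a, x$orf_b))
  expect_setequal(key(full), key(fast))
})
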