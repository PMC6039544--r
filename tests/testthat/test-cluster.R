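# Genome cluster / singleton assignment.

id_mat <- function(v, ids) {
  n <- length(ids)
  m <- matrix(v, n, n, dimnames = list(ids, ids))
  diag(m) <- 100
  structure(m, class = c("identity_matrix", "matrix"))
}

sh_mat <- function(v, ids) {
  n <- length(ids)
  m <- matrix(as.integer(v), n, n, dimnames = list(ids, ids))
  diag(m) <- 50L
  m
}

test_that("the three clustering criteria behave as specified", {
  ids3 <- c("a", "b", "c")
  asg <- assign_clusters(id_mat(50, ids3), sh_mat(25, ids3))
  expect_equal(asg$membership$cluster, rep("A", 3))

  # two genomes alone can never form a cluster
  ids2 <- c("a", "b")
  asg2 <- assign_clusters(id_mat(90, ids2), sh_mat(40, ids2))
  expect_equal(asg2$membership$cluster, rep("SINGLETON", 2))

  # thresholds are strict: identity 45.0 and 20 shared families fail
  asg3 <- assign_clusters(id_mat(45, ids3), sh_mat(25, ids3))
  expect_equal(asg3$membership$cluster, rep("SINGLETON", 3))
  asg4 <- assign_clusters(id_mat(50, ids3), sh_mat(20, ids3))
  expect_equal(asg4$membership$cluster, rep("SINGLETON", 3))
  asg5 <- assign_clusters(id_mat(45.1, ids3), sh_mat(21, ids3))
  expect_equal(asg5$membership$cluster, rep("A", 3))

  expect_error(assign_clusters(id_mat(50, ids3), sh_mat(25, ids3),
                               id_threshold = 120), "0, 100")
})

test_that("single linkage chains while complete linkage does not", {
  ids <- c("a", "b", "c", "d")
  idm <- id_mat(10, ids); shm <- sh_mat(0, ids)
  for (pair in list(c("a", "b"), c("b", "c"), c("c", "d"))) {
    idm[pair[1], pair[2]] <- idm[pair[2], pair[1]] <- 60
    shm[pair[1], pair[2]] <- shm[pair[2], pair[1]] <- 30L
  }
  single <- assign_clusters(idm, shm)
  expect_equal(single$membership$cluster, rep("A", 4))
  comp <- assign_clusters(idm, shm, linkage = "complete")
  expect_true(all(comp$membership$cluster == "SINGLETON"))

  # evidence records only qualifying within-cluster edges
  expect_equal(nrow(single$evidence), 3L)
  expect_true(all(single$evidence$identity_pct == 60))
})

test_that("tightening thresholds never grows the clustered set", {
  set.seed(41)
  ids <- sprintf("g%02d", 1:12)
  n <- length(ids)
  idm <- matrix(runif(n * n, 20, 80), n, n, dimnames = list(ids, ids))
  idm[lower.tri(idm)] <- t(idm)[lower.tri(idm)]
  diag(idm) <- 100
  idm <- structure(idm, class = c("identity_matrix", "matrix"))
  shm <- matrix(as.integer(sample(0:60, n * n, TRUE)), n, n,
                dimnames = list(ids, ids))
  shm[lower.tri(shm)] <- t(shm)[lower.tri(shm)]
  n_clustered <- function(id_thr, ph_thr) {
    asg <- assign_clusters(idm, shm, id_threshold = id_thr,
                           pham_threshold = ph_thr)
    sum(asg$membership$cluster != "SINGLETON")
  }
  for (thr in list(c(30, 10), c(45, 10), c(45, 20), c(60, 20), c(60, 40))) {
    expect_gte(n_clustered(thr[1], thr[2]), n_clustered(thr[1] + 10, thr[2]))
    expect_gte(n_clustered(thr[1], thr[2]), n_clustered(thr[1], thr[2] + 10))
  }
})

test_that("assignment is invariant under genome input order", {
  set.seed(42)
  sim <- simulate_genome_set(sim_config(seed = 13, n_clusters = 2,
                                        members_per_cluster = 3,
                                        n_singletons = 2,
                                        n_gene_modules = 10L))
  orfs <- call_orfs(sim$genomes)
  mem <- dplyr::inner_join(dplyr::select(orfs, orf_id, genome_id),
                           build_phams(protein_pairwise(orfs, prefilter_k = 5L),
                                       orfs$orf_id),
                           by = "orf_id")
  idm <- identity_matrix(sim$genomes)
  shm <- shared_pham_matrix(sim$genomes$genome_id, mem)
  asg <- assign_clusters(idm, shm)
  perm <- sample(nrow(sim$genomes))
  asg2 <- assign_clusters(
    structure(unclass(idm)[perm, perm], class = class(idm)), shm[perm, perm])
  m1 <- asg$membership[order(asg$membership$genome_id), ]
  m2 <- asg2$membership[order(asg2$membership$genome_id), ]
  expect_equal(m1, m2, ignore_attr = TRUE)
})

test_that("shared pham counting uses distinct families", {
  mem <- tibble::tibble(
    orf_id = sprintf("o%d", 1:7),
    genome_id = c("a", "a", "b", "b", "b", "a", "b"),
    pham_id = c(7L, 7L, 7L, 7L, 7L, 2L, 3L))
  expect_equal(shared_pham_count("a", "b", mem), 1L)
  expect_warning(expect_equal(shared_pham_count("a", "zz", mem), 0L),
                 "no ORFs")
  m <- shared_pham_matrix(c("a", "b"), mem)
  expect_equal(m["a", "b"], 1L)
  expect_equal(m["a", "a"], 2L)

  # identical complements share all families
  mem2 <- tibble::tibble(orf_id = sprintf("p%d", 1:60),
                         genome_id = rep(c("x", "y"), each = 30),
                         pham_id = rep(1:30, 2))
  expect_equal(shared_pham_count("x", "y", mem2), 30L)
  expect_equal(shared_pham_count("x", "y",
                                 dplyr::filter(mem2, pham_id > 15 |
                                                 genome_id == "x")), 15L)
})

test_that("cluster summaries aggregate members and flag multiple hosts", {
  ids <- c("a", "b", "c", "d")
  asg <- assign_clusters(id_mat(60, ids[1:3]) -> im3,
                         sh_mat(30, ids[1:3]))
  # add a singleton by hand
  asg$membership <- dplyr::bind_rows(asg$membership,
                                     tibble::tibble(genome_id = "d",
                                                    cluster = "SINGLETON"))
  stats <- tibble::tibble(genome_id = ids, size_bp = c(40000, 40000, 46000, 9000),
                          gc_percent = c(60, 62, 61, 40),
                          orf_count = c(50L, 50L, 56L, 10L),
                          orfs_per_kb = orf_count / (size_bp / 1000),
                          coding_fraction = 90)
  hosts <- tibble::tibble(genome_id = ids,
                          host_species = c("Pseudomonas aeruginosa",
                                           "Pseudomonas putida",
                                           "Pseudomonas aeruginosa", "x"))
  sm <- cluster_summary(asg, stats, hosts)
  expect_equal(nrow(sm), 1L)           # singleton excluded
  expect_equal(sm$n_members, 3L)
  expect_true(sm$multi_host)
  expect_equal(sm$size_bp_mean, 42000)
  expect_equal(sm$size_bp_sd, sd(c(40000, 40000, 46000)))

  sm2 <- cluster_summary(asg, stats,
                         dplyr::mutate(hosts,
                                       host_species = "Pseudomonas putida"))
  expect_false(sm2$multi_host)

  g <- glance(asg)
  expect_equal(g$n_singletons, 1L)
  expect_equal(g$n_clusters, 1L)
})
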