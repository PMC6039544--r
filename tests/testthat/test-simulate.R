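# The synthetic-data generator: determinism, calibration, ground truth.

test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- sim_config(seed = 71, n_clusters = 2, members_per_cluster = 2,
                    n_singletons = 1, n_gene_modules = 6L)
  s1 <- simulate_genome_set(cfg)
  s2 <- simulate_genome_set(cfg)
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(s1$truth$cluster_of, s2$truth$cluster_of)

  f1 <- simulate_codon_family(5, 50, 0.1, 0.5, seed = 72)
  f2 <- simulate_codon_family(5, 50, 0.1, 0.5, seed = 72)
  expect_identical(f1, f2)

  sp1 <- simulate_spacers(s1$genomes, n_spacers = 10, seed = 73)
  sp2 <- simulate_spacers(s1$genomes, n_spacers = 10, seed = 73)
  expect_identical(sp1, sp2)

  # and the session RNG stream is left untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_genome_set(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("identity 1 with no module swaps gives identical cluster members", {
  cfg <- sim_config(seed = 74, n_clusters = 1, members_per_cluster = 3,
                    n_singletons = 0, n_gene_modules = 5L,
                    within_cluster_identity = 1, module_swap_rate = 0)
  sim <- simulate_genome_set(cfg)
  expect_equal(length(unique(sim$genomes$sequence)), 1L)
})

test_that("realized member identity stays within 5 points of the target", {
  for (target in c(0.65, 0.8, 0.9)) {
    cfg <- sim_config(seed = 75 + round(100 * target), n_clusters = 1,
                      members_per_cluster = 3, n_singletons = 0,
                      n_gene_modules = 8L,
                      within_cluster_identity = target,
                      module_swap_rate = 0)
    sim <- simulate_genome_set(cfg)
    idm <- identity_matrix(sim$genomes)
    off <- unclass(idm)[upper.tri(idm)]
    expect_true(all(abs(off - 100 * target) <= 5),
                info = sprintf("target %.2f realized %s", target,
                               paste(round(off, 1), collapse = ", ")))
  }
})

test_that("simulated genomes are ORF-dense like real phage genomes", {
  sim <- simulate_genome_set(sim_config(seed = 77, n_clusters = 1,
                                        members_per_cluster = 2,
                                        n_singletons = 1,
                                        n_gene_modules = 12L))
  orfs <- call_orfs(sim$genomes)
  st <- genome_stats(sim$genomes, orfs)
  expect_true(all(st$orf_count >= 10))
  expect_true(all(st$coding_fraction > 70))
})

test_that("codon families respond to omega as dN/dS", {
  # omega 0: proteins frozen at the ancestor
  f0 <- simulate_codon_family(6, 100, divergence = 0.1, omega = 0, seed = 81)
  prot <- phagecompare:::translate11(unname(f0))
  expect_equal(length(unique(prot)), 1L)

  # ratio increases with omega (10 replicates averaged)
  mean_ratio <- function(om) {
    mean(sapply(1:10, function(k) {
      seqs <- simulate_codon_family(8, 200, divergence = 0.05, omega = om,
                                    seed = 820 + k)
      family_diversity(codon_alignment(seqs))$ratio
    }), na.rm = TRUE)
  }
  r <- sapply(c(0.1, 0.3, 1.0), mean_ratio)
  expect_true(all(diff(r) > 0))
  expect_lt(r[1], 0.25)
  expect_gt(r[3], 0.75)
})

test_that("planted spacers carry correct loci and labels", {
  sim <- simulate_genome_set(sim_config(seed = 83, n_clusters = 1,
                                        members_per_cluster = 2,
                                        n_singletons = 1,
                                        n_gene_modules = 8L))
  sp <- simulate_spacers(sim$genomes, n_spacers = 25, mutations = 0,
                         seed = 84, decoy_fraction = 0.2)
  expect_equal(nrow(sp$spacers), 30L)
  expect_true(all(sp$spacers$length >= 25 & sp$spacers$length <= 75))
  planted <- !is.na(sp$truth$genome_id)
  expect_equal(sum(planted), 25L)
  # excised sequence matches the recorded locus
  for (i in which(planted)[1:10]) {
    g <- sim$genomes[sim$genomes$genome_id == sp$truth$genome_id[i], ]
    len <- sp$spacers$length[i]
    cut <- substr(g$sequence, sp$truth$start[i] + 1, sp$truth$start[i] + len)
    if (sp$truth$strand[i] == "-") cut <- revcomp(cut)
    expect_identical(sp$spacers$sequence[i], cut)
  }
})

test_that("simulated inputs round-trip through the standard formats", {
  sim <- simulate_genome_set(sim_config(seed = 85, n_clusters = 1,
                                        members_per_cluster = 2,
                                        n_singletons = 0,
                                        n_gene_modules = 5L))
  sp <- simulate_spacers(sim$genomes, n_spacers = 5, seed = 86)
  dir <- withr::local_tempdir()
  write_simulated_inputs(sim, sp, dir)
  g <- read_genome_fasta(file.path(dir, "genomes.fasta"))
  expect_equal(g$sequence, sim$genomes$sequence)
  back <- read_spacers(file.path(dir, "spacers.fasta"),
                       file.path(dir, "spacers.tsv"))
  expect_equal(back$sequence, sp$spacers$sequence)
  expect_equal(back$source_species, sp$spacers$source_species)
})
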