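# FASTA/GenBank input, minimal ORF calling, per-genome statistics.

write_fasta_text <- function(lines) {
  p <- withr::local_tempfile(fileext = ".fasta",
                             .local_envir = parent.frame())
  writeLines(lines, p)
  p
}

test_that("FASTA reading normalises case, keeps ids unique and lengths right", {
  p <- write_fasta_text(c(">p1 a phage", "ACGTacgtACGTACGTACGT",
                          "ACGTACGTACGTACGTACGT", ">p2", "acgt"))
  g <- read_genome_fasta(p)
  expect_equal(nrow(g), 2L)
  expect_equal(g$length, c(40L, 4L))
  expect_equal(g$sequence[2], "ACGT")
  expect_equal(g$description[1], "a phage")

  dup <- write_fasta_text(c(">p1", "ACGT", ">p1", "TTTT"))
  expect_error(read_genome_fasta(dup), "duplicate")

  bad <- write_fasta_text(c(">p1", "ACRT"))
  expect_error(read_genome_fasta(bad), "outside")
  expect_equal(read_genome_fasta(bad, ambiguous = "to_n")$sequence, "ACNT")
})

make_genbank <- function(path, cds_lines, host = TRUE, seq_len = 120) {
  seq <- strsplit(random_dna_str(seq_len), "")[[1]]
  chunks <- sapply(seq(1, seq_len, 60), function(i) {
    paste(sapply(seq(i, min(i + 59, seq_len), 10), function(k) {
      paste(tolower(seq[k:min(k + 9, seq_len)]), collapse = "")
    }), collapse = " ")
  })
  writeLines(c(
    "LOCUS       TESTPHAGE        120 bp    DNA     linear   PHG 01-JAN-2020",
    "DEFINITION  Test phage, complete genome.",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    if (host) '                     /host="Pseudomonas aeruginosa PAO1"',
    cds_lines,
    "ORIGIN",
    sprintf("%9d %s", seq(1, seq_len, 60), chunks),
    "//"), path)
  path
}

test_that("GenBank CDS coordinates convert to 0-based half-open with strand", {
  p <- withr::local_tempfile(fileext = ".gbk")
  make_genbank(p, c("     CDS             complement(10..108)",
                    '                     /product="hypothetical protein"'))
  res <- read_genbank(p)
  expect_equal(res$genome$genome_id, "TESTPHAGE")
  expect_equal(res$genome$host_species, "Pseudomonas aeruginosa PAO1")
  expect_equal(res$orfs$start, 9L)
  expect_equal(res$orfs$end, 108L)
  expect_equal(res$orfs$strand, "-")

  p2 <- withr::local_tempfile(fileext = ".gbk")
  make_genbank(p2, "     CDS             join(1..30,61..90)", host = FALSE)
  res2 <- read_genbank(p2)
  expect_true(is.na(res2$genome$host_species))
  expect_equal(res2$orfs$start, 0L)
  expect_equal(res2$orfs$end, 90L)

  p3 <- withr::local_tempfile(fileext = ".gbk")
  make_genbank(p3, character(0))
  expect_equal(nrow(read_genbank(p3)$orfs), 0L)
})

# ORF-shaped construct: start codon, n sense codons, stop, inside a context
# with stops in all frames so no longer ORF swallows it.
flanked <- function(core) {
  paste0("ACCTAGCTAGCTAACTGGTAATAATAATAA", core, "ACCTAGCTAGCTAACTGGTAA")
}

test_that("ORF caller keeps >=300 bp ORFs anchored at the 5'-most start", {
  core303 <- paste(c("ATG", rep("GCT", 99), "TAA"), collapse = "")
  g <- genome_tbl(flanked(core303))
  orfs <- call_orfs(g)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$end - orfs$start, 303L)
  expect_equal(orfs$strand, "+")
  expect_equal(orfs$aa_seq, paste(c("M", rep("A", 99)), collapse = ""))

  core297 <- paste(c("ATG", rep("GCT", 97), "TAA"), collapse = "")
  expect_equal(nrow(call_orfs(genome_tbl(flanked(core297)))), 0L)

  # two in-frame ATGs: the ORF starts at the 5'-most
  core2 <- paste(c("ATG", rep("GCT", 5), "ATG", rep("GCT", 95), "TAA"),
                 collapse = "")
  orfs2 <- call_orfs(genome_tbl(flanked(core2)))
  expect_equal(nrow(orfs2), 1L)
  expect_equal(substr(orfs2$nt_seq, 1, 3), "ATG")
  expect_equal(orfs2$end - orfs2$start, nchar(core2))
})

test_that("ORF calls mirror exactly on the reverse complement", {
  set.seed(42)
  sim <- simulate_genome_set(sim_config(seed = 3, n_clusters = 1,
                                        members_per_cluster = 1,
                                        n_singletons = 0,
                                        n_gene_modules = 8L))
  g <- sim$genomes
  orfs <- call_orfs(g)
  grc <- g
  grc$sequence <- revcomp(g$sequence)
  orfs_rc <- call_orfs(grc)
  expect_equal(nrow(orfs), nrow(orfs_rc))
  L <- g$length
  mirrored <- tibble::tibble(start = L - orfs_rc$end, end = L - orfs_rc$start,
                             strand = ifelse(orfs_rc$strand == "+", "-", "+"))
  mirrored <- mirrored[order(mirrored$start), ]
  expect_equal(mirrored$start, orfs$start)
  expect_equal(mirrored$end, orfs$end)
  expect_equal(mirrored$strand, orfs$strand)
  # every called ORF translates back to its aa_seq plus a stop
  tr <- phagecompare:::translate11(orfs$nt_seq)
  expect_true(all(tr == paste0(orfs$aa_seq, "*")))
})

test_that("GFF3 round-trips ORF coordinates and strands", {
  sim <- simulate_genome_set(sim_config(seed = 4, n_clusters = 1,
                                        members_per_cluster = 1,
                                        n_singletons = 1,
                                        n_gene_modules = 6L))
  orfs <- call_orfs(sim$genomes)
  p <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(orfs, p)
  back <- read_gff3(p)
  expect_equal(back$start, orfs$start)
  expect_equal(back$end, orfs$end)
  expect_equal(back$strand, orfs$strand)
  expect_equal(back$orf_id, orfs$orf_id)
})

test_that("genome statistics follow their definitions", {
  g <- genome_tbl("GGCC")
  empty_orfs <- call_orfs(genome_tbl(strrep("T", 400)))[0, ]
  s <- genome_stats(g, empty_orfs)
  expect_equal(s$gc_percent, 100)
  expect_equal(s$orf_count, 0L)

  # arithmetic: 48 ORFs on 40 kb -> 1.2 per kb; union of overlapping ORFs
  g2 <- genome_tbl(strrep("A", 1000))
  o2 <- tibble::tibble(orf_id = c("a", "b"), genome_id = "g01",
                       start = c(100L, 100L), end = c(400L, 400L),
                       strand = "+", nt_seq = "", aa_seq = "")
  s2 <- genome_stats(g2, o2)
  expect_equal(s2$coding_fraction, 30)
  expect_equal(genome_stats(genome_tbl(strrep("ACGT", 10000)),
                            o2[0, ])$size_bp / 1000, 40)

  # gc on non-N bases only; invariant under reverse complement
  g3 <- genome_tbl("GGCANN")
  expect_equal(genome_stats(g3, o2[0, ])$gc_percent, 75)
  set.seed(1)
  r <- random_dna_str(500)
  expect_equal(genome_stats(genome_tbl(r), o2[0, ])$gc_percent,
               genome_stats(genome_tbl(revcomp(r)), o2[0, ])$gc_percent)
})
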