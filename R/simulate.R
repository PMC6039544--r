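# Synthetic phage genomes, codon families and CRISPR spacers with known
# ground truth, emulating a collection of related phage genomes: clusters of
# genomes diverged to a controlled identity with gene-module gain/loss,
# independent singletons, codon families evolved under a dN/dS ratio omega,
# and spacers excised from the simulated genomes.

# 21 bp with stop codons in all six reading frames and no ATG; placed in
# intergenic spacers so that called ORFs coincide with planted genes.
STOP_CASSETTE <- "ACCTAGCTAGCTAACTGGTAA"

HOST_POOL <- c("Pseudomonas aeruginosa", "Pseudomonas putida",
               "Pseudomonas fluorescens", "Pseudomonas syringae",
               "Pseudomonas protegens")

#' Simulation configuration
#'
#' Defaults describe a desk-scale phage collection: a handful of clusters of
#' related genomes plus unrelated singletons, with gene modules shared
#' within clusters and diverged by point substitutions.
#'
#' @param seed integer seed controlling all randomness.
#' @param n_clusters number of planted clusters.
#' @param members_per_cluster genomes per cluster.
#' @param n_singletons unrelated genomes.
#' @param n_gene_modules minimum gene modules per genome; per-cluster (and
#'   per-singleton) counts are drawn between this and 1.5x it, giving the
#'   genome-size spread real collections show.
#' @param gene_len_range gene length range in bp (rounded to codons).
#' @param intergenic_pad random intergenic padding in bp (added to a fixed
#'   stop cassette separating genes).
#' @param within_cluster_identity target pairwise nucleotide identity of
#'   cluster members, as a fraction.
#' @param module_swap_rate per-member probability that any given module is
#'   lost, and that a novel module is gained.
#' @param multi_host_fraction fraction of clusters whose members are split
#'   across two host species.
#' @param omega dN/dS ratio for codon families.
#' @param n_families,family_members,family_codons codon-family design.
#' @param family_divergence expected proposed changes per site per branch.
#' @param n_spacers,spacer_len_range,spacer_mutations,decoy_fraction spacer
#'   design.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_clusters = 5L, members_per_cluster = 3L,
                       n_singletons = 5L,
                       n_gene_modules = 36L,
                       gene_len_range = c(300L, 750L),
                       intergenic_pad = 40L,
                       within_cluster_identity = 0.75,
                       module_swap_rate = 0.06,
                       multi_host_fraction = 0.4,
                       omega = 0.1, n_families = 50L, family_members = 15L,
                       family_codons = 300L, family_divergence = 0.04,
                       n_spacers = 100L, spacer_len_range = c(25L, 75L),
                       spacer_mutations = 0L, decoy_fraction = 0) {
  cfg <- as.list(environment())
  if (cfg$within_cluster_identity <= 0 || cfg$within_cluster_identity > 1) {
    abort("`within_cluster_identity` must be in (0, 1].")
  }
  if (cfg$omega < 0) abort("`omega` must be >= 0.")
  structure(cfg, class = "sim_config")
}

# Random gene module: ATG + random sense codons + stop, length >= 300 bp.
random_gene <- function(len_range) {
  n_cod <- sample(seq(len_range[1] %/% 3L, len_range[2] %/% 3L), 1L)
  body <- sample(setdiff(sense_codons(), "ATG"), n_cod - 2L, replace = TRUE)
  paste(c("ATG", body, sample(STOP_CODONS, 1L)), collapse = "")
}

# Per-member substitution rate so that the *pairwise* identity of two
# independently mutated copies matches the target:
# identity = (1-r)^2 + r^2/3  (both positions mutated agree with prob 1/3).
member_mutation_rate <- function(target_identity) {
  f <- function(r) (1 - r)^2 + r^2 / 3 - target_identity
  if (target_identity >= 1) return(0)
  stats::uniroot(f, c(0, 0.75))$root
}

# Apply point substitutions to a module genome. `gene_mask` marks positions
# that must not mutate (start/stop codons, stop cassettes); `frame_start`
# maps gene-interior positions to their codon frame so substitutions that
# would create an in-frame stop are redrawn.
mutate_modular <- function(seq, rate, protect, gene_frame) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  cand <- which(!protect)
  n_mut <- stats::rbinom(1L, length(cand), rate)
  if (n_mut == 0L) return(seq)
  pos <- sample(cand, n_mut)
  for (p in pos) {
    alt <- setdiff(DNA_BASES, chars[p])
    if (!is.na(gene_frame[p])) {
      ok <- vapply(alt, function(b) {
        c0 <- p - gene_frame[p]
        cod <- chars[c0:(c0 + 2L)]
        cod[gene_frame[p] + 1L] <- b
        !(paste(cod, collapse = "") %in% STOP_CODONS)
      }, logical(1))
      alt <- alt[ok]
      if (!length(alt)) next
    }
    chars[p] <- sample(alt, 1L)
  }
  paste(chars, collapse = "")
}

#' Apply random point substitutions (and optionally short indels)
#'
#' General-purpose mutator for property checks: each position is substituted
#' with probability `rate`; with `indel_rate > 0`, short insertions or
#' deletions (1-6 bp) are additionally introduced at that per-position rate.
#'
#' @param seq DNA string.
#' @param rate per-position substitution probability.
#' @param indel_rate per-position indel probability.
#' @return mutated DNA string.
#' @export
mutate_sequence <- function(seq, rate, indel_rate = 0) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  hit <- stats::runif(n) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit],
                         function(b) sample(setdiff(DNA_BASES, b), 1L), "")
  }
  if (indel_rate > 0) {
    events <- which(stats::runif(n) < indel_rate)
    for (p in rev(events)) {
      len <- sample(1:6, 1L)
      if (stats::runif(1) < 0.5) {
        chars <- append(chars, sample(DNA_BASES, len, replace = TRUE),
                        after = p)
      } else {
        drop <- p:min(p + len - 1L, length(chars))
        chars <- chars[-drop]
      }
    }
  }
  paste(chars, collapse = "")
}

# One genome "part": an intergenic spacer (random pad + stop cassette +
# in-frame stops) or a gene module, with per-base bookkeeping for the
# mutator: `protect` marks bases that must not mutate (cassettes, in-frame
# stops, gene start/stop codons), `frame` maps gene-interior bases to their
# codon offset so stop-creating substitutions can be redrawn.
intergenic_part <- function(pad, terminal = FALSE) {
  fixed <- if (terminal) STOP_CASSETTE else paste0(STOP_CASSETTE, "TAATAATAA")
  list(seq = paste0(random_dna(pad), fixed),
       protect = c(rep(FALSE, pad), rep(TRUE, nchar(fixed))),
       frame = rep(NA_integer_, pad + nchar(fixed)),
       gene = FALSE)
}

gene_part <- function(len_range) {
  m <- random_gene(len_range)
  list(seq = m,
       protect = c(rep(TRUE, 3L), rep(FALSE, nchar(m) - 6L), rep(TRUE, 3L)),
       frame = (seq_len(nchar(m)) - 1L) %% 3L,
       gene = TRUE)
}

# Ancestor = alternating intergenic/gene parts plus a terminal intergenic.
ancestor_parts <- function(n_modules, len_range, pad) {
  parts <- list()
  for (i in seq_len(n_modules)) {
    parts <- c(parts, list(intergenic_part(pad)), list(gene_part(len_range)))
  }
  c(parts, list(intergenic_part(pad, terminal = TRUE)))
}

concat_parts <- function(parts) {
  list(seq = paste(map_chr(parts, "seq"), collapse = ""),
       protect = unlist(map(parts, "protect")),
       frame = unlist(map(parts, "frame")))
}

#' Simulate a genome collection with planted clusters
#'
#' Per cluster, an ancestor genome of ORF-shaped gene modules separated by
#' stop-codon-rich intergenic spacers is built; each member receives point
#' substitutions calibrated so that member pairs meet the target identity
#' (gene start/stop codons and intergenic stop cassettes are protected, and
#' substitutions creating in-frame stops are redrawn so planted genes stay
#' intact). Module gain/loss at `module_swap_rate` creates synteny breaks
#' and ORFans. Singletons are drawn independently. Host species are assigned
#' per cluster, a configurable fraction of clusters receiving two species.
#'
#' @param config a [sim_config()].
#' @return list with `genomes` (tibble), `hosts` (tibble `genome_id`,
#'   `host_species`) and `truth` (list: `cluster_of`, `module_of_gene`,
#'   `config`).
#' @export
simulate_genome_set <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    rate <- member_mutation_rate(config$within_cluster_identity)
    ids <- character(0); seqs <- character(0); hostv <- character(0)
    truth_cluster <- character(0)
    module_count <- function() {
      lo <- config$n_gene_modules
      hi <- max(lo, round(1.5 * lo))
      if (hi > lo) sample(seq(lo, hi), 1L) else lo
    }
    for (cl in seq_len(config$n_clusters)) {
      parts <- ancestor_parts(module_count(), config$gene_len_range,
                              config$intergenic_pad)
      gene_idx <- which(map_lgl(parts, "gene"))
      multi <- cl <= round(config$multi_host_fraction * config$n_clusters)
      h1 <- HOST_POOL[(cl - 1L) %% length(HOST_POOL) + 1L]
      h2 <- HOST_POOL[cl %% length(HOST_POOL) + 1L]
      for (mb in seq_len(config$members_per_cluster)) {
        mem <- parts
        drop <- gene_idx[stats::runif(length(gene_idx)) <
                           config$module_swap_rate]
        if (length(drop) >= length(gene_idx)) drop <- drop[-1L]
        if (length(drop)) mem <- mem[-drop]
        n_gain <- stats::rbinom(1L, length(gene_idx),
                                config$module_swap_rate)
        for (k in seq_len(n_gain)) {
          # insert a novel module after an existing gene (or at the start)
          # so genes always stay separated by an intergenic spacer
          cand <- c(0L, which(map_lgl(mem, "gene")))
          at <- cand[sample.int(length(cand), 1L)]
          mem <- append(mem, list(intergenic_part(config$intergenic_pad),
                                  gene_part(config$gene_len_range)),
                        after = at)
        }
        asm <- concat_parts(mem)
        seq <- mutate_modular(asm$seq, rate, asm$protect, asm$frame)
        gid <- sprintf("cluster%02d_m%02d", cl, mb)
        ids <- c(ids, gid); seqs <- c(seqs, seq)
        hostv <- c(hostv, if (multi && mb %% 2L == 0L) h2 else h1)
        truth_cluster <- c(truth_cluster, sprintf("cluster%02d", cl))
      }
    }
    for (sg in seq_len(config$n_singletons)) {
      asm <- concat_parts(ancestor_parts(module_count(),
                                         config$gene_len_range,
                                         config$intergenic_pad))
      gid <- sprintf("singleton%02d", sg)
      ids <- c(ids, gid); seqs <- c(seqs, asm$seq)
      hostv <- c(hostv, HOST_POOL[(sg - 1L) %% length(HOST_POOL) + 1L])
      truth_cluster <- c(truth_cluster, "SINGLETON")
    }
    genomes <- tibble(genome_id = ids, description = "simulated phage genome",
                      host_species = hostv, length = nchar(seqs),
                      sequence = seqs)
    list(genomes = genomes,
         hosts = tibble(genome_id = ids, host_species = hostv),
         truth = list(cluster_of = setNames(truth_cluster, ids),
                      config = config))
  })
}

#' Simulate a codon family under a dN/dS ratio omega
#'
#' A star phylogeny: from a random stop-free ancestor, each sequence
#' independently receives Poisson(`divergence` x sites) proposed single-
#' nucleotide changes at uniform random positions; synonymous proposals are
#' always accepted, non-synonymous proposals accepted with probability
#' `omega`, and proposals creating stop codons are rejected.
#'
#' @param n_seqs sequences in the family.
#' @param n_codons codons per sequence.
#' @param divergence expected proposed changes per site per branch (0, 0.5].
#' @param omega dN/dS acceptance probability for non-synonymous proposals.
#' @param seed integer seed.
#' @return named character vector of gap-free, equal-length coding sequences
#'   (attribute `omega` records the truth).
#' @export
simulate_codon_family <- function(n_seqs = 15L, n_codons = 300L,
                                  divergence = 0.04, omega = 1,
                                  seed = 1L) {
  if (omega < 0) abort("`omega` must be >= 0.")
  if (divergence <= 0 || divergence > 0.5) {
    abort("`divergence` must be in (0, 0.5].")
  }
  gcode <- genetic_code11()
  with_seed(seed, {
    anc <- sample(sense_codons(), n_codons, replace = TRUE)
    seqs <- character(n_seqs)
    for (s in seq_len(n_seqs)) {
      cods <- anc
      n_prop <- stats::rpois(1L, divergence * 3 * n_codons)
      for (k in seq_len(n_prop)) {
        p <- sample.int(3L * n_codons, 1L)
        ci <- (p - 1L) %/% 3L + 1L
        off <- (p - 1L) %% 3L + 1L
        ch <- strsplit(cods[ci], "")[[1]]
        b <- sample(setdiff(DNA_BASES, ch[off]), 1L)
        ch[off] <- b
        newc <- paste(ch, collapse = "")
        if (gcode[newc] == "*") next
        if (gcode[newc] == gcode[cods[ci]] || stats::runif(1) < omega) {
          cods[ci] <- newc
        }
      }
      seqs[s] <- paste(cods, collapse = "")
    }
    structure(setNames(seqs, sprintf("seq%02d", seq_len(n_seqs))),
              omega = omega)
  })
}

#' Simulate CRISPR spacers excised from genomes
#'
#' Spacers are cut from random loci and strands of the given genomes, each
#' receiving `mutations` random substitutions; their source species mimics
#' past infection records: most spacers are labelled with the host species
#' of the genome they came from, the rest with another species from the
#' pool. A `decoy_fraction` of additional spacers is drawn as random
#' sequence unrelated to any genome.
#'
#' @param genomes genome tibble with `host_species` populated.
#' @param n_spacers planted spacers.
#' @param len_range spacer length range in bp.
#' @param mutations substitutions per planted spacer.
#' @param seed integer seed.
#' @param decoy_fraction decoys as a fraction of `n_spacers`.
#' @param same_species_fraction fraction of planted spacers labelled with
#'   their genome's own host species.
#' @return list with `spacers` (tibble `spacer_id`, `source_species`,
#'   `length`, `sequence`) and `truth` (tibble `spacer_id`, `genome_id`,
#'   `start`, `strand`; decoys have `NA` loci).
#' @export
simulate_spacers <- function(genomes, n_spacers = 100L,
                             len_range = c(25L, 75L), mutations = 0L,
                             seed = 1L, decoy_fraction = 0,
                             same_species_fraction = 0.7) {
  if (!nrow(genomes)) abort("`genomes` must be non-empty.")
  with_seed(seed, {
    ids <- character(0); seqsv <- character(0); species <- character(0)
    t_gid <- character(0); t_start <- integer(0); t_strand <- character(0)
    for (k in seq_len(n_spacers)) {
      g <- sample.int(nrow(genomes), 1L)
      len <- sample(seq(len_range[1], len_range[2]), 1L)
      # draw a locus whose sequence occurs exactly once in the genome (on
      # either strand), as a real protospacer would; repeated loci (e.g.
      # shared intergenic motifs) would make the planted origin ambiguous
      for (try in 1:50) {
        start <- sample.int(genomes$length[g] - len + 1L, 1L) - 1L
        fwd <- substring(genomes$sequence[g], start + 1L, start + len)
        n_occ <- length(gregexpr(fwd, genomes$sequence[g], fixed = TRUE)[[1]]) +
          sum(gregexpr(revcomp(fwd), genomes$sequence[g],
                       fixed = TRUE)[[1]] > 0)
        if (n_occ == 1L) break
      }
      strand <- sample(c("+", "-"), 1L)
      sp <- if (strand == "-") revcomp(fwd) else fwd
      if (mutations > 0L) {
        ch <- strsplit(sp, "")[[1]]
        pos <- sample.int(len, min(mutations, len))
        for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
        sp <- paste(ch, collapse = "")
      }
      own <- genomes$host_species[g] %||% HOST_POOL[1]
      sp_species <- if (stats::runif(1) < same_species_fraction) own else
        sample(setdiff(HOST_POOL, own), 1L)
      ids <- c(ids, sprintf("spacer%03d", k))
      seqsv <- c(seqsv, sp); species <- c(species, sp_species)
      t_gid <- c(t_gid, genomes$genome_id[g])
      t_start <- c(t_start, start); t_strand <- c(t_strand, strand)
    }
    n_decoy <- round(decoy_fraction * n_spacers)
    for (k in seq_len(n_decoy)) {
      len <- sample(seq(len_range[1], len_range[2]), 1L)
      ids <- c(ids, sprintf("decoy%03d", k))
      seqsv <- c(seqsv, random_dna(len))
      species <- c(species, sample(HOST_POOL, 1L))
      t_gid <- c(t_gid, NA_character_)
      t_start <- c(t_start, NA_integer_); t_strand <- c(t_strand, NA_character_)
    }
    list(spacers = tibble(spacer_id = ids, source_species = species,
                          length = nchar(seqsv), sequence = seqsv),
         truth = tibble(spacer_id = ids, genome_id = t_gid,
                        start = t_start, strand = t_strand))
  })
}

#' Write a simulated dataset to pipeline input files
#'
#' Emits genomes FASTA, host TSV, spacer FASTA + sidecar TSV and a JSON
#' ground-truth file into a directory.
#'
#' @param sim result of [simulate_genome_set()].
#' @param spacers optional result of [simulate_spacers()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_inputs <- function(sim, spacers = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(sim$genomes, file.path(dir, "genomes.fasta"))
  write_tsv_with_header(sim$hosts, file.path(dir, "hosts.tsv"))
  truth <- list(cluster_of = as.list(sim$truth$cluster_of))
  if (!is.null(spacers)) {
    sp <- spacers$spacers
    write_genome_fasta(tibble(genome_id = sp$spacer_id, description = "",
                              sequence = sp$sequence),
                       file.path(dir, "spacers.fasta"))
    write_tsv_with_header(sp[, c("spacer_id", "source_species")],
                          file.path(dir, "spacers.tsv"))
    truth$spacer_loci <- spacers$truth
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
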