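# Genome input/output, minimal ORF calling and per-genome statistics.

#' Read genomes from a FASTA file
#'
#' Returns one row per record with the sequence upper-cased. The genome id is
#' the first whitespace-delimited token of the header; the remainder becomes
#' the description.
#'
#' @param path path to a nucleotide FASTA file.
#' @param ambiguous how to treat characters outside `{A,C,G,T,N}`:
#'   `"error"` rejects the file, `"to_n"` maps them to `N`.
#' @return a tibble with columns `genome_id`, `description`, `host_species`
#'   (`NA`, fill from metadata later), `length`, `sequence`.
#' @export
read_genome_fasta <- function(path, ambiguous = c("error", "to_n")) {
  ambiguous <- match.arg(ambiguous)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) abort("FASTA file contains no records.")
  headers <- names(recs)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 str_squish(sub("^\\S+\\s+", "", headers)), "")
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate genome id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- str_to_upper(as.character(recs))
  if (ambiguous == "to_n") {
    seqs <- gsub("[^ACGTN]", "N", seqs)
  } else {
    assert_dna(seqs, what = sprintf("FASTA file %s", basename(path)))
  }
  if (any(nchar(seqs) == 0L)) abort("empty sequence record in FASTA.")
  tibble(genome_id = ids, description = desc,
         host_species = NA_character_,
         length = nchar(seqs), sequence = unname(seqs))
}

#' Write genomes to a FASTA file
#'
#' @param genomes tibble with `genome_id`, `sequence` (and optionally
#'   `description`).
#' @param path output path.
#' @param width line width for wrapping.
#' @return the path, invisibly.
#' @export
write_genome_fasta <- function(genomes, path, width = 70L) {
  hdr <- genomes$genome_id
  if (!is.null(genomes$description)) {
    hdr <- ifelse(nzchar(genomes$description %||% ""),
                  paste(hdr, genomes$description), hdr)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(genomes))) {
    writeLines(paste0(">", hdr[i]), con)
    s <- genomes$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a GenBank flat file
#'
#' Minimal parser for single-record GenBank flat files: LOCUS/DEFINITION,
#' `source` qualifiers `/host` or `/lab_host`, `CDS` feature locations
#' (including `complement(...)` and `join(...)`), and the ORIGIN sequence.
#' GenBank 1-based inclusive coordinates are converted to 0-based half-open.
#'
#' @param path path to a GenBank flat file.
#' @return a list with elements `genome` (one-row tibble as in
#'   [read_genome_fasta()]) and `orfs` (tibble as in [call_orfs()]).
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- if (length(locus)) strsplit(str_squish(locus[1]), " ")[[1]][2] else
    tools::file_path_sans_ext(basename(path))
  defn <- grep("^DEFINITION", lines, value = TRUE)
  desc <- if (length(defn)) str_squish(sub("^DEFINITION", "", defn[1])) else ""

  origin_at <- grep("^ORIGIN", lines)
  if (!length(origin_at)) abort("GenBank file has no ORIGIN sequence.")
  seq_lines <- lines[(origin_at[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- str_to_upper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  seq <- gsub("[^ACGTN]", "N", seq)
  if (!nzchar(seq)) abort("GenBank ORIGIN sequence is empty.")

  feat_at <- grep("^FEATURES", lines)
  feat <- if (length(feat_at)) lines[(feat_at[1] + 1L):(origin_at[1] - 1L)]
          else character(0)
  host <- NA_character_
  hq <- grep('/(lab_)?host="', feat, value = TRUE)
  if (length(hq)) host <- sub('.*/(lab_)?host="([^"]*)".*', "\\2", hq[1])

  # collect CDS feature locations (location may continue on following lines)
  cds_idx <- grep("^\\s{5}CDS\\s", feat)
  starts <- integer(0); ends <- integer(0); strands <- character(0)
  for (i in cds_idx) {
    loc <- str_squish(sub("^\\s{5}CDS\\s+", "", feat[i]))
    j <- i + 1L
    while (j <= length(feat) && !grepl("^\\s{21}/", feat[j]) &&
           grepl("^\\s{21}\\S", feat[j]) && !grepl("^\\s{5}\\S", feat[j])) {
      loc <- paste0(loc, str_squish(feat[j]))
      j <- j + 1L
    }
    strand <- if (grepl("complement", loc)) "-" else "+"
    nums <- as.integer(unlist(regmatches(loc, gregexpr("[0-9]+", loc))))
    if (!length(nums)) abort(sprintf("unparseable CDS location: %s", loc))
    starts <- c(starts, min(nums) - 1L)   # 1-based incl -> 0-based half-open
    ends <- c(ends, max(nums))
    strands <- c(strands, strand)
  }
  genome <- tibble(genome_id = id, description = desc, host_species = host,
                   length = nchar(seq), sequence = seq)
  orfs <- orf_tibble(genome, starts, ends, strands, validate = FALSE)
  list(genome = genome, orfs = orfs)
}

# Build an OrfRecord tibble from coordinates on the forward axis.
orf_tibble <- function(genome, starts, ends, strands, validate = TRUE) {
  if (!length(starts)) {
    return(tibble(orf_id = character(0), genome_id = character(0),
                  start = integer(0), end = integer(0), strand = character(0),
                  nt_seq = character(0), aa_seq = character(0)))
  }
  ord <- order(starts, ends)
  starts <- starts[ord]; ends <- ends[ord]; strands <- strands[ord]
  nt_fwd <- substring(genome$sequence, starts + 1L, ends)
  nt <- ifelse(strands == "+", nt_fwd, revcomp(nt_fwd))
  aa <- rep(NA_character_, length(nt))
  ok <- (ends - starts) %% 3L == 0L & (ends - starts) >= 6L
  if (any(ok)) {
    tr <- translate11(nt[ok])
    aa[ok] <- sub("\\*$", "", tr)
  }
  tibble(orf_id = sprintf("%s_%03d", genome$genome_id, seq_along(starts)),
         genome_id = genome$genome_id,
         start = as.integer(starts), end = as.integer(ends),
         strand = strands, nt_seq = nt, aa_seq = aa)
}

#' Call open reading frames with minimal gene-calling rules
#'
#' Scans all six reading frames of each genome. Within every stop-to-stop
#' open stretch at most one ORF is emitted, anchored at the 5'-most start
#' codon, and only ORFs spanning at least `min_len` bases from start codon
#' through stop codon (inclusive) are kept. This mirrors the behaviour of
#' self-training phage gene callers that suppress short candidates, and
#' deliberately underestimates genes relative to curated annotation.
#'
#' Codons containing `N` never act as start or stop codons. Genomes are
#' treated as linear; ORFs wrapping a circular origin are not called.
#'
#' @param genomes tibble from [read_genome_fasta()] (any number of rows).
#' @param min_len minimum ORF length in bp, start through stop codon.
#' @param start_codons character vector of allowed start codons.
#' @return a tibble of ORFs: `orf_id`, `genome_id`, `start`, `end` (0-based
#'   half-open on the forward strand), `strand`, `nt_seq`, `aa_seq`; ordered
#'   by genome then ascending `start`.
#' @export
call_orfs <- function(genomes, min_len = 300L, start_codons = "ATG") {
  if (min_len < 3L || min_len %% 3L != 0L) {
    abort("`min_len` must be a positive multiple of 3.")
  }
  out <- vector("list", nrow(genomes))
  for (g in seq_len(nrow(genomes))) {
    row <- genomes[g, ]
    fwd <- scan_strand(row$sequence, min_len, start_codons)
    rc <- scan_strand(revcomp(row$sequence), min_len, start_codons)
    L <- row$length
    starts <- c(fwd$start, L - rc$end)
    ends <- c(fwd$end, L - rc$start)
    strands <- c(rep("+", nrow(fwd)), rep("-", nrow(rc)))
    out[[g]] <- orf_tibble(row, starts, ends, strands)
  }
  bind_rows(out)
}

# One strand, three frames; returns 0-based half-open coords on that strand.
scan_strand <- function(seq, min_len, start_codons) {
  n <- nchar(seq)
  res_start <- integer(0); res_end <- integer(0)
  for (f in 0:2) {
    n_cod <- (n - f) %/% 3L
    if (n_cod < min_len %/% 3L) next
    pos <- f + 1L + 3L * (seq_len(n_cod) - 1L)
    cods <- substring(seq, pos, pos + 2L)
    is_stop <- cods %in% STOP_CODONS            # N-codons never stop
    is_start <- cods %in% start_codons
    stop_idx <- which(is_stop)
    prev_stop <- 0L
    for (si in stop_idx) {
      lo <- prev_stop + 1L
      prev_stop <- si
      if (si - lo < 1L) next
      cand <- which(is_start[lo:(si - 1L)])
      if (!length(cand)) next
      a <- lo + cand[1L] - 1L                   # 5'-most start codon
      len <- (si - a + 1L) * 3L
      if (len < min_len) next
      res_start <- c(res_start, pos[a] - 1L)
      res_end <- c(res_end, pos[si] + 2L)
    }
  }
  tibble(start = res_start, end = res_end)
}

#' Per-genome summary statistics
#'
#' @param genomes genome tibble.
#' @param orfs ORF tibble covering those genomes (may be empty).
#' @return a tibble with `genome_id`, `size_bp`, `gc_percent` (over non-N
#'   bases), `orf_count`, `orfs_per_kb`, `coding_fraction` (% of bases in at
#'   least one ORF; overlaps counted once).
#' @export
genome_stats <- function(genomes, orfs) {
  stray <- setdiff(unique(orfs$genome_id), genomes$genome_id)
  if (length(stray)) {
    abort(sprintf("ORFs reference unknown genome(s): %s",
                  paste(stray, collapse = ", ")))
  }
  gc <- map_dbl(genomes$sequence, function(s) {
    tot <- nchar(s) - lengths(regmatches(s, gregexpr("N", s, fixed = TRUE)))
    gcn <- lengths(regmatches(s, gregexpr("[GC]", s)))
    if (tot == 0) return(NA_real_)
    100 * gcn / tot
  })
  per_genome <- function(gid, L) {
    o <- orfs[orfs$genome_id == gid, ]
    cov <- if (nrow(o)) {
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(start = o$start + 1L, end = o$end))))
    } else 0L
    c(n = nrow(o), cov = cov)
  }
  counts <- t(mapply(per_genome, genomes$genome_id, genomes$length))
  tibble(genome_id = genomes$genome_id,
         size_bp = genomes$length,
         gc_percent = gc,
         orf_count = as.integer(counts[, "n"]),
         orfs_per_kb = counts[, "n"] / (genomes$length / 1000),
         coding_fraction = 100 * counts[, "cov"] / genomes$length)
}

#' Write ORF calls as GFF3
#'
#' Emits one `CDS` line per ORF (source `phagecompare`), converting internal
#' 0-based half-open coordinates to 1-based inclusive GFF3 coordinates.
#'
#' @param orfs ORF tibble.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gff3 <- function(orfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(orfs)) {
    lines <- sprintf("%s\tphagecompare\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                     orfs$genome_id, orfs$start + 1L, orfs$end,
                     orfs$strand, orfs$orf_id)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read CDS features from a GFF3 file written by [write_gff3()]
#'
#' @param path GFF3 path.
#' @return tibble with `orf_id`, `genome_id`, `start`, `end`, `strand`
#'   (0-based half-open coordinates).
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(tibble(orf_id = character(0), genome_id = character(0),
                  start = integer(0), end = integer(0), strand = character(0)))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  tibble(orf_id = sub("^ID=", "", map_chr(f, 9)),
         genome_id = map_chr(f, 1),
         start = as.integer(map_chr(f, 4)) - 1L,
         end = as.integer(map_chr(f, 5)),
         strand = map_chr(f, 7))
}

#' Write the per-genome statistics table
#'
#' @param stats tibble from [genome_stats()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_genome_stats <- function(stats, path) {
  out <- stats
  out$gc_percent <- round(out$gc_percent, 2)
  out$orfs_per_kb <- round(out$orfs_per_kb, 3)
  out$coding_fraction <- round(out$coding_fraction, 2)
  write_tsv_with_header(out, path)
}
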