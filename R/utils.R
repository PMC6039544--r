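# Internal sequence and RNG helpers.

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over `{A,C,G,T,N}`.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Evaluate `code` with the session RNG seeded to `seed`, restoring the
# caller's RNG state afterwards so library code never perturbs user scripts.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Draw a random DNA string of length n from the current RNG stream.
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# All k-mers of a sequence as a character vector (positions 1..n-k+1).
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

assert_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    abort(sprintf("%s contains characters outside {A,C,G,T%s}.",
                  what, if (allow_n) ",N" else ""))
  }
  invisible(x)
}

# Genetic code 11 translation of in-frame nucleotide strings (no trailing
# stop removal; codons containing N translate to X).
translate11 <- function(x) {
  as.character(Biostrings::translate(
    Biostrings::DNAStringSet(x),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X"
  ))
}

split_codons <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3L == 0L)
  if (n == 0L) return(character(0))
  starts <- seq(1L, n, by = 3L)
  substring(seq, starts, starts + 2L)
}

# Header comment written at the top of every emitted table.
output_header <- function(params = NULL) {
  ver <- as.character(utils::packageVersion("phagecompare"))
  line <- sprintf("# phagecompare %s", ver)
  if (length(params)) {
    kv <- paste(names(params), unlist(params), sep = "=", collapse = " ")
    line <- paste0(line, " | ", kv)
  }
  line
}

write_tsv_with_header <- function(x, path, params = NULL) {
  writeLines(output_header(params), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, ...)
}
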