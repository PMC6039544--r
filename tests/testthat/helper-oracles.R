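# Independent brute-force oracles used to validate the package's fast
# implementations. These are written as plain, direct translations of the
# definitions and deliberately share no code with the package internals.

# ---- affine-gap global alignment (Needleman-Wunsch / Gotoh) ------------
# End gaps are penalized; a gap of length k costs open + k * ext; 'N' is a
# mismatch against everything. Returns score plus identity counts after
# stripping terminal-gap columns.
oracle_nw <- function(a, b, match = 1, mismatch = -1, open = 5, ext = 1,
                      subfun = NULL) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e15
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  pM <- matrix(0L, n + 1, m + 1); pX <- pM; pY <- pM
  M[1, 1] <- 0
  for (i in 2:(n + 1)) { X[i, 1] <- -open - (i - 1) * ext; pX[i, 1] <- if (i == 2) 1L else 2L }
  for (j in 2:(m + 1)) { Y[1, j] <- -open - (j - 1) * ext; pY[1, j] <- if (j == 2) 1L else 3L }
  sub_score <- subfun %||% function(x, y) {
    if (x == "N" || y == "N" || x != y) mismatch else match
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- sub_score(av[i - 1], bv[j - 1])
      cand <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      w <- which.max(cand); M[i, j] <- cand[w] + s; pM[i, j] <- w
      cand <- c(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                Y[i - 1, j] - open - ext)
      w <- which.max(cand); X[i, j] <- cand[w]; pX[i, j] <- w
      cand <- c(M[i, j - 1] - open - ext, X[i, j - 1] - open - ext,
                Y[i, j - 1] - ext)
      w <- which.max(cand); Y[i, j] <- cand[w]; pY[i, j] <- w
    }
  }
  fin <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  st <- which.max(fin)
  score <- fin[st]
  # traceback
  cols <- character(0); i <- n + 1; j <- m + 1
  while (i > 1 || j > 1) {
    if (st == 1L) {
      cols <- c(if (av[i - 1] == bv[j - 1] && av[i - 1] != "N") "M" else "m",
                cols)
      st <- pM[i, j]; i <- i - 1; j <- j - 1
    } else if (st == 2L) {
      cols <- c("g", cols); st <- pX[i, j]; i <- i - 1
    } else {
      cols <- c("g", cols); st <- pY[i, j]; j <- j - 1
    }
  }
  lo <- 1; hi <- length(cols)
  while (lo <= hi && cols[lo] == "g") lo <- lo + 1
  while (hi >= lo && cols[hi] == "g") hi <- hi - 1
  kept <- if (hi >= lo) cols[lo:hi] else character(0)
  list(score = score, matches = sum(kept == "M"), cols = length(kept))
}

# ---- Smith-Waterman local alignment ------------------------------------
# Generic substitution function; returns best score and 1-based subject
# (b) range of the best local alignment.
oracle_sw <- function(a, b, subfun, open, ext) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e15
  H <- matrix(0, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1); Y <- X
  pH <- matrix(0L, n + 1, m + 1)  # 0 start, 1 diag, 2 from X, 3 from Y
  pX <- matrix(0L, n + 1, m + 1)  # 1 open (from H), 2 extend (from X)
  pY <- matrix(0L, n + 1, m + 1)
  best <- 0; bi <- 0; bj <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      xo <- H[i - 1, j] - open - ext; xe <- X[i - 1, j] - ext
      if (xo >= xe) { X[i, j] <- xo; pX[i, j] <- 1L }
      else { X[i, j] <- xe; pX[i, j] <- 2L }
      yo <- H[i, j - 1] - open - ext; ye <- Y[i, j - 1] - ext
      if (yo >= ye) { Y[i, j] <- yo; pY[i, j] <- 1L }
      else { Y[i, j] <- ye; pY[i, j] <- 2L }
      dg <- H[i - 1, j - 1] + subfun(av[i - 1], bv[j - 1])
      h <- max(0, dg, X[i, j], Y[i, j])
      H[i, j] <- h
      pH[i, j] <- if (h == 0) 0L else if (h == dg) 1L else
        if (h == X[i, j]) 2L else 3L
      if (h > best) { best <- h; bi <- i; bj <- j }
    }
  }
  if (best <= 0) return(list(score = 0, s_start = NA, s_end = NA))
  i <- bi; j <- bj; state <- "H"
  repeat {
    if (state == "H") {
      if (pH[i, j] == 0L) break
      if (pH[i, j] == 1L) { i <- i - 1; j <- j - 1 }
      else if (pH[i, j] == 2L) state <- "X"
      else state <- "Y"
    } else if (state == "X") {
      state <- if (pX[i, j] == 1L) "H" else "X"
      i <- i - 1
    } else {
      state <- if (pY[i, j] == 1L) "H" else "Y"
      j <- j - 1
    }
  }
  list(score = best, s_start = j, s_end = bj - 1)
}

dna_subfun <- function(match = 1, mismatch = -1) {
  function(x, y) if (x == "N" || y == "N" || x != y) mismatch else match
}

# ---- dot-plot brute force ----------------------------------------------
oracle_dotplot <- function(a, b, w) {
  na <- nchar(a); nb <- nchar(b)
  is <- integer(0); js <- integer(0)
  for (i in 0:(na - w)) {
    wa <- substr(a, i + 1, i + w)
    if (grepl("N", wa)) next
    for (j in 0:(nb - w)) {
      wb <- substr(b, j + 1, j + w)
      if (grepl("N", wb)) next
      if (wa == wb) { is <- c(is, i); js <- c(js, j) }
    }
  }
  data.frame(i = is, j = js)
}

# ---- Nei-Gojobori oracles ----------------------------------------------
# Independent enumeration built on the Biostrings standard code restricted
# to sense codons (identical to code 11 over sense codons and stops).
oracle_code <- Biostrings::GENETIC_CODE
oracle_sense <- names(oracle_code)[oracle_code != "*"]

oracle_ng_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    ref <- substr(codon, pos, pos)
    for (b in bases[bases != ref]) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (oracle_code[[mut]] != "*" &&
          oracle_code[[mut]] == oracle_code[[codon]]) {
        s <- s + 1 / 3
      }
    }
  }
  c(s = s, n = 3 - s)
}

# Pathway-averaged synonymous/non-synonymous difference counts between two
# sense codons (stop-traversing pathways excluded; if all pathways are
# blocked, all orderings are used with stop steps counted non-synonymous).
oracle_ng_pair <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(sd = 0, nd = 0))
  perm_list <- if (length(pos) == 1) list(pos) else {
    pm <- function(v) {
      if (length(v) == 1) return(list(v))
      out <- list()
      for (i in seq_along(v)) {
        for (rest in pm(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
      }
      out
    }
    pm(pos)
  }
  walk <- function(ord, allow_stop) {
    cur <- c1; sd <- 0; nd <- 0
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (oracle_code[[nxt]] == "*") {
        if (!allow_stop) return(NULL)
        nd <- nd + 1
      } else if (oracle_code[[nxt]] == oracle_code[[cur]]) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- Filter(Negate(is.null), lapply(perm_list, walk, allow_stop = FALSE))
  if (!length(res)) res <- lapply(perm_list, walk, allow_stop = TRUE)
  colMeans(do.call(rbind, res))
}

oracle_pn_ps <- function(seq_a, seq_b) {
  ca <- substring(seq_a, seq(1, nchar(seq_a), 3), seq(3, nchar(seq_a), 3))
  cb <- substring(seq_b, seq(1, nchar(seq_b), 3), seq(3, nchar(seq_b), 3))
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (k in seq_along(ca)) {
    sa <- oracle_ng_sites(ca[k]); sb <- oracle_ng_sites(cb[k])
    S <- S + (sa[["s"]] + sb[["s"]]) / 2
    N <- N + (sa[["n"]] + sb[["n"]]) / 2
    d <- oracle_ng_pair(ca[k], cb[k])
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  c(pn = Nd / N, ps = Sd / S)
}

# ---- misc --------------------------------------------------------------
oracle_union_find <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein_str <- function(n) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

genome_tbl <- function(seqs, ids = NULL, hosts = NA_character_) {
  ids <- ids %||% sprintf("g%02d", seq_along(seqs))
  tibble::tibble(genome_id = ids, description = "",
                 host_species = hosts, length = nchar(seqs),
                 sequence = toupper(seqs))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

adjusted_rand <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab)); si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab))); n <- comb2(sum(tab))
  exp_idx <- si * sj / n
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}
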