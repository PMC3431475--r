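# Independent oracles used across the suite. Each reimplements the checked
# operation through a different route than the package (pure-R window
# comparison, PCRE lookaround regexes, combinatorial tail sums, quadratic
# dynamic programming) so agreement is informative.

# Exhaustive window scan: 0-based starts of all ungapped windows with
# identity >= threshold (X matches nothing). Brute force, no short cuts.
oracle_window_starts <- function(pep, prot, threshold = 1) {
  p <- strsplit(pep, "")[[1]]
  s <- strsplit(prot, "")[[1]]
  L <- length(p)
  if (length(s) < L) return(integer(0))
  starts <- integer(0)
  for (i in 0:(length(s) - L)) {
    w <- s[(i + 1):(i + L)]
    ident <- sum(p == w & p != "X" & w != "X") / L
    if (ident >= threshold - 1e-9) starts <- c(starts, i)
  }
  starts
}

# Exact substring starts (0-based), overlapping occurrences included.
oracle_substring_starts <- function(pep, prot) {
  hits <- integer(0)
  L <- nchar(pep)
  n <- nchar(prot)
  if (n < L) return(hits)
  for (i in 0:(n - L)) {
    if (substr(prot, i + 1, i + L) == pep) hits <- c(hits, i)
  }
  hits
}

# Per-bond cleavage oracle via PCRE lookaround regexes (the PeptideCutter
# specificity in regex form). A match at 1-based character i marks the bond
# after residue i. Valid only for X-free peptides (the regex character
# classes would treat X as an ordinary letter).
.regex_bonds <- function(s, rx) {
  m <- gregexpr(rx, s, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

oracle_cleavage_sites <- function(s, enzymes = c("trypsin", "pepsin_ph1.3",
                                                 "chymotrypsin_high")) {
  stopifnot(!grepl("X", s, fixed = TRUE))
  n <- nchar(s)
  sites <- integer(0)
  if ("trypsin" %in% enzymes) {
    main <- .regex_bonds(s, "([KR](?=[^P]))|((?<=W)K(?=P))|((?<=M)R(?=P))")
    exc <- .regex_bonds(
      s, "((?<=[CD])K(?=D))|((?<=C)K(?=[HY]))|((?<=C)R(?=K))|((?<=R)R(?=[HR]))"
    )
    sites <- c(sites, setdiff(main, exc))
  }
  if ("pepsin_ph1.3" %in% enzymes) {
    sites <- c(sites, .regex_bonds(
      s, "((?<=[^HKR][^P])[^R](?=[FL][^P]))|((?<=[^HKR][^P])[FL](?=\\w[^P]))"
    ))
  }
  if ("chymotrypsin_high" %in% enzymes) {
    sites <- c(sites, .regex_bonds(s, "([FY](?=[^P]))|(W(?=[^MP]))"))
  }
  sort(unique(sites[sites >= 1 & sites <= n - 1]))
}

# Intactness via the fragment view: the epitope survives iff its interval
# lies within a single digestion fragment.
oracle_intact_by_fragments <- function(seq, start0, end0, bonds) {
  frags <- allerscreen::fragments(seq, bonds)
  pos <- 0L
  for (f in frags) {
    if (start0 >= pos && end0 <= pos + nchar(f)) return(TRUE)
    pos <- pos + nchar(f)
  }
  FALSE
}

# Upper-tail hypergeometric probability by combinatorial tail summation.
oracle_hyper_tail <- function(k, n, K, N) {
  hi <- min(n, K)
  if (k > hi) return(0)
  sum(choose(K, k:hi) * choose(N - K, n - (k:hi))) / choose(N, n)
}

# Benjamini-Hochberg step-up by hand: sort, scale, enforce monotonicity from
# the largest rank down, cap at 1, realign to input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Quadratic-space Gotoh local alignment (affine gaps: a gap of length L
# costs open + L * ext) returning the optimal score.
oracle_sw_score <- function(a, b, mat, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1) # gap in a (consume b)
  F <- matrix(NEG, n + 1, m + 1) # gap in b (consume a)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0,
                     H[i - 1, j - 1] + mat[av[i - 1], bv[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Manual six-frame translation: per-codon lookup in the standard code table,
# N-containing codons -> X, stops -> *.
oracle_translate_frame <- function(nt, offset) {
  gc_tab <- Biostrings::GENETIC_CODE
  n <- nchar(nt) - offset + 1
  if (n < 3) return("")
  out <- character(0)
  i <- offset
  while (i + 2 <= nchar(nt)) {
    codon <- substr(nt, i, i + 2)
    out <- c(out, if (grepl("N", codon)) "X" else unname(gc_tab[codon]))
    i <- i + 3
  }
  paste(out, collapse = "")
}

oracle_six_frames <- function(nt) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  c("+1" = oracle_translate_frame(nt, 1),
    "+2" = oracle_translate_frame(nt, 2),
    "+3" = oracle_translate_frame(nt, 3),
    "-1" = oracle_translate_frame(rc, 1),
    "-2" = oracle_translate_frame(rc, 2),
    "-3" = oracle_translate_frame(rc, 3))
}

random_peptide <- function(len, alphabet = NULL) {
  if (is.null(alphabet)) {
    alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  }
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
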