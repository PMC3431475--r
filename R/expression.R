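FRAME_NAMES <- c("+1", "+2", "+3", "-1", "-2", "-3")

#' Translate a nucleotide read in all six reading frames
#'
#' Standard genetic code, both strands, three offsets each. Incomplete
#' trailing codons are dropped, stop codons render `*`, and any codon
#' containing `N` renders `X`. Frame `-k` is frame `+k` of the reverse
#' complement.
#'
#' @param est Nucleotide sequence (string or `DNAString`) over `ACGTN`.
#' @return Named character vector of six amino-acid strings
#'   (`+1`, `+2`, `+3`, `-1`, `-2`, `-3`).
#' @examples
#' translate_six_frames("ATGAAA")[c("+1", "-1")]
#' @export
translate_six_frames <- function(est) {
  s <- toupper(as.character(est))
  .check_alphabet(list(s), list("est"), "nucleotide")
  fwd <- Biostrings::DNAString(s)
  rev <- Biostrings::reverseComplement(fwd)
  one_frame <- function(strand_seq, offset) {
    n <- length(strand_seq) - offset + 1L
    if (n < 3L) return("")
    keep <- (n %/% 3L) * 3L
    codons <- Biostrings::subseq(strand_seq, offset, offset + keep - 1L)
    as.character(Biostrings::translate(codons, if.fuzzy.codon = "X",
                                       no.init.codon = TRUE))
  }
  out <- c(
    one_frame(fwd, 1L), one_frame(fwd, 2L), one_frame(fwd, 3L),
    one_frame(rev, 1L), one_frame(rev, 2L), one_frame(rev, 3L)
  )
  setNames(out, FRAME_NAMES)
}

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

.alignment_stats <- function(aln_pattern, aln_subject) {
  pa <- .chars(aln_pattern)
  sa <- .chars(aln_subject)
  cols <- length(pa)
  if (cols == 0L) {
    return(list(aligned_cols = 0L, identity = NA_real_))
  }
  # identical residue pairs / alignment columns; gap columns stay in the
  # denominator and X matches nothing, consistent with the scanner.
  matches <- sum(pa == sa & pa != "-" & pa != "X")
  list(aligned_cols = cols, identity = matches / cols)
}

#' Optimal local alignment of two peptides
#'
#' Smith-Waterman local alignment through
#' [Biostrings::pairwiseAlignment()] with BLAST-protein default scoring
#' (BLOSUM62, gap open 11, gap extend 1). Identity is identical residue
#' pairs over alignment columns, gap columns counted in the denominator.
#' When no positive-scoring local alignment exists the result is reported
#' as no hit (`aligned_cols = 0`, identity `NA`).
#'
#' @param query,target Non-empty peptide strings.
#' @param gap_open,gap_extend Affine gap penalties (non-negative).
#' @param matrix Substitution matrix name or matrix (default BLOSUM62).
#' @return List with `score`, `aligned_cols`, `identity`, `hit` flag and the
#'   aligned strings.
#' @export
local_align <- function(query, target, gap_open = 11, gap_extend = 1,
                        matrix = NULL) {
  stopifnot(nchar(query) > 0L, nchar(target) > 0L)
  if (is.null(matrix)) matrix <- .blosum62()
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(target),
    type = "local", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  pa <- as.character(Biostrings::alignedPattern(aln))
  sa <- as.character(Biostrings::alignedSubject(aln))
  stats <- .alignment_stats(pa, sa)
  sc <- Biostrings::score(aln)
  hit <- sc > 0 && stats$aligned_cols > 0L
  list(score = if (hit) sc else 0, aligned_cols = stats$aligned_cols,
       identity = stats$identity, hit = hit,
       aligned_query = pa, aligned_target = sa)
}

# Provable BLOSUM62 score floor for an acceptable hit: an alignment with C
# columns at identity >= theta has >= theta*C identical pairs (diagonal
# score >= 4) and <= (1-theta)*C mismatch/gap columns (each costing at most
# 12 = gap open 11 + extend 1), so its score is at least
# C * (4*theta - 12*(1-theta)). Optimal local score below that floor rules
# out any acceptable alignment.
.score_floor <- function(threshold, min_aligned) {
  max(1, min_aligned * (4 * threshold - 12 * (1 - threshold)))
}

# Vectorised core: align many frame translations against one protein and
# return per-frame score / columns / identity. A cheap score-only pass
# first; the full traceback (columns, identity) is computed only for frames
# whose optimal score reaches `score_floor`.
.align_frames <- function(frames, protein, gap_open = 11, gap_extend = 1,
                          score_floor = 1) {
  res <- data.frame(
    score = rep(0, length(frames)), aligned_cols = 0L,
    identity = NA_real_, stringsAsFactors = FALSE
  )
  keep <- which(nchar(frames) > 0L)
  if (length(keep) == 0L) return(res)
  subject <- Biostrings::AAString(protein)
  scores <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(frames[keep]), subject,
    type = "local", substitutionMatrix = .blosum62(),
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE
  )
  res$score[keep] <- pmax(scores, 0)
  full <- keep[scores >= score_floor]
  if (length(full) == 0L) return(res)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(frames[full]), subject,
    type = "local", substitutionMatrix = .blosum62(),
    gapOpening = gap_open, gapExtension = gap_extend
  )
  pa <- as.character(Biostrings::alignedPattern(aln))
  sa <- as.character(Biostrings::alignedSubject(aln))
  stats <- mapply(function(p, s) unlist(.alignment_stats(p, s)), pa, sa)
  res$aligned_cols[full] <- as.integer(stats["aligned_cols", ])
  res$identity[full] <- as.numeric(stats["identity", ])
  res
}

#' Test a protein for seed-expression support
#'
#' The tBlastN-like screen: every EST is translated in all six frames and
#' locally aligned against the protein; the protein counts as expressed when
#' some frame reaches the identity threshold over at least `min_aligned`
#' alignment columns. With the default `strict = FALSE`, "over 98 %
#' homology" is read inclusively (identity >= `threshold`); `strict = TRUE`
#' switches to strictly greater.
#'
#' @param protein Protein sequence (string or `AAString`).
#' @param ests Named `DNAStringSet` (or character vector) of EST reads.
#' @param threshold Identity acceptance threshold in `(0, 1]`.
#' @param min_aligned Minimum alignment columns for an acceptable hit.
#' @param strict Require identity strictly greater than `threshold`?
#' @param frames Optional precomputed frame table (see
#'   [est_frame_table()]), to amortise translation across proteins.
#' @return List with `expressed` flag and `best` (one-row data.frame:
#'   est_id, frame, score, aligned_cols, identity, accepted) or `NULL` when
#'   no alignment scored.
#' @export
is_expressed <- function(protein, ests, threshold = 0.98, min_aligned = 30,
                         strict = FALSE, frames = NULL) {
  stopifnot(threshold > 0, threshold <= 1)
  if (is.null(frames)) frames <- est_frame_table(ests)
  if (nrow(frames) == 0L) return(list(expressed = FALSE, best = NULL))
  stats <- .align_frames(frames$translation, as.character(protein),
                         score_floor = .score_floor(threshold, min_aligned))
  ok_id <- !is.na(stats$identity) &
    (if (strict) stats$identity > threshold + .ID_EPS
     else stats$identity >= threshold - .ID_EPS)
  accepted <- ok_id & stats$aligned_cols >= min_aligned & stats$score > 0
  scored <- which(stats$aligned_cols > 0L)
  if (length(scored) == 0L) return(list(expressed = FALSE, best = NULL))
  ord <- scored[order(-stats$identity[scored], -stats$aligned_cols[scored],
                      -stats$score[scored])]
  b <- ord[1L]
  best <- data.frame(
    est_id = frames$est_id[b], frame = frames$frame[b],
    score = stats$score[b], aligned_cols = stats$aligned_cols[b],
    identity = stats$identity[b], accepted = accepted[b],
    stringsAsFactors = FALSE
  )
  list(expressed = any(accepted), best = best)
}

#' Precompute the six-frame translations of an EST collection
#'
#' @param ests Named `DNAStringSet` or character vector.
#' @return `data.frame` with columns `est_id`, `frame`, `translation`.
#' @export
est_frame_table <- function(ests) {
  seqs <- .as_named_chr(ests)
  ids <- names(seqs)
  if (length(seqs) > 0L && is.null(ids)) {
    stop("ESTs must be named", call. = FALSE)
  }
  rows <- lapply(seq_along(seqs), function(i) {
    tr <- translate_six_frames(seqs[[i]])
    data.frame(est_id = ids[[i]], frame = names(tr), translation = unname(tr),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(est_id = character(0), frame = character(0),
                      translation = character(0), stringsAsFactors = FALSE)
  }
  out[nchar(out$translation) > 0L, , drop = FALSE]
}

#' Restrict a match catalog to seed-expressed proteins
#'
#' Applies [is_expressed()] to every candidate protein of the catalog and
#' retains only matches on expressed proteins. Per-protein expression
#' evidence (best hit) is recorded on the returned catalog.
#'
#' @param catalog A `match_catalog`.
#' @param proteome The named protein collection the catalog was built from.
#' @param ests Named `DNAStringSet` of EST reads (may be empty).
#' @param threshold,min_aligned,strict See [is_expressed()].
#' @return A `match_catalog` restricted to expressed proteins, with an
#'   `expression` data.frame (protein_id, est_id, frame, aligned_cols,
#'   identity, score, accepted) attached.
#' @export
filter_expressed <- function(catalog, proteome, ests, threshold = 0.98,
                             min_aligned = 30, strict = FALSE) {
  stopifnot(inherits(catalog, "match_catalog"))
  seqs <- .as_named_chr(proteome)
  prot_ids <- unique(catalog$matches$protein_id)
  frames <- est_frame_table(ests)
  evidence <- lapply(prot_ids, function(id) {
    r <- is_expressed(seqs[[id]], ests, threshold, min_aligned, strict,
                      frames = frames)
    if (is.null(r$best)) {
      data.frame(protein_id = id, est_id = NA_character_,
                 frame = NA_character_, aligned_cols = 0L,
                 identity = NA_real_, score = 0, accepted = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(protein_id = id, est_id = r$best$est_id,
                 frame = r$best$frame, aligned_cols = r$best$aligned_cols,
                 identity = r$best$identity, score = r$best$score,
                 accepted = r$expressed, stringsAsFactors = FALSE)
    }
  })
  evidence <- do.call(rbind, evidence)
  if (is.null(evidence)) {
    evidence <- data.frame(
      protein_id = character(0), est_id = character(0), frame = character(0),
      aligned_cols = integer(0), identity = numeric(0), score = numeric(0),
      accepted = logical(0), stringsAsFactors = FALSE
    )
  }
  expressed_ids <- evidence$protein_id[evidence$accepted]
  out <- catalog
  out$matches <- catalog$matches[
    catalog$matches$protein_id %in% expressed_ids, , drop = FALSE]
  rownames(out$matches) <- NULL
  out$expression <- evidence
  out
}
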