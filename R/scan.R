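#' Ungapped window identity between two equal-length peptides
#'
#' Positional identity in the epitope-conservancy sense: the fraction of
#' aligned positions carrying the same residue. `X` (unknown) matches
#' nothing, including another `X`.
#'
#' @param epitope,window Equal-length peptide strings.
#' @return Fraction in `[0, 1]`.
#' @examples
#' window_identity("IPEQ", "IPEG") # 0.75
#' @export
window_identity <- function(epitope, window) {
  a <- .chars(epitope)
  b <- .chars(window)
  if (length(a) != length(b)) {
    stop("window_identity requires equal-length peptides", call. = FALSE)
  }
  sum(a == b & a != "X" & b != "X") / length(a)
}

# Comparison slack for ratios of small integers stored as doubles.
.ID_EPS <- 1e-9

#' Find all windows of a protein matching an epitope
#'
#' Slides an ungapped window of epitope length along the protein and reports
#' every placement whose [window_identity()] reaches `min_identity`.
#' Overlapping matches are all reported, in ascending start order.
#' Coordinates are 0-based half-open on the protein.
#'
#' Candidate windows are located with [Biostrings::matchPattern()] at the
#' corresponding mismatch budget and then re-scored with the package's
#' X-aware identity, so `X` never produces a match even against a literal
#' `X`.
#'
#' @param peptide Epitope peptide (standard residues only).
#' @param protein Protein sequence (string or `AAString`).
#' @param min_identity Identity threshold in `(0, 1]`.
#' @return `data.frame` with columns `start`, `end` (0-based half-open) and
#'   `identity`.
#' @export
find_matches <- function(peptide, protein, min_identity = 1) {
  stopifnot(min_identity > 0, min_identity <= 1)
  protein <- as.character(protein)
  len <- nchar(peptide)
  empty <- data.frame(start = integer(0), end = integer(0),
                      identity = numeric(0))
  if (nchar(protein) < len) return(empty)
  max_mm <- floor((1 - min_identity + .ID_EPS) * len)
  hits <- Biostrings::matchPattern(peptide, Biostrings::AAString(protein),
                                   max.mismatch = max_mm)
  if (length(hits) == 0L) return(empty)
  # matchPattern may report candidates hanging off the sequence ends when
  # max.mismatch > 0; only fully contained windows are scored.
  starts1 <- BiocGenerics::start(hits)
  starts1 <- starts1[starts1 >= 1L & starts1 <= nchar(protein) - len + 1L]
  if (length(starts1) == 0L) return(empty)
  ident <- vapply(starts1, function(s) {
    window_identity(peptide, substr(protein, s, s + len - 1L))
  }, numeric(1))
  keep <- ident >= min_identity - .ID_EPS
  out <- data.frame(start = starts1[keep] - 1L,
                    end = starts1[keep] - 1L + len,
                    identity = ident[keep])
  out[order(out$start), , drop = FALSE]
}

#' Epitope conservancy across a proteome
#'
#' Fraction of proteome sequences containing at least one window matching the
#' epitope at or above the identity threshold, together with the matched
#' protein ids.
#'
#' @param peptide Epitope peptide.
#' @param proteome Named `AAStringSet` (or named character vector).
#' @param threshold Identity threshold in `(0, 1]`.
#' @return List with `fraction` and `protein_ids`.
#' @export
conservancy <- function(peptide, proteome, threshold = 1) {
  seqs <- .as_named_chr(proteome)
  if (length(seqs) == 0L) {
    stop("conservancy requires a non-empty proteome", call. = FALSE)
  }
  hit <- vapply(seqs, function(p) {
    nrow(find_matches(peptide, p, threshold)) > 0L
  }, logical(1))
  list(fraction = mean(hit), protein_ids = names(seqs)[hit])
}

#' Map a filtered epitope set onto a proteome
#'
#' The conservancy-mapping stage of the screen: every epitope is scanned
#' against every protein at the identity threshold (default 1.0, i.e. exact
#' peptide occurrence) and all matches are collected into a catalog. A
#' protein may carry epitopes of both disease classes; disease views are
#' non-exclusive.
#'
#' @param epitopes A filtered `epitope_set` (see [filter_epitopes()]).
#' @param proteome Named `AAStringSet` of protein sequences.
#' @param threshold Identity threshold in `(0, 1]`.
#' @param chromosome Optional character vector of chromosome labels aligned
#'   with the proteome; by default parsed from ids with
#'   [parse_chromosome()] and `chromosome_pattern`.
#' @param chromosome_pattern Pattern forwarded to [parse_chromosome()].
#' @return A `match_catalog`: list with `matches` (data.frame: epitope_id,
#'   peptide, disease, protein_id, chromosome, start, end, identity;
#'   coordinates 0-based half-open), `threshold`, `proteome_ids`,
#'   `chromosome` (named by protein id) and `n_proteins`.
#' @export
map_epitopes <- function(epitopes, proteome, threshold = 1,
                         chromosome = NULL,
                         chromosome_pattern = "^Bradi([0-9]+)g") {
  stopifnot(inherits(epitopes, "epitope_set"))
  seqs <- .as_named_chr(proteome)
  ids <- names(seqs)
  if (is.null(ids)) stop("proteome must be named", call. = FALSE)
  if (is.null(chromosome)) {
    chromosome <- parse_chromosome(ids, chromosome_pattern)
  }
  chromosome <- setNames(as.character(chromosome), ids)

  rows <- vector("list", nrow(epitopes))
  for (i in seq_len(nrow(epitopes))) {
    pep <- epitopes$peptide[i]
    per_prot <- lapply(seq_along(seqs), function(j) {
      m <- find_matches(pep, seqs[[j]], threshold)
      if (nrow(m) == 0L) return(NULL)
      data.frame(
        epitope_id = epitopes$id[i], peptide = pep,
        disease = epitopes$disease[i], protein_id = ids[[j]],
        chromosome = unname(chromosome[[j]]),
        start = m$start, end = m$end, identity = m$identity,
        stringsAsFactors = FALSE
      )
    })
    rows[[i]] <- do.call(rbind, per_prot)
  }
  matches <- do.call(rbind, rows)
  if (is.null(matches)) {
    matches <- data.frame(
      epitope_id = character(0), peptide = character(0),
      disease = character(0), protein_id = character(0),
      chromosome = character(0), start = integer(0), end = integer(0),
      identity = numeric(0), stringsAsFactors = FALSE
    )
  }
  rownames(matches) <- NULL
  structure(
    list(matches = matches, threshold = threshold, proteome_ids = ids,
         chromosome = chromosome, n_proteins = length(ids)),
    class = "match_catalog"
  )
}

#' @export
print.match_catalog <- function(x, ...) {
  cat(sprintf(
    "match_catalog: %d match(es) on %d of %d protein(s), threshold %.3g\n",
    nrow(x$matches), length(unique(x$matches$protein_id)), x$n_proteins,
    x$threshold
  ))
  invisible(x)
}

#' Candidate proteins of a match catalog
#'
#' Unique ids of proteins carrying at least one epitope match, optionally
#' restricted to one disease class. A protein counts once per class
#' regardless of match multiplicity.
#'
#' @param catalog A `match_catalog` (or `digest_catalog`).
#' @param disease `NULL` (union), `"CD"` or `"WA"`.
#' @return Character vector of protein ids.
#' @export
candidate_proteins <- function(catalog, disease = NULL) {
  m <- catalog$matches
  if (!is.null(disease)) m <- m[m$disease %in% disease, , drop = FALSE]
  sort(unique(m$protein_id))
}

#' Distinct epitope peptides found per chromosome and disease
#'
#' "Epitopes found" in the per-chromosome summary sense: the duplicate-free,
#' sorted list of distinct peptide strings with at least one match in at
#' least one protein of that chromosome. Proteins without a chromosome label
#' are excluded here (they remain in the catalog).
#'
#' @param catalog A `match_catalog`.
#' @return `data.frame` with columns `chromosome`, `disease`, `peptide`.
#' @export
epitopes_by_chromosome <- function(catalog) {
  m <- catalog$matches
  m <- m[!is.na(m$chromosome), , drop = FALSE]
  out <- unique(m[, c("chromosome", "disease", "peptide")])
  out <- out[order(out$chromosome, out$disease, out$peptide), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a match catalog as TSV
#'
#' Coordinates are rendered 1-based inclusive for display; the in-memory
#' catalog stays 0-based half-open.
#'
#' @param catalog A `match_catalog`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_matches <- function(catalog, path) {
  m <- catalog$matches
  out <- data.frame(
    epitope_id = m$epitope_id, peptide = m$peptide, disease = m$disease,
    protein_id = m$protein_id, chromosome = m$chromosome,
    start_1based = m$start + 1L, end_1based = m$end,
    identity = m$identity, stringsAsFactors = FALSE
  )
  .write_tsv(out, path)
}
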