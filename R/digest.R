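# Offsets of the Keil context positions relative to the bond index b
# (bond b sits between 1-based residues b and b+1, 0 < b < length).
.POS_OFFSETS <- c(P4 = -3L, P3 = -2L, P2 = -1L, P1 = 0L, P1p = 1L, P2p = 2L)

#' Predict cleavage sites on a peptide
#'
#' Evaluates every rule line of the selected enzymes on the P4..P2' context
#' of each internal bond and returns the union of predicted sites
#' (simultaneous digestion). Bond index `b` denotes the bond between
#' residues `b` and `b + 1` (1-based residues), i.e. `b` residues lie
#' N-terminal of the cut; valid bonds satisfy `0 < b < length`.
#'
#' Context positions that fall outside the sequence satisfy no residue
#' class: requirements referencing them fail and exceptions referencing them
#' cannot fire. `X` belongs to no residue class, so it neither enables nor
#' blocks cleavage.
#'
#' @param sequence Peptide string (length >= 2).
#' @param rules A `cleavage_ruleset` (default: the shipped three-enzyme set).
#' @param enzymes Optional subset of enzyme names to apply.
#' @return Sorted integer vector of bond indices.
#' @examples
#' rules <- load_cleavage_rules()
#' cleavage_sites("AKAA", rules, "trypsin") # 2
#' cleavage_sites("IPEQ", rules)            # none: no K/R/F/Y/W/L
#' @export
cleavage_sites <- function(sequence, rules = load_cleavage_rules(),
                           enzymes = NULL) {
  sequence <- as.character(sequence)
  n <- nchar(sequence)
  if (n < 2L) stop("cleavage_sites requires length >= 2", call. = FALSE)
  if (is.null(enzymes)) {
    enzymes <- names(rules)
  } else {
    unknown <- setdiff(enzymes, names(rules))
    if (length(unknown) > 0L) {
      stop("unknown enzyme(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  res <- .chars(sequence)
  bonds <- seq_len(n - 1L)

  # logical matrix: does residue at (bond + offset) belong to `class`?
  ctx_match <- function(class, offset) {
    idx <- bonds + offset
    ok <- idx >= 1L & idx <= n
    out <- logical(length(bonds))
    out[ok] <- res[idx[ok]] %in% class
    out
  }
  eval_context <- function(ctx) {
    hit <- rep(TRUE, length(bonds))
    for (p in names(ctx)) {
      hit <- hit & ctx_match(ctx[[p]], .POS_OFFSETS[[p]])
      if (!any(hit)) break
    }
    hit
  }

  cut <- rep(FALSE, length(bonds))
  for (enz in enzymes) {
    for (line in rules[[enz]]) {
      fires <- eval_context(line$require)
      for (exc in line$exceptions) {
        if (!any(fires)) break
        fires <- fires & !eval_context(exc)
      }
      cut <- cut | fires
    }
  }
  bonds[cut]
}

#' Split a peptide at cleavage bonds
#'
#' @param sequence Peptide string.
#' @param bonds Sorted bond indices strictly inside the sequence.
#' @return Character vector of `length(bonds) + 1` fragments whose
#'   concatenation reproduces the input exactly.
#' @examples
#' fragments("AKAA", 2L) # "AK" "AA"
#' @export
fragments <- function(sequence, bonds) {
  sequence <- as.character(sequence)
  n <- nchar(sequence)
  bonds <- sort(unique(as.integer(bonds)))
  if (length(bonds) > 0L && (min(bonds) < 1L || max(bonds) > n - 1L)) {
    stop("bond index out of range (must satisfy 0 < b < length)",
         call. = FALSE)
  }
  starts <- c(1L, bonds + 1L)
  ends <- c(bonds, n)
  substring(sequence, starts, ends)
}

#' Is an epitope match left intact by a set of cleavage bonds?
#'
#' An epitope occurrence on `[start, end)` (0-based half-open residue
#' coordinates) survives digestion iff no bond falls strictly inside the
#' interval. Bonds at the interval's own boundaries excise the epitope whole
#' and do not destroy it.
#'
#' @param start,end 0-based half-open residue coordinates of the match.
#' @param bonds Integer vector of bond indices (see [cleavage_sites()]).
#' @return Logical flag.
#' @export
epitope_intact <- function(start, end, bonds) {
  !any(bonds > start & bonds < end)
}

#' Digest all catalogued proteins and call epitope survival
#'
#' Runs the simultaneous digest once per catalogued protein, flags every
#' epitope match intact or cleaved, and derives the two result views used by
#' the per-chromosome summary: proteins counted digest-resistant for a
#' disease (>= 1 intact match of that disease) and epitope peptides intact
#' anywhere (>= 1 intact occurrence in >= 1 protein of a chromosome).
#'
#' @param catalog A `match_catalog` built over `proteome`.
#' @param proteome The same named protein collection the catalog was built
#'   from.
#' @param rules A `cleavage_ruleset`.
#' @param enzymes Optional enzyme subset.
#' @return A `digest_catalog`: list with `bonds` (named list of bond index
#'   vectors), `matches` (catalog matches plus an `intact` flag),
#'   `resistant` (data.frame protein_id/disease of digest-resistant
#'   proteins), the parent catalog's threshold and chromosome map.
#' @export
digest_catalog <- function(catalog, proteome, rules = load_cleavage_rules(),
                           enzymes = NULL) {
  stopifnot(inherits(catalog, "match_catalog"))
  seqs <- .as_named_chr(proteome)
  missing_ids <- setdiff(unique(catalog$matches$protein_id), names(seqs))
  if (length(missing_ids) > 0L) {
    stop("catalog refers to protein(s) absent from the proteome: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "), call. = FALSE)
  }
  prot_ids <- unique(catalog$matches$protein_id)
  bonds <- lapply(setNames(prot_ids, prot_ids), function(id) {
    cleavage_sites(seqs[[id]], rules, enzymes)
  })
  m <- catalog$matches
  m$intact <- vapply(seq_len(nrow(m)), function(i) {
    epitope_intact(m$start[i], m$end[i], bonds[[m$protein_id[i]]])
  }, logical(1))
  resistant <- unique(m[m$intact, c("protein_id", "disease"), drop = FALSE])
  rownames(resistant) <- NULL
  structure(
    list(bonds = bonds, matches = m, resistant = resistant,
         threshold = catalog$threshold, chromosome = catalog$chromosome,
         proteome_ids = catalog$proteome_ids,
         n_proteins = catalog$n_proteins),
    class = "digest_catalog"
  )
}

#' @export
print.digest_catalog <- function(x, ...) {
  cat(sprintf(
    "digest_catalog: %d protein(s) digested, %d/%d match(es) intact\n",
    length(x$bonds), sum(x$matches$intact), nrow(x$matches)
  ))
  invisible(x)
}

#' Export per-protein digestion results as TSV
#'
#' @param digest A `digest_catalog`.
#' @param path Output path for the per-protein bond table.
#' @param match_path Optional output path for the per-match intact table
#'   (1-based inclusive display coordinates).
#' @return `path`, invisibly.
#' @export
export_digest <- function(digest, path, match_path = NULL) {
  per_protein <- data.frame(
    protein_id = names(digest$bonds),
    bonds = vapply(digest$bonds, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  .write_tsv(per_protein, path)
  if (!is.null(match_path)) {
    m <- digest$matches
    out <- data.frame(
      epitope_id = m$epitope_id, peptide = m$peptide, disease = m$disease,
      protein_id = m$protein_id, chromosome = m$chromosome,
      start_1based = m$start + 1L, end_1based = m$end,
      identity = m$identity, intact = ifelse(m$intact, "TRUE", "FALSE"),
      stringsAsFactors = FALSE
    )
    .write_tsv(out, match_path)
  }
  invisible(path)
}
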