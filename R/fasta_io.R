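#' Read a FASTA file of protein or nucleotide sequences
#'
#' Thin wrapper around the Biostrings FASTA parser that normalises records for
#' the screening pipeline: sequences are uppercased, a single trailing stop
#' (`*`) is stripped from protein records, and every residue is validated
#' against the declared alphabet (20 standard amino acids plus `X` for
#' proteins; `ACGTN` for nucleotide reads). Record ids are the first
#' whitespace-delimited token of the header; the remainder is kept as the
#' description.
#'
#' @param path Path to a FASTA file (optionally gzip-compressed).
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return An [Biostrings::AAStringSet] (protein) or
#'   [Biostrings::DNAStringSet] (nucleotide) named by record id, with a
#'   `description` entry in its metadata columns.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">p1 demo", "MKQ", ">p2", "AASVPE"), f)
#' read_fasta(f, "protein")
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("malformed FASTA in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  headers <- names(raw)
  if (is.null(headers)) headers <- character(length(raw))
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(raw))
  if (alphabet == "protein") {
    seqs <- sub("\\*$", "", seqs)
  }
  if (any(nchar(seqs) == 0L) && length(seqs) > 0L) {
    stop("empty sequence for record(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "), call. = FALSE)
  }
  .check_alphabet(seqs, ids, alphabet)
  out <- if (alphabet == "protein") {
    Biostrings::AAStringSet(seqs)
  } else {
    Biostrings::DNAStringSet(seqs)
  }
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc)
  out
}

#' Write sequences to a FASTA file
#'
#' @param x A named `XStringSet` or named character vector of sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) {
    x <- Biostrings::BStringSet(x)
  }
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Extract chromosome labels from sequence identifiers
#'
#' Gene identifiers in Brachypodium-style protein databases encode the
#' chromosome (e.g. `Bradi3g12345` sits on chromosome 3). The label is pulled
#' out with a configurable regular expression holding exactly one capture
#' group; identifiers that do not match get `NA` and are excluded from
#' per-chromosome summaries while remaining in the match catalogs.
#'
#' @param ids Character vector of sequence identifiers.
#' @param pattern Regular expression with one capture group for the label.
#' @return Character vector of labels, `NA` where the pattern does not match.
#' @examples
#' parse_chromosome(c("Bradi3g12345", "scaffold_12"))
#' @export
parse_chromosome <- function(ids, pattern = "^Bradi([0-9]+)g") {
  m <- regexec(pattern, ids)
  vapply(regmatches(ids, m), function(g) {
    if (length(g) >= 2L) g[[2L]] else NA_character_
  }, character(1))
}

#' Override chromosome labels from a GFF3 file
#'
#' Consults only the `seqid` column and a single attribute (default `ID`) of
#' gene-bearing lines; all other GFF3 semantics are ignored. Where the GFF3
#' names an id, its seqid replaces the pattern-derived label.
#'
#' @param ids Identifiers to label.
#' @param gff_path Path to a GFF3 file.
#' @param attribute Attribute key carrying the identifier.
#' @param pattern Fallback pattern passed to [parse_chromosome()].
#' @return Character vector of labels aligned with `ids`.
#' @export
chromosome_from_gff <- function(ids, gff_path, attribute = "ID",
                                pattern = "^Bradi([0-9]+)g") {
  lines <- readLines(gff_path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  fields <- fields[lengths(fields) >= 9L]
  seqid <- vapply(fields, `[[`, character(1), 1L)
  attrs <- vapply(fields, `[[`, character(1), 9L)
  rx <- paste0("(?:^|;)", attribute, "=([^;]+)")
  mm <- regexec(rx, attrs)
  gff_id <- vapply(regmatches(attrs, mm), function(g) {
    if (length(g) >= 2L) g[[2L]] else NA_character_
  }, character(1))
  lookup <- setNames(seqid, gff_id)
  out <- parse_chromosome(ids, pattern)
  hit <- ids %in% names(lookup)
  out[hit] <- unname(lookup[ids[hit]])
  out
}
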