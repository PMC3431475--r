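#' @keywords internal
"_PACKAGE"

#' @importFrom stats phyper p.adjust setNames rbinom runif
#' @importFrom utils read.delim write.table data
NULL

# The 20 standard amino acids. X is admitted in protein sequences as "unknown"
# but matches no residue class anywhere downstream (scanning, digestion).
AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)
AA_VALID <- c(AA_STANDARD, "X")
NT_VALID <- c("A", "C", "G", "T", "N")

.check_alphabet <- function(seqs, ids, alphabet) {
  valid <- if (alphabet == "protein") AA_VALID else NT_VALID
  for (i in seq_along(seqs)) {
    letters_i <- unique(strsplit(seqs[[i]], "")[[1]])
    bad <- setdiff(letters_i, valid)
    if (length(bad) > 0L) {
      stop(sprintf(
        "record '%s': illegal %s residue(s): %s",
        ids[[i]], alphabet, paste(bad, collapse = ", ")
      ), call. = FALSE)
    }
  }
  invisible(TRUE)
}

.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# as.character() drops names from plain character vectors; sequence
# collections are name-keyed throughout, so coerce with names preserved.
.as_named_chr <- function(x) {
  s <- as.character(x)
  names(s) <- names(x)
  s
}

# Locale-independent TSV writer: fixed column order, '\n' endings, '.' decimal.
.write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(
    paste(colnames(df), collapse = "\t"),
    if (nrow(df) > 0L) {
      do.call(paste, c(lapply(df, function(col) {
        if (is.numeric(col)) {
          vapply(col, function(v) {
            if (is.na(v)) "NA" else format(v, scientific = FALSE, trim = TRUE)
          }, character(1))
        } else {
          as.character(col)
        }
      }), sep = "\t"))
    }
  )
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
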