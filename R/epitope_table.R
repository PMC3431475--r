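DISEASE_ALIASES <- c(
  "cd" = "CD", "celiac" = "CD", "celiac disease" = "CD",
  "coeliac" = "CD", "coeliac disease" = "CD",
  "wa" = "WA", "wheat allergy" = "WA", "allergy" = "WA"
)

EPITOPE_COLUMNS <- c(
  "id", "peptide", "disease", "host", "is_pollen", "is_linear",
  "source_protein", "source_species"
)

.parse_flag <- function(x, column) {
  key <- tolower(trimws(as.character(x)))
  map <- c("true" = TRUE, "t" = TRUE, "1" = TRUE, "yes" = TRUE,
           "false" = FALSE, "f" = FALSE, "0" = FALSE, "no" = FALSE)
  out <- map[key]
  if (anyNA(out)) {
    stop(sprintf("column '%s': unparseable flag value(s): %s", column,
                 paste(unique(key[is.na(out)]), collapse = ", ")),
         call. = FALSE)
  }
  unname(out)
}

#' Read a table of linear disease epitopes
#'
#' Loads the tab-separated epitope table used throughout the screen. The
#' dialect is fixed: tab-separated, UTF-8, `#` comment lines skipped, header
#' row naming the seven descriptive fields plus the id. Disease labels are
#' normalised to the two classes `CD` (celiac disease) and `WA` (wheat
#' allergy) through a small alias table (`"celiac disease"` parses to `CD`,
#' etc.). All rows are loaded unfiltered; inclusion criteria are applied
#' separately by [filter_epitopes()]. Duplicate peptides are allowed - the
#' same peptide may be reported under both diseases.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` of class `epitope_set` with columns
#'   `r paste(EPITOPE_COLUMNS, collapse = ", ")`.
#' @export
read_epitope_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   colClasses = "character", fileEncoding = "UTF-8",
                   check.names = FALSE)
  missing_cols <- setdiff(EPITOPE_COLUMNS, colnames(df))
  if (length(missing_cols) > 0L) {
    stop("epitope table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, EPITOPE_COLUMNS, drop = FALSE]
  as_epitope_set(
    id = df$id, peptide = df$peptide, disease = df$disease, host = df$host,
    is_pollen = .parse_flag(df$is_pollen, "is_pollen"),
    is_linear = .parse_flag(df$is_linear, "is_linear"),
    source_protein = df$source_protein, source_species = df$source_species
  )
}

#' Construct a validated epitope set
#'
#' @param id,peptide,disease,host,source_protein,source_species Character
#'   vectors of equal length.
#' @param is_pollen,is_linear Logical vectors.
#' @return A `data.frame` of class `epitope_set`.
#' @export
as_epitope_set <- function(id, peptide, disease, host,
                           is_pollen, is_linear,
                           source_protein = "", source_species = "") {
  peptide <- toupper(trimws(peptide))
  disease_norm <- DISEASE_ALIASES[tolower(trimws(disease))]
  if (anyNA(disease_norm)) {
    bad <- which(is.na(disease_norm))
    stop(sprintf("unparseable disease value '%s' in row %d",
                 disease[bad[1L]], bad[1L]), call. = FALSE)
  }
  bad_len <- which(nchar(peptide) < 2L)
  if (length(bad_len) > 0L) {
    stop(sprintf("row %d: epitope peptide must have length >= 2", bad_len[1L]),
         call. = FALSE)
  }
  for (i in seq_along(peptide)) {
    bad <- setdiff(unique(.chars(peptide[i])), AA_STANDARD)
    if (length(bad) > 0L) {
      stop(sprintf(
        "row %d (id '%s'): peptide contains non-standard residue(s): %s",
        i, id[i], paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  if (anyDuplicated(id)) {
    stop("duplicate epitope id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    id = as.character(id), peptide = peptide,
    disease = unname(disease_norm), host = as.character(host),
    is_pollen = as.logical(is_pollen), is_linear = as.logical(is_linear),
    source_protein = as.character(source_protein),
    source_species = as.character(source_species),
    stringsAsFactors = FALSE
  )
  class(out) <- c("epitope_set", "data.frame")
  out
}

#' Write an epitope set back to TSV
#'
#' Inverse of [read_epitope_table()]; round-trips all fields bit-stably.
#'
#' @param epitopes An `epitope_set`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_epitope_table <- function(epitopes, path) {
  df <- as.data.frame(epitopes)
  df$is_pollen <- ifelse(df$is_pollen, "TRUE", "FALSE")
  df$is_linear <- ifelse(df$is_linear, "TRUE", "FALSE")
  .write_tsv(df, path)
}

#' Apply the study's epitope inclusion criteria
#'
#' Keeps epitopes whose host matches (case-insensitively), that are not
#' pollen allergens (when `exclude_pollen`), that are linear (when
#' `linear_only`), and whose disease class is requested. Defaults encode the
#' screen's criteria: human host, pollen allergens excluded, linear epitopes
#' only, both celiac disease and wheat allergy. Input order is preserved.
#'
#' @param epitopes An `epitope_set`.
#' @param host Host organism to retain.
#' @param exclude_pollen Drop pollen-allergen records?
#' @param linear_only Keep only linear epitopes?
#' @param diseases Non-empty subset of `c("CD", "WA")`.
#' @return The filtered `epitope_set`.
#' @export
filter_epitopes <- function(epitopes, host = "Homo sapiens",
                            exclude_pollen = TRUE, linear_only = TRUE,
                            diseases = c("CD", "WA")) {
  stopifnot(inherits(epitopes, "epitope_set"))
  if (length(diseases) == 0L || !all(diseases %in% c("CD", "WA"))) {
    stop("diseases must be a non-empty subset of c('CD', 'WA')",
         call. = FALSE)
  }
  keep <- tolower(trimws(epitopes$host)) == tolower(trimws(host)) &
    epitopes$disease %in% diseases
  if (exclude_pollen) keep <- keep & !epitopes$is_pollen
  if (linear_only) keep <- keep & epitopes$is_linear
  out <- epitopes[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("epitope_set", "data.frame")
  out
}
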