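#' Round half away from zero
#'
#' Commercial rounding at a fixed number of decimal places (`round()` in R
#' rounds half to even; printed report percentages use half-away-from-zero).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @examples
#' round_half_away(20.96, 0) # 21
#' @export
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

.summary_row_template <- function() {
  data.frame(
    disease = character(0), chromosome = character(0),
    n_proteins = integer(0), epitopes = character(0),
    n_resistant = integer(0), intact_epitopes = character(0),
    stringsAsFactors = FALSE
  )
}

#' Per-chromosome summary of candidates and digestion survivors
#'
#' Builds the screen's central result table: for every (chromosome, disease)
#' cell, the number of candidate proteins, the duplicate-free sorted list of
#' distinct epitope peptides found, the number of proteins still carrying at
#' least one intact epitope of that disease after digestion, and the list of
#' epitopes intact anywhere on that chromosome. Proteins without a
#' chromosome label are excluded from the rows and reported in the
#' `unlocalized` footnote count. A protein carrying epitopes of both
#' diseases is counted once in each disease block; the union candidate
#' count deduplicates across diseases.
#'
#' @param catalog A `match_catalog` (the undigested view).
#' @param digest The `digest_catalog` built over the same catalog.
#' @return A `summary_table`: list with `rows`, `totals`, `union_candidates`,
#'   `union_resistant`, `unlocalized` and `threshold`.
#' @export
per_chromosome_summary <- function(catalog, digest) {
  stopifnot(inherits(catalog, "match_catalog"),
            inherits(digest, "digest_catalog"))
  if (!identical(catalog$proteome_ids, digest$proteome_ids)) {
    stop("catalog and digest were built over different proteomes",
         call. = FALSE)
  }
  m <- digest$matches
  loc <- m[!is.na(m$chromosome), , drop = FALSE]
  unlocalized <- length(unique(m$protein_id[is.na(m$chromosome)]))

  diseases <- sort(unique(m$disease))
  chromosomes <- sort(unique(loc$chromosome))
  rows <- .summary_row_template()
  for (d in diseases) {
    for (ch in chromosomes) {
      cell <- loc[loc$disease == d & loc$chromosome == ch, , drop = FALSE]
      if (nrow(cell) == 0L) next
      rows <- rbind(rows, data.frame(
        disease = d, chromosome = ch,
        n_proteins = length(unique(cell$protein_id)),
        epitopes = paste(sort(unique(cell$peptide)), collapse = ","),
        n_resistant = length(unique(cell$protein_id[cell$intact])),
        intact_epitopes = paste(sort(unique(cell$peptide[cell$intact])),
                                collapse = ","),
        stringsAsFactors = FALSE
      ))
    }
  }
  totals <- do.call(rbind, lapply(diseases, function(d) {
    sub <- loc[loc$disease == d, , drop = FALSE]
    data.frame(
      disease = d,
      n_proteins = length(unique(sub$protein_id)),
      n_resistant = length(unique(sub$protein_id[sub$intact])),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(totals)) {
    totals <- data.frame(disease = character(0), n_proteins = integer(0),
                         n_resistant = integer(0), stringsAsFactors = FALSE)
  }
  structure(
    list(rows = rows, totals = totals,
         union_candidates = length(unique(loc$protein_id)),
         union_resistant = length(unique(loc$protein_id[loc$intact])),
         unlocalized = unlocalized, threshold = catalog$threshold),
    class = "summary_table"
  )
}

#' Build a summary table directly from printed counts
#'
#' Reconstructs a `summary_table` from externally reported per-chromosome
#' protein counts (e.g. a published distribution table), so the percentage
#' arithmetic can be applied to them. Epitope lists are left empty.
#'
#' @param counts Named list: one entry per disease (`CD`, `WA`), each a
#'   data.frame with columns `chromosome`, `n_proteins`, `n_resistant`.
#' @param union_candidates Total number of distinct candidate proteins
#'   across diseases (overlap allowed, so it may be less than the sum).
#' @return A `summary_table`.
#' @export
summary_from_counts <- function(counts, union_candidates = NA_integer_) {
  rows <- .summary_row_template()
  for (d in names(counts)) {
    df <- counts[[d]]
    stopifnot(all(c("chromosome", "n_proteins", "n_resistant") %in%
                    colnames(df)))
    rows <- rbind(rows, data.frame(
      disease = d, chromosome = as.character(df$chromosome),
      n_proteins = as.integer(df$n_proteins), epitopes = "",
      n_resistant = as.integer(df$n_resistant), intact_epitopes = "",
      stringsAsFactors = FALSE
    ))
  }
  totals <- do.call(rbind, lapply(names(counts), function(d) {
    data.frame(disease = d,
               n_proteins = sum(as.integer(counts[[d]]$n_proteins)),
               n_resistant = sum(as.integer(counts[[d]]$n_resistant)),
               stringsAsFactors = FALSE)
  }))
  structure(
    list(rows = rows, totals = totals,
         union_candidates = as.integer(union_candidates),
         union_resistant = NA_integer_, unlocalized = 0L, threshold = NA),
    class = "summary_table"
  )
}

#' Read a published per-chromosome count table
#'
#' Loads a TSV with columns `disease`, `chromosome`, `n_proteins`,
#' `n_resistant` (plus an optional `union`/`all` row giving the distinct
#' candidate total) and assembles it into a `summary_table` via
#' [summary_from_counts()], ready for [percentages()]. The package ships the
#' published distribution at
#' `system.file("extdata", "table1_counts.tsv", package = "allerscreen")`.
#'
#' @param path Path to the counts TSV.
#' @return A `summary_table`.
#' @export
read_summary_counts <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   colClasses = "character", check.names = FALSE)
  need <- c("disease", "chromosome", "n_proteins", "n_resistant")
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols) > 0L) {
    stop("count table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  union_row <- df$disease == "union"
  union_candidates <- if (any(union_row)) {
    as.integer(df$n_proteins[union_row][1L])
  } else {
    NA_integer_
  }
  df <- df[!union_row, , drop = FALSE]
  counts <- lapply(split(df, df$disease), function(sub) {
    data.frame(chromosome = sub$chromosome,
               n_proteins = as.integer(sub$n_proteins),
               n_resistant = as.integer(sub$n_resistant),
               stringsAsFactors = FALSE)
  })
  summary_from_counts(counts, union_candidates = union_candidates)
}

#' @export
print.summary_table <- function(x, ...) {
  cat("summary_table:", nrow(x$rows), "chromosome/disease cell(s);",
      "union candidates:", x$union_candidates, "\n")
  print(x$rows)
  invisible(x)
}

#' Derived percentage report
#'
#' Computes the report percentages from a [per_chromosome_summary()] (or
#' [summary_from_counts()]) table, rounded half away from zero at the
#' requested precision:
#' * `chromosome_share` - each chromosome's share of a disease's candidate
#'   proteins (default 1 decimal);
#' * `digest_resistant_share` - the share of each disease's proteins that
#'   remain digest-resistant (default 2 decimals);
#' * `disease_share_of_candidates` - each disease's share of the union
#'   candidate count (default integer).
#' Percentages over a zero (or unknown) total are reported as `NA`, never 0.
#'
#' @param table A `summary_table`.
#' @param digits Decimals for chromosome shares.
#' @param resistant_digits Decimals for digest-resistant shares.
#' @param share_digits Decimals for disease shares of the union count.
#' @return `data.frame` with columns `measure`, `disease`, `chromosome`,
#'   `value`.
#' @export
percentages <- function(table, digits = 1, resistant_digits = 2,
                        share_digits = 0) {
  stopifnot(inherits(table, "summary_table"))
  rows <- table$rows
  totals <- table$totals
  out <- data.frame(measure = character(0), disease = character(0),
                    chromosome = character(0), value = numeric(0),
                    stringsAsFactors = FALSE)
  tot_of <- setNames(totals$n_proteins, totals$disease)
  for (i in seq_len(nrow(rows))) {
    tot <- tot_of[[rows$disease[i]]]
    val <- if (is.na(tot) || tot == 0L) NA_real_ else {
      round_half_away(100 * rows$n_proteins[i] / tot, digits)
    }
    out <- rbind(out, data.frame(
      measure = "chromosome_share", disease = rows$disease[i],
      chromosome = rows$chromosome[i], value = val, stringsAsFactors = FALSE
    ))
  }
  for (i in seq_len(nrow(totals))) {
    tot <- totals$n_proteins[i]
    val <- if (is.na(tot) || tot == 0L) NA_real_ else {
      round_half_away(100 * totals$n_resistant[i] / tot, resistant_digits)
    }
    out <- rbind(out, data.frame(
      measure = "digest_resistant_share", disease = totals$disease[i],
      chromosome = "", value = val, stringsAsFactors = FALSE
    ))
  }
  uc <- table$union_candidates
  for (i in seq_len(nrow(totals))) {
    val <- if (is.na(uc) || uc == 0L) NA_real_ else {
      round_half_away(100 * totals$n_proteins[i] / uc, share_digits)
    }
    out <- rbind(out, data.frame(
      measure = "disease_share_of_candidates", disease = totals$disease[i],
      chromosome = "", value = val, stringsAsFactors = FALSE
    ))
  }
  rownames(out) <- NULL
  out
}

#' Render the summary surfaces to TSV files
#'
#' Writes `summary.tsv` (the per-chromosome table), `percentages.tsv` and
#' `footnotes.txt` (unlocalized-protein count and a configuration echo) into
#' a directory. Output is bit-stable: fixed column order, `\n` line endings,
#' `.` decimal separator.
#'
#' @param table A `summary_table`.
#' @param pct The matching [percentages()] data.frame.
#' @param dir Output directory (created if needed).
#' @param params Named list echoed into the footnotes (thresholds, enzyme
#'   set, rounding, ...).
#' @return The directory, invisibly.
#' @export
render_report <- function(table, pct, dir, params = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_tsv(table$rows, file.path(dir, "summary.tsv"))
  .write_tsv(pct, file.path(dir, "percentages.tsv"))
  totals_line <- vapply(seq_len(nrow(table$totals)), function(i) {
    sprintf("total %s: %d proteins, %d digest-resistant",
            table$totals$disease[i], table$totals$n_proteins[i],
            table$totals$n_resistant[i])
  }, character(1))
  foot <- c(
    totals_line,
    sprintf("union candidate proteins: %s", table$union_candidates),
    sprintf("proteins without chromosome label: %d", table$unlocalized),
    if (length(params) > 0L) {
      paste0("config ", names(params), " = ",
             vapply(params, function(v) paste(v, collapse = ","),
                    character(1)))
    }
  )
  con <- file(file.path(dir, "footnotes.txt"), open = "wb")
  writeLines(foot, con, sep = "\n")
  close(con)
  invisible(dir)
}
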