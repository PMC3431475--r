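RULE_POSITIONS <- c("P4", "P3", "P2", "P1", "P1p", "P2p")
DEFAULT_ENZYMES <- c("trypsin", "pepsin_ph1.3", "chymotrypsin_high")

.parse_class <- function(token) {
  token <- trimws(token)
  if (token == "-" || token == "") return(NULL)       # unconstrained
  if (token == ".") return(AA_STANDARD)                # any residue, in range
  if (startsWith(token, "^")) {
    excl <- .chars(substring(token, 2L))
    bad <- setdiff(excl, AA_STANDARD)
    if (length(bad) > 0L) {
      stop("non-standard residue in rule class: ", paste(bad, collapse = ","),
           call. = FALSE)
    }
    return(setdiff(AA_STANDARD, excl))
  }
  letters_tok <- .chars(token)
  bad <- setdiff(letters_tok, AA_STANDARD)
  if (length(bad) > 0L) {
    stop("non-standard residue in rule class: ", paste(bad, collapse = ","),
         call. = FALSE)
  }
  letters_tok
}

#' Load protease cleavage rules
#'
#' Parses a declarative specificity table into a `cleavage_ruleset`. Each
#' rule line names required residue classes at the context positions
#' P4, P3, P2, P1, P1', P2' around a candidate scissile bond (absent
#' position = wildcard) plus optional exception patterns over the same
#' positions; the enzyme cleaves the P1|P1' bond when some line's
#' requirements hold and none of its exceptions hold. The default table
#' ships the three-enzyme gastrointestinal set: trypsin, pepsin at pH 1.3,
#' chymotrypsin (high specificity).
#'
#' @param path Path to a rule TSV (see
#'   `system.file("extdata", "cleavage_rules.tsv", package = "allerscreen")`
#'   for the format); `NULL` loads the shipped default.
#' @param enzymes Optional subset of enzyme names to load.
#' @return A `cleavage_ruleset`: named list of enzymes, each a list of rule
#'   lines with `require` and `exceptions` context lists.
#' @export
load_cleavage_rules <- function(path = NULL, enzymes = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cleavage_rules.tsv",
                        package = "allerscreen", mustWork = TRUE)
  }
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   colClasses = "character", check.names = FALSE)
  need <- c("enzyme", "line", "kind", RULE_POSITIONS)
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols) > 0L) {
    stop("rule file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) stop("rule file defines no enzymes", call. = FALSE)
  if (!is.null(enzymes)) {
    unknown <- setdiff(enzymes, unique(df$enzyme))
    if (length(unknown) > 0L) {
      stop("unknown enzyme(s) requested: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    df <- df[df$enzyme %in% enzymes, , drop = FALSE]
  }
  parse_context <- function(row) {
    ctx <- lapply(RULE_POSITIONS, function(p) .parse_class(row[[p]]))
    names(ctx) <- RULE_POSITIONS
    ctx[!vapply(ctx, is.null, logical(1))]
  }
  rules <- list()
  for (enz in unique(df$enzyme)) {
    sub <- df[df$enzyme == enz, , drop = FALSE]
    lines <- list()
    for (ln in unique(sub$line)) {
      lsub <- sub[sub$line == ln, , drop = FALSE]
      req_rows <- which(lsub$kind == "require")
      if (length(req_rows) != 1L) {
        stop(sprintf("enzyme %s line %s must have exactly one 'require' row",
                     enz, ln), call. = FALSE)
      }
      req <- parse_context(lsub[req_rows, ])
      if (!any(c("P1", "P1p") %in% names(req))) {
        stop(sprintf("enzyme %s line %s constrains neither P1 nor P1'",
                     enz, ln), call. = FALSE)
      }
      exc <- lapply(which(lsub$kind == "except"),
                    function(i) parse_context(lsub[i, ]))
      lines[[ln]] <- list(require = req, exceptions = exc)
    }
    rules[[enz]] <- lines
  }
  structure(rules, class = "cleavage_ruleset")
}

#' @export
print.cleavage_ruleset <- function(x, ...) {
  cat("cleavage_ruleset with", length(x), "enzyme(s):\n")
  for (enz in names(x)) {
    n_exc <- sum(lengths(lapply(x[[enz]], `[[`, "exceptions")))
    cat(sprintf("  %s: %d rule line(s), %d exception(s)\n",
                enz, length(x[[enz]]), n_exc))
  }
  invisible(x)
}
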