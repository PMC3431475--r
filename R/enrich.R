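#' Read a two-column GO annotation table
#'
#' Tab-separated `sequence id <TAB> GO term`; `#` comment lines are skipped
#' and a header row naming the columns (`id`, `go_term`) is recognised and
#' dropped. Duplicate pairs collapse to one.
#'
#' @param path Path to the TSV file.
#' @return An `annotation_set`: list with `pairs` (data.frame `id`, `term`)
#'   and `universe` (unique annotated ids).
#' @export
read_go_annotations <- function(path) {
  df <- read.delim(path, sep = "\t", header = FALSE, comment.char = "#",
                   colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L) stop("annotation table needs two columns", call. = FALSE)
  df <- df[, 1:2]
  colnames(df) <- c("id", "term")
  if (nrow(df) > 0L && df$id[1L] == "id" && df$term[1L] == "go_term") {
    df <- df[-1L, , drop = FALSE]
  }
  as_annotation_set(df$id, df$term)
}

#' Construct an annotation set from id/term pairs
#'
#' @param ids,terms Character vectors of equal length.
#' @return An `annotation_set`.
#' @export
as_annotation_set <- function(ids, terms) {
  stopifnot(length(ids) == length(terms))
  pairs <- unique(data.frame(id = as.character(ids),
                             term = as.character(terms),
                             stringsAsFactors = FALSE))
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, universe = sort(unique(pairs$id))),
            class = "annotation_set")
}

#' Read an OBO-lite parent table
#'
#' Two tab-separated columns `child_term <TAB> parent_term`; `#` comments
#' skipped, optional header (`child_term`, `parent_term`) dropped. The edge
#' set must be acyclic.
#'
#' @param path Path to the TSV file.
#' @return A `term_graph`: list with `edges` (data.frame `child`, `parent`).
#' @export
read_term_graph <- function(path) {
  df <- read.delim(path, sep = "\t", header = FALSE, comment.char = "#",
                   colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L) stop("term graph needs two columns", call. = FALSE)
  df <- df[, 1:2]
  colnames(df) <- c("child", "parent")
  if (nrow(df) > 0L && df$child[1L] == "child_term" &&
        df$parent[1L] == "parent_term") {
    df <- df[-1L, , drop = FALSE]
  }
  as_term_graph(df$child, df$parent)
}

#' Construct a term graph from child/parent edges
#'
#' @param child,parent Character vectors of equal length.
#' @return A `term_graph`.
#' @export
as_term_graph <- function(child = character(0), parent = character(0)) {
  edges <- unique(data.frame(child = as.character(child),
                             parent = as.character(parent),
                             stringsAsFactors = FALSE))
  rownames(edges) <- NULL
  g <- structure(list(edges = edges), class = "term_graph")
  .check_acyclic(g)
  g
}

# Kahn topological check; cycles are a configuration error.
.check_acyclic <- function(graph) {
  e <- graph$edges
  if (nrow(e) == 0L) return(invisible(TRUE))
  nodes <- unique(c(e$child, e$parent))
  indeg <- setNames(integer(length(nodes)), nodes)
  tab <- table(e$parent)
  indeg[names(tab)] <- as.integer(tab)
  queue <- nodes[indeg == 0L]
  removed <- 0L
  children <- split(e$parent, e$child)
  while (length(queue) > 0L) {
    v <- queue[[1L]]; queue <- queue[-1L]; removed <- removed + 1L
    for (p in children[[v]]) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (removed != length(nodes)) {
    stop("term graph contains a cycle", call. = FALSE)
  }
  invisible(TRUE)
}

.ancestors <- function(graph) {
  e <- graph$edges
  parents_of <- split(e$parent, e$child)
  memo <- new.env(parent = emptyenv())
  anc <- function(term) {
    if (!is.null(memo[[term]])) return(memo[[term]])
    direct <- parents_of[[term]]
    out <- character(0)
    for (p in direct) out <- union(out, c(p, anc(p)))
    memo[[term]] <- out
    out
  }
  anc
}

#' Propagate annotations up the term graph
#'
#' DAG-aware counting: every (id, term) pair induces (id, ancestor) for each
#' ancestor of the term; duplicates (e.g. from diamond-shaped paths)
#' collapse to one pair.
#'
#' @param annotations An `annotation_set`.
#' @param graph A `term_graph`.
#' @return The propagated `annotation_set`.
#' @export
propagate_annotations <- function(annotations, graph) {
  stopifnot(inherits(annotations, "annotation_set"),
            inherits(graph, "term_graph"))
  if (nrow(graph$edges) == 0L) return(annotations)
  anc <- .ancestors(graph)
  terms <- unique(annotations$pairs$term)
  anc_of <- lapply(setNames(terms, terms), anc)
  extra <- lapply(terms, function(t) {
    up <- anc_of[[t]]
    if (length(up) == 0L) return(NULL)
    ids <- annotations$pairs$id[annotations$pairs$term == t]
    data.frame(id = rep(ids, times = length(up)),
               term = rep(up, each = length(ids)),
               stringsAsFactors = FALSE)
  })
  all_pairs <- rbind(annotations$pairs, do.call(rbind, extra))
  as_annotation_set(all_pairs$id, all_pairs$term)
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of seeing
#' at least `k` annotated sequences in a study set of size `n` drawn from a
#' background of `N` sequences of which `K` carry the term. Computed with
#' the stable survival function [stats::phyper()].
#'
#' @param k Observed study-set count.
#' @param n Study-set size.
#' @param K Background count carrying the term.
#' @param N Background size.
#' @return Probability in `[0, 1]` (vectorised over its arguments).
#' @export
hypergeom_pvalue <- function(k, n, K, N) {
  bad <- k < 0 | k > pmin(n, K) | n > N | K > N | k < pmax(0, n + K - N)
  if (any(bad)) {
    stop("inconsistent hypergeometric counts (need 0 <= k <= min(n, K), ",
         "max(0, n + K - N) <= k, n <= N, K <= N)", call. = FALSE)
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjustment with monotonicity enforcement, values capped at 1,
#' output aligned to the input order (delegates to [stats::p.adjust()]).
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvalues, method = "BH")
}

#' GO term over-representation of a study set
#'
#' BiNGO-style over-representation: for every term annotating at least one
#' study-set member (after any propagation), an upper-tail hypergeometric
#' test of the study count against the background, followed by
#' Benjamini-Hochberg FDR across exactly the tested terms. Sequences without
#' annotations count in the set sizes `n` and `N` but contribute to no term.
#' Significance is called at BH-adjusted `q <= alpha`.
#'
#' @param study Character vector of study-set ids (subset of `background`).
#' @param background Character vector of background ids.
#' @param annotations An `annotation_set` (propagate first with
#'   [propagate_annotations()] for DAG-aware counting).
#' @param alpha Significance level (default 0.05).
#' @return `data.frame` of class `enrichment_table` with columns `term`,
#'   `k`, `n`, `K`, `N`, `p`, `q`, `significant`, sorted by `q`, then `p`,
#'   then term id.
#' @export
enrich <- function(study, background, annotations, alpha = 0.05) {
  stopifnot(inherits(annotations, "annotation_set"),
            alpha > 0, alpha < 1)
  study <- unique(as.character(study))
  background <- unique(as.character(background))
  if (!all(study %in% background)) {
    stop("study set must be a subset of the background", call. = FALSE)
  }
  pairs <- annotations$pairs
  pairs <- pairs[pairs$id %in% background, , drop = FALSE]
  n <- length(study)
  N <- length(background)
  k_tab <- table(pairs$term[pairs$id %in% study])
  if (length(k_tab) == 0L) {
    out <- data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("enrichment_table", "data.frame")
    return(out)
  }
  terms <- names(k_tab)
  K_tab <- table(pairs$term)
  k <- as.integer(k_tab)
  K <- as.integer(K_tab[terms])
  p <- hypergeom_pvalue(k, n, K, N)
  q <- bh_adjust(p)
  out <- data.frame(
    term = terms, k = k, n = n, K = K, N = N, p = p, q = q,
    significant = q <= alpha, stringsAsFactors = FALSE
  )
  out <- out[order(out$q, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Export an enrichment table as TSV
#'
#' @param table An `enrichment_table`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_enrichment <- function(table, path) {
  df <- as.data.frame(table)
  df$significant <- ifelse(df$significant, "TRUE", "FALSE")
  .write_tsv(df, path)
}
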