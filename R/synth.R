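# Background residue alphabet excludes Q and P so that the glutamine- and
# proline-rich epitope repertoire cannot arise spontaneously; remaining
# Q/P-free epitopes are caught by the post-construction scan.
BACKGROUND_AA <- setdiff(AA_STANDARD, c("Q", "P"))

.with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  fn()
}

#' Default epitope table of the synthetic generator
#'
#' The plantable repertoire mirrors the celiac-disease and wheat-allergy
#' peptides of the study's per-chromosome distribution table (gliadin- and
#' glutenin-derived CD peptides such as FFQP, QQQP, IPEQ, PQQLPQ and the
#' poly-glutamine stretches; WA peptides from alpha-amylase inhibitors and
#' omega/HMW/LMW prolamins such as AASVPE, ADINNE, GSQVPE, CRAMVK). Three
#' decoy records exercise the inclusion criteria: a pollen allergen, a
#' discontinuous epitope and a non-human-host record; they are never
#' planted.
#'
#' @return An `epitope_set`.
#' @export
default_epitope_table <- function() {
  as_epitope_set(
    id = c(paste0("cd", 1:6), paste0("wa", 1:10), "dx1", "dx2", "dx3"),
    peptide = c(
      "FFQP", "QQQP", "IPEQ", "PQQLPQ", "LQQQQQQQQQ", "QQQQQQQQLQ",
      "AASVPE", "ADINNE", "GSQVPE", "QQPGQ", "QQPPQQ", "QQQPP",
      "CRAMVK", "VSALTG", "SMLRSV", "GKEVLP",
      "QYPWQE", "QQWPYD", "PQYWED"
    ),
    disease = c(rep("CD", 6), rep("WA", 10), "WA", "CD", "WA"),
    host = c(rep("Homo sapiens", 17), "Homo sapiens", "Mus musculus"),
    is_pollen = c(rep(FALSE, 16), TRUE, FALSE, FALSE),
    is_linear = c(rep(TRUE, 17), FALSE, TRUE),
    source_protein = c(
      "alpha gliadin", "alpha gliadin", "gluten", "alpha gliadin",
      "alpha gliadin", "alpha gliadin",
      "alpha-amylase inhibitor", "alpha-amylase inhibitor",
      "alpha-amylase inhibitor", "omega gliadin", "LMW glutenin",
      "HMW glutenin", "alpha-amylase inhibitor", "alpha-amylase inhibitor",
      "omega gliadin", "alpha-amylase inhibitor",
      "grass pollen protein", "alpha gliadin", "gliadin-like"
    ),
    source_species = c(rep("Triticum aestivum", 16),
                       "Phleum pratense", "Triticum aestivum",
                       "Triticum aestivum")
  )
}

#' Generator configuration
#'
#' Collects the tunable parameters of [generate_synthetic_data()] with the
#' defaults used throughout the package's tests.
#'
#' @param n_proteins Proteome size.
#' @param chromosomes Chromosome labels.
#' @param chromosome_weights Sampling weights per chromosome.
#' @param length_range Protein length range (residues).
#' @param epitopes The epitope table (see [default_epitope_table()]).
#' @param candidate_fraction Fraction of proteins carrying planted epitopes.
#' @param occurrences_range Planted fragments per candidate protein.
#' @param exposed_fraction Fraction of plantings requested as `exposed`
#'   (falls back to `shielded` where chemistry makes exposure impossible).
#' @param expressed_fraction Fraction of candidate proteins given
#'   full-identity seed ESTs.
#' @param decoy_fraction Fraction of candidate proteins given only diverged
#'   (decoy) ESTs.
#' @param decoy_divergence Amino-acid divergence of decoy ESTs (exact forced
#'   substitution fraction; 0.05 keeps them safely below a 0.98 identity
#'   acceptance threshold).
#' @param ests_per_gene Range of EST reads per expressed gene.
#' @param est_segment_range EST segment length range (residues).
#' @param n_terms Number of background GO terms.
#' @param planted_term Identifier of the enriched term.
#' @param planted_factor Enrichment factor of the planted term in the
#'   candidate set relative to the background annotation probability.
#' @param base_term_prob Background probability of the planted term.
#' @param mean_terms_per_protein Poisson mean of background terms per
#'   protein.
#' @param max_resample Attempts to rebuild a protein that acquired an
#'   accidental epitope occurrence.
#' @return Named list of parameters.
#' @export
synthetic_config <- function(n_proteins = 300,
                             chromosomes = as.character(1:5),
                             chromosome_weights = c(0.3, 0.2, 0.2, 0.2, 0.1),
                             length_range = c(120, 400),
                             epitopes = default_epitope_table(),
                             candidate_fraction = 0.4,
                             occurrences_range = c(1, 2),
                             exposed_fraction = 0.3,
                             expressed_fraction = 0.4,
                             decoy_fraction = 0.1,
                             decoy_divergence = 0.05,
                             ests_per_gene = c(1, 2),
                             est_segment_range = c(50, 100),
                             n_terms = 40,
                             planted_term = "GO:1000000",
                             planted_factor = 10,
                             base_term_prob = 0.03,
                             mean_terms_per_protein = 2,
                             max_resample = 25) {
  as.list(environment())
}

#' Flank an epitope for a controlled digestion outcome
#'
#' Builds the planted sequence fragment `left + epitope + right` whose
#' interior cleavage status is known by construction:
#' * `shielded` - lysine-rich flanks place K at the P2/P3 reach-in positions
#'   so no default rule fires strictly inside the epitope from outside
#'   context, and trypsin releases the fragment at the epitope's entry bond
#'   (a WK flank handles proline-initial epitopes). Epitopes whose cleavage
#'   context is entirely self-contained (an interior K/R/F/Y/W, or an L with
#'   permissive in-epitope context) still cleave; the achieved status is
#'   computed and returned rather than assumed.
#' * `exposed` - neutral glycine flanks; requires that some rule fires
#'   strictly inside the planted interval, which needs a rule-class residue
#'   (K/R/F/Y/W/L) in the epitope. Requesting exposure for an epitope
#'   without one is an error.
#'
#' @param peptide Epitope peptide (standard residues, no X).
#' @param template `"shielded"` or `"exposed"`.
#' @param rules A `cleavage_ruleset`.
#' @return List with `fragment`, `offset` (0-based epitope start within the
#'   fragment), `interior_sites` (bond indices relative to the epitope
#'   start) and `intact`.
#' @export
make_cleavable <- function(peptide, template = c("shielded", "exposed"),
                           rules = load_cleavage_rules()) {
  template <- match.arg(template)
  if (grepl("X", peptide, fixed = TRUE)) {
    stop("epitope peptide must not contain X", call. = FALSE)
  }
  if (template == "shielded") {
    left <- if (startsWith(peptide, "P")) "GWK" else "GKK"
    right <- "KKG"
  } else {
    left <- "GGG"
    right <- "GGG"
  }
  fragment <- paste0(left, peptide, right)
  off <- nchar(left)
  len <- nchar(peptide)
  sites <- cleavage_sites(fragment, rules)
  interior <- sites[sites > off & sites < off + len]
  if (template == "exposed" && length(interior) == 0L) {
    stop(sprintf("epitope '%s' cannot be made cleavable: no rule fires ",
                 peptide), "strictly inside the planted interval",
         call. = FALSE)
  }
  list(fragment = fragment, offset = off,
       interior_sites = interior - off, intact = length(interior) == 0L,
       template = template)
}

# Reverse-translate an amino-acid string with uniformly random synonymous
# codons under the standard genetic code (draws from the active RNG stream).
.codon_choices <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc_tab <- Biostrings::GENETIC_CODE
      cache <<- split(names(gc_tab), unname(gc_tab))
    }
    cache
  }
})

#' Reverse-translate a peptide with random synonymous codons
#'
#' @param peptide Amino-acid string (standard residues).
#' @return Nucleotide string of length `3 * nchar(peptide)`.
#' @export
reverse_translate <- function(peptide) {
  choices <- .codon_choices()
  aa <- .chars(peptide)
  bad <- setdiff(unique(aa), AA_STANDARD)
  if (length(bad) > 0L) {
    stop("cannot reverse-translate residue(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  paste(vapply(aa, function(a) {
    cod <- choices[[a]]
    if (length(cod) == 1L) cod else sample(cod, 1L)
  }, character(1)), collapse = "")
}

# All exact occurrences of `pep` in `s`, including overlapping ones, found
# with base-R fixed string search (independent of the package's scanner);
# 0-based starts.
.substr_hits <- function(pep, s) {
  hits <- integer(0)
  from <- 1L
  repeat {
    m <- regexpr(pep, substr(s, from, nchar(s)), fixed = TRUE)
    if (m == -1L) break
    hits <- c(hits, from + as.integer(m) - 2L)
    from <- from + as.integer(m)
  }
  hits
}

#' Generate a synthetic screening dataset with known ground truth
#'
#' Emulates the four external inputs of the screen - a multi-chromosome
#' proteome with epitope peptides planted at known coordinates, the epitope
#' table, developing-seed ESTs reverse-translated from a known subset of
#' genes, and GO annotations with one term planted at a stated enrichment
#' factor - and records every construction decision in a truth manifest so
#' each pipeline stage has an exact oracle.
#'
#' Background residues are drawn from an alphabet excluding Q and P (the
#' epitope repertoire is glutamine/proline-rich); after construction each
#' protein is scanned with an independent fixed-string search and rebuilt if
#' any epitope occurrence exists beyond the manifested ones, so the
#' manifest is exact by verification, not just by construction. Planted
#' fragments also manifest the occurrences they imply of *other* table
#' epitopes (e.g. QQQP inside a planted QQQPP), with intact status computed
#' on the fragment.
#'
#' @param config See [synthetic_config()].
#' @param seed Integer seed; the generator touches no global random state
#'   beyond a save/restore of R's RNG.
#' @param dir Optional directory; when given, writes `proteome.fasta`,
#'   `epitopes.tsv`, `ests.fasta`, `annotations.tsv`, `term_graph.tsv` and
#'   `manifest.json` there.
#' @return List with `proteome` (`AAStringSet`), `epitopes`
#'   (`epitope_set`), `ests` (`DNAStringSet`), `annotations`
#'   (`annotation_set`), `term_graph` and `manifest`.
#' @export
generate_synthetic_data <- function(config = synthetic_config(), seed,
                                    dir = NULL) {
  .with_seed(seed, function() .generate_impl(config, seed, dir))
}

.generate_impl <- function(cfg, seed, dir) {
  rules <- load_cleavage_rules()
  epitopes <- cfg$epitopes
  if (any(grepl("X", epitopes$peptide, fixed = TRUE))) {
    stop("epitope peptide containing X is not allowed", call. = FALSE)
  }
  plantable <- filter_epitopes(epitopes)
  n <- cfg$n_proteins
  chrom <- sample(cfg$chromosomes, n, replace = TRUE,
                  prob = cfg$chromosome_weights)
  ids <- sprintf("Bradi%sg%05d", chrom, seq_len(n) * 10L)
  is_candidate <- rep(FALSE, n)
  is_candidate[sample.int(n, round(cfg$candidate_fraction * n))] <- TRUE

  all_peptides <- epitopes$peptide
  planted_rows <- list()
  proteins <- character(n)

  for (i in seq_len(n)) {
    target_len <- sample(cfg$length_range[1]:cfg$length_range[2], 1L)
    frags <- list()
    if (is_candidate[i]) {
      k <- sample(cfg$occurrences_range[1]:cfg$occurrences_range[2], 1L)
      rows <- sample.int(nrow(plantable), k,
                         replace = k > nrow(plantable))
      for (r in rows) {
        pep <- plantable$peptide[r]
        want_exposed <- runif(1L) < cfg$exposed_fraction
        frag <- if (want_exposed) {
          tryCatch(make_cleavable(pep, "exposed", rules),
                   error = function(e) make_cleavable(pep, "shielded", rules))
        } else {
          make_cleavable(pep, "shielded", rules)
        }
        frag$epitope_row <- r
        frags[[length(frags) + 1L]] <- frag
      }
    }
    for (attempt in seq_len(cfg$max_resample)) {
      frag_len <- sum(vapply(frags, function(f) nchar(f$fragment),
                             numeric(1)))
      n_gaps <- length(frags) + 1L
      bg_total <- max(target_len - frag_len, 20L * n_gaps)
      extra <- bg_total - 20L * n_gaps
      add <- if (extra > 0L) {
        as.integer(stats::rmultinom(1L, extra, rep(1, n_gaps)))
      } else {
        rep(0L, n_gaps)
      }
      gap_len <- 20L + add
      pieces <- character(0)
      expected <- list()
      pos <- 0L
      for (g in seq_len(n_gaps)) {
        bg <- paste(sample(BACKGROUND_AA, gap_len[g], replace = TRUE),
                    collapse = "")
        pieces <- c(pieces, bg)
        pos <- pos + gap_len[g]
        if (g <= length(frags)) {
          f <- frags[[g]]
          pieces <- c(pieces, f$fragment)
          # all table-epitope occurrences this fragment induces
          for (pj in seq_along(all_peptides)) {
            rel <- .substr_hits(all_peptides[pj], f$fragment)
            for (rs in rel) {
              plen <- nchar(all_peptides[pj])
              sub_interior <- f$interior_sites + f$offset
              sub_interior <- sub_interior[sub_interior > rs &
                                             sub_interior < rs + plen]
              expected[[length(expected) + 1L]] <- data.frame(
                protein_id = ids[i], epitope_id = epitopes$id[pj],
                peptide = all_peptides[pj], disease = epitopes$disease[pj],
                start = pos + rs, end = pos + rs + plen,
                template = f$template,
                primary = epitopes$id[pj] == plantable$id[f$epitope_row],
                intact = length(sub_interior) == 0L,
                stringsAsFactors = FALSE
              )
            }
          }
          pos <- pos + nchar(f$fragment)
        }
      }
      prot <- paste(pieces, collapse = "")
      exp_df <- do.call(rbind, expected)
      ok <- TRUE
      for (pj in seq_along(all_peptides)) {
        found <- .substr_hits(all_peptides[pj], prot)
        want <- if (is.null(exp_df)) integer(0) else {
          sort(exp_df$start[exp_df$peptide == all_peptides[pj]])
        }
        if (!identical(sort(found), as.integer(want))) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        proteins[i] <- prot
        if (!is.null(exp_df)) {
          planted_rows[[length(planted_rows) + 1L]] <- exp_df
        }
        break
      }
      if (attempt == cfg$max_resample) {
        stop("could not build an accidental-occurrence-free protein after ",
             cfg$max_resample, " attempts; relax the generator parameters",
             call. = FALSE)
      }
    }
  }
  planted <- do.call(rbind, planted_rows)
  if (is.null(planted)) {
    planted <- data.frame(
      protein_id = character(0), epitope_id = character(0),
      peptide = character(0), disease = character(0), start = integer(0),
      end = integer(0), template = character(0), primary = logical(0),
      intact = logical(0), stringsAsFactors = FALSE
    )
  }

  # --- expression truth and ESTs -------------------------------------------
  cand_idx <- which(is_candidate)
  n_expr <- round(cfg$expressed_fraction * length(cand_idx))
  expr_idx <- sample(cand_idx, n_expr)
  rest <- setdiff(cand_idx, expr_idx)
  n_decoy <- min(length(rest), round(cfg$decoy_fraction * length(cand_idx)))
  decoy_idx <- if (n_decoy > 0L) sample(rest, n_decoy) else integer(0)

  est_seqs <- character(0)
  est_ids <- character(0)
  est_rows <- list()
  mutate_segment <- function(segment, divergence) {
    if (divergence <= 0) return(segment)
    aa <- .chars(segment)
    n_mut <- ceiling(divergence * length(aa))
    at <- sample.int(length(aa), n_mut)
    for (j in at) {
      aa[j] <- sample(setdiff(BACKGROUND_AA, aa[j]), 1L)
    }
    paste(aa, collapse = "")
  }
  for (i in c(expr_idx, decoy_idx)) {
    divergence <- if (i %in% decoy_idx) cfg$decoy_divergence else 0
    n_e <- sample(cfg$ests_per_gene[1]:cfg$ests_per_gene[2], 1L)
    for (e in seq_len(n_e)) {
      plen <- nchar(proteins[i])
      seg_len <- min(plen,
                     sample(cfg$est_segment_range[1]:cfg$est_segment_range[2],
                            1L))
      seg_start <- sample.int(plen - seg_len + 1L, 1L)
      segment <- substr(proteins[i], seg_start, seg_start + seg_len - 1L)
      segment <- mutate_segment(segment, divergence)
      nt <- reverse_translate(segment)
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") {
        nt <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(nt)))
      }
      est_id <- sprintf("EST%05d", length(est_ids) + 1L)
      est_ids <- c(est_ids, est_id)
      est_seqs <- c(est_seqs, nt)
      est_rows[[length(est_rows) + 1L]] <- data.frame(
        est_id = est_id, protein_id = ids[i], divergence = divergence,
        strand = strand, seg_start = seg_start, seg_len = seg_len,
        stringsAsFactors = FALSE
      )
    }
  }
  ests_truth <- do.call(rbind, est_rows)
  if (is.null(ests_truth)) {
    ests_truth <- data.frame(est_id = character(0), protein_id = character(0),
                             divergence = numeric(0), strand = character(0),
                             seg_start = integer(0), seg_len = integer(0),
                             stringsAsFactors = FALSE)
  }

  # --- GO annotations with one planted enriched term -----------------------
  ann <- simulate_annotations(
    ids = ids, study_ids = ids[is_candidate], n_terms = cfg$n_terms,
    planted_term = cfg$planted_term, planted_factor = cfg$planted_factor,
    base_term_prob = cfg$base_term_prob,
    mean_terms_per_protein = cfg$mean_terms_per_protein
  )
  term_graph <- .default_term_graph(cfg$n_terms, cfg$planted_term)

  manifest <- list(
    schema = "allerscreen-manifest/1",
    seed = seed,
    params = cfg[setdiff(names(cfg), "epitopes")],
    proteins = data.frame(
      id = ids, chromosome = chrom, length = nchar(proteins),
      is_candidate = is_candidate,
      expressed = seq_len(n) %in% expr_idx,
      decoy_est = seq_len(n) %in% decoy_idx,
      stringsAsFactors = FALSE
    ),
    planted = planted,
    ests = ests_truth,
    go = list(planted_term = cfg$planted_term,
              planted_factor = cfg$planted_factor,
              base_term_prob = cfg$base_term_prob,
              study = ids[is_candidate])
  )

  proteome <- Biostrings::AAStringSet(setNames(proteins, ids))
  ests <- Biostrings::DNAStringSet(setNames(est_seqs, est_ids))

  out <- list(proteome = proteome, epitopes = epitopes, ests = ests,
              annotations = ann, term_graph = term_graph,
              manifest = manifest)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(proteome, file.path(dir, "proteome.fasta"))
    write_epitope_table(epitopes, file.path(dir, "epitopes.tsv"))
    write_fasta(ests, file.path(dir, "ests.fasta"))
    .write_tsv(setNames(ann$pairs, c("id", "go_term")),
               file.path(dir, "annotations.tsv"))
    .write_tsv(setNames(term_graph$edges, c("child_term", "parent_term")),
               file.path(dir, "term_graph.tsv"))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$dir <- dir
  }
  out
}

#' Draw GO annotations with one planted enriched term
#'
#' Background terms are assigned per protein at a Poisson-distributed count;
#' the planted term is assigned with probability
#' `planted_factor * base_term_prob` inside the study set and
#' `base_term_prob` outside it. Used by the generator and by power
#' replications of the enrichment stage.
#'
#' @param ids All protein ids (the annotation universe).
#' @param study_ids The enriched subset.
#' @param n_terms,planted_term,planted_factor,base_term_prob,mean_terms_per_protein
#'   See [synthetic_config()].
#' @return An `annotation_set`.
#' @export
simulate_annotations <- function(ids, study_ids, n_terms = 40,
                                 planted_term = "GO:1000000",
                                 planted_factor = 10, base_term_prob = 0.03,
                                 mean_terms_per_protein = 2) {
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  pair_id <- character(0)
  pair_term <- character(0)
  n_bg <- stats::rpois(length(ids), mean_terms_per_protein)
  for (i in seq_along(ids)) {
    if (n_bg[i] > 0L) {
      pair_id <- c(pair_id, rep(ids[i], n_bg[i]))
      pair_term <- c(pair_term, sample(terms, min(n_bg[i], n_terms)))
    }
  }
  p_in <- min(1, planted_factor * base_term_prob)
  hit <- ifelse(ids %in% study_ids,
                runif(length(ids)) < p_in,
                runif(length(ids)) < base_term_prob)
  pair_id <- c(pair_id, ids[hit])
  pair_term <- c(pair_term, rep(planted_term, sum(hit)))
  as_annotation_set(pair_id, pair_term)
}

# Two-level hierarchy over the background terms plus a diamond above the
# planted term (two parents, one grandparent), exercising DAG-aware
# propagation.
.default_term_graph <- function(n_terms, planted_term) {
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  parents <- sprintf("GO:%07d", 2000000 + (seq_len(n_terms) - 1L) %% 5 + 1L)
  root <- "GO:3000000"
  as_term_graph(
    child = c(terms, unique(parents),
              planted_term, planted_term, "GO:2100001", "GO:2100002"),
    parent = c(parents, rep(root, length(unique(parents))),
               "GO:2100001", "GO:2100002", root, root)
  )
}
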