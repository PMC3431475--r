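---
title: "Screening a seed proteome for digestion-resistant allergen epitopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening a seed proteome for digestion-resistant allergen epitopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allerscreen)
```

## The screening problem

Celiac disease (CD) and IgE-mediated wheat allergies (WA) are triggered by
short linear peptide epitopes, mostly described from wheat prolamins
(gliadins, glutenins) and related proteins. A proteome with a low prolamin
content — such as that of the model grass *Brachypodium distachyon* — can
still harbour the same peptides inside entirely different, non-prolamin
proteins. `allerscreen` implements an in-silico screen that asks, for every
protein in a predicted seed proteome:

1. Does it contain a known disease-linked linear epitope verbatim
   (or above a configurable windowed-identity threshold)?
2. Is the protein actually expressed in the developing seed, judged by a
   translated-EST alignment screen?
3. Would the epitope survive gastrointestinal digestion, modelled as the
   simultaneous action of pepsin (stomach, pH 1.3), trypsin and
   chymotrypsin (small intestine)?
4. Which molecular functions are over-represented among the surviving
   candidates (Gene Ontology over-representation)?

Because the corresponding published inputs (an IEDB epitope export, a
specific proteome release, seed EST libraries, an annotation snapshot) were
never deposited with accessions, the package pairs the pipeline with a
synthetic-data generator that emulates all four inputs with a known truth
manifest. Every pipeline stage can therefore be validated exactly, with no
downloads.

## Epitope mapping (conservancy model)

Epitope inclusion follows the screen's criteria: human host, pollen
allergens excluded, linear epitopes only, disease class in {CD, WA}
(`filter_epitopes()`). Mapping then slides an ungapped window of epitope
length along each protein and scores positional identity — the
conservancy-analysis model, not a gapped alignment. At the default
threshold of 1.0 a match is an exact peptide occurrence; overlapping and
repeated matches are all recorded. Coordinates are 0-based half-open
internally and rendered 1-based inclusive in reports. The unknown residue
`X` matches nothing, including another `X`, so undetermined stretches can
neither create matches nor (later) cleavage sites.

A protein counts once per disease class no matter how many matches it
carries, and the two disease views are non-exclusive: the per-class counts
may sum to more than the union candidate count.

## Digestion model

Protease specificity is declarative: each enzyme is a set of rule lines
over the Keil context positions P4–P2′ around a candidate scissile bond,
with optional blocking exceptions; the shipped table transcribes the ExPASy
PeptideCutter models for trypsin (including the WKP/MRP positive
sub-rules and the [CD]K-D, C-K-[HY], C-R-K, R-R-[HR] exceptions), pepsin at
pH 1.3 and high-specificity chymotrypsin. Digestion is simultaneous: the
cleavage-bond set of a protein is the union over the three enzymes. Two
deliberate conventions:

* **Termini.** Context positions beyond the sequence ends satisfy no
  residue class — requirements referencing them fail, exceptions
  referencing them cannot fire. This pins otherwise-undefined behaviour at
  the termini and makes results near sequence ends auditable.
* **Intactness is boundary-exclusive.** An epitope occurrence survives iff
  no bond falls strictly inside its interval; bonds at its own boundaries
  merely excise the peptide whole, which still presents the epitope.

Cleavage is deterministic and all-or-nothing — no partial-digestion
probabilities, no structure-dependent site exposure. The pipeline's two
result views (undigested and digested) bracket the two structural extremes:
all cleavage sites buried versus all exposed.

A chemical consequence worth stating: under these rules a peptide
containing none of K, R, F, Y, W, L can never be cleaved, while some
glutamine-rich epitopes with an interior leucine (e.g. `QQQQQQQQLQ`,
`PQQLPQ`) carry a pepsin site whose entire context lies inside the peptide,
so no flanking sequence can protect them. The engine reports such sites
rather than suppressing them; intactness of those peptides in any
real-world report cannot be reproduced from the published rule tables
alone.

## Expression filter

The tBlastN-style screen translates each EST in all six reading frames
(standard code, incomplete trailing codons dropped, stops rendered `*`,
N-containing codons rendered `X`) and aligns every frame against each
candidate protein with Smith–Waterman local alignment under BLAST-protein
default scoring (BLOSUM62, gap open 11, gap extend 1). A protein counts as
seed-expressed when some frame reaches identity ≥ 0.98 over at least 30
alignment columns. Design choices:

* Identity is identical residue pairs over alignment columns, with gap
  columns in the denominator — the conservative reading.
* "Over 98%" is read inclusively (≥ 0.98) by default; a `strict` switch
  gives the strictly-greater reading, so the boundary behaviour is explicit
  and configurable rather than silent.
* The 30-column floor is a package knob, not a claim about any published
  protocol: without a coverage floor a 4-residue perfect alignment would
  count as expression evidence. It also makes shared planted epitopes
  (≤ 16 residues with flanks) unable to cross-link unrelated genes in the
  synthetic data.
* No E-values: acceptance is identity-based, and at desk scale exact
  alignment dominates the seeded heuristic it stands in for.

For throughput, each frame–protein pair is first scored without traceback;
the full alignment is computed only when the optimal score reaches a
provable floor for an acceptable hit (an alignment with `C` columns at
identity θ scores at least `C·(4θ − 12(1−θ))` under BLOSUM62, whose
smallest diagonal entry is 4 and whose costliest column is a gap opening at
12). Alignments that cannot possibly pass are never tracebacked.

## GO over-representation

Annotations are propagated up the term graph (every annotated term implies
its ancestors, duplicates collapsed) before testing, emulating DAG-aware
counting. For each term annotating at least one study-set member, the
upper-tail hypergeometric probability
\(P(X \ge k)\) with \(X \sim \mathrm{Hypergeom}(N, K, n)\) is computed via
the survival function, followed by Benjamini–Hochberg adjustment across
exactly the tested terms; significance is `q ≤ 0.05`. Pinned conventions:
unannotated proteins count in the set sizes but toward no term; the default
background is the full annotation universe (configurable); the multiple-
testing family is exactly the terms with a nonzero study count. The
pipeline tests four study sets, crossing disease class with digestion mode.

## The synthetic generator and its manifest

`generate_synthetic_data()` builds a five-chromosome proteome (default 300
proteins of 120–400 residues, identifiers in the `Bradi<chr>g<num>` style),
plants epitope occurrences at known coordinates in a 40% candidate subset,
emits ESTs for a 40% subset of the candidates, and draws GO annotations
with one term enriched tenfold (30% in the candidate set vs a 3% base
rate). Background residues are drawn from an alphabet *excluding Q and P*,
so the glutamine/proline-rich epitope repertoire cannot arise by chance;
the few Q/P-free epitopes are covered by a post-construction scan with an
independent fixed-string search, and any protein carrying an occurrence
beyond the manifested ones is rebuilt. The manifest is therefore exact by
verification, not merely by construction — including occurrences *implied*
by planting (e.g. `QQQP` inside a planted `QQQPP`).

Digestion truth is controlled by flank templates: `shielded` plantings use
lysine-rich flanks (K at the P2/P3 reach-in positions blocks the pepsin
context, and trypsin releases the fragment at the epitope's entry bond,
with a WK flank handling proline-initial epitopes); `exposed` plantings use
neutral glycine flanks and require a rule to fire strictly inside the
epitope, which is an error to request for a rule-residue-free peptide. For
self-cleaving epitopes (previous section) the achieved status is computed
with the engine and recorded — the manifest never asserts chemistry the
rules contradict.

EST divergence is controlled at the amino-acid level by an exact count of
forced substitutions — expressed genes at divergence 0 (identity 1.0),
decoy genes at 0.05 (identity 0.95, safely below the 0.98 acceptance
threshold) — and only then reverse-translated with uniformly random
synonymous codons, half on the reverse strand. Nucleotide-level point
mutation was rejected because synonymous changes make the resulting
amino-acid identity stochastic around the acceptance boundary, which would
break the manifest's role as an exact oracle.

What the generator does **not** emulate: real gene models (introns, UTRs),
codon usage bias, EST sequencing-error profiles, homologous protein
families, or biologically structured GO namespaces. Passing the synthetic
acceptance checks therefore demonstrates that the pipeline's machinery is
correct — exact recovery of planted truth, calibrated statistics — not that
its biological conclusions transfer to any particular real proteome.

## Numerical and reproducibility choices

* Report percentages round half away from zero at the printed precision
  (1 decimal for chromosome shares, 2 for digest-resistant shares, integer
  for disease shares of the union), matching how such tables are printed;
  `round()`'s half-to-even rule would disagree on exact halves.
  Percentages over an empty total are reported as absent, never as 0.
* Identity comparisons carry a 1e-9 slack so ratios of small integers
  stored as doubles compare correctly at thresholds like 49/50 = 0.98.
* All TSV output is written with fixed column order, `\n` endings and `.`
  decimals, so reruns are byte-identical and locale-independent.
* The generator takes an explicit seed and saves/restores the caller's RNG
  state; problem sizes in the shipped tests (120-protein fixture for
  end-to-end checks; a 50-of-1000 study condition for the 200-replicate
  power check; 1000-case oracle-equivalence sweeps) were chosen to keep the
  default suite comfortably interactive while leaving the statistical
  checks well-powered.

## Worked example

```{r example, eval = FALSE}
dat <- tempfile("data_")
out <- tempfile("results_")
generate_synthetic_data(synthetic_config(n_proteins = 150), seed = 42,
                        dir = dat)
res <- run_allergen_screen(
  proteome = file.path(dat, "proteome.fasta"),
  epitopes = file.path(dat, "epitopes.tsv"),
  ests = file.path(dat, "ests.fasta"),
  annotations = file.path(dat, "annotations.tsv"),
  term_graph = file.path(dat, "term_graph.tsv"),
  out_dir = out
)
res$log          # stage-wise record counts
res$summary      # per-chromosome candidate / digest-resistant table
head(res$enrichment$cd_not_digested)
```

## Known limitations

* The digestion model is primary-structure only; the undigested/digested
  pair brackets, but does not model, conformational shielding.
* Sub-100% epitope matching follows the ungapped conservancy window model;
  it is not a gapped homology search and makes no claim about reproducing
  unpublished intermediate-identity screens.
* Published per-epitope resistance lists cannot all be reproduced from the
  public rule tables (self-cleaving peptides above); the package reproduces
  the *calling procedure* and the published count arithmetic, not those
  specific entries.
* BH control is applied per study set; results across the four study sets
  are not jointly corrected, mirroring the per-network testing convention
  of the tool this stage emulates.
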