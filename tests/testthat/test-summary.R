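test_that("half-away-from-zero rounding matches printed-report conventions", {
  expect_equal(round_half_away(20.96, 0), 21)
  expect_equal(round_half_away(0.5, 0), 1)
  expect_equal(round_half_away(-0.5, 0), -1)
  expect_equal(round_half_away(2.5, 0), 3) # round() would give 2
  expect_equal(round_half_away(63.8297, 2), 63.83)
  expect_equal(round_half_away(33.532, 1), 33.5)
})

test_that("the summary table matches the generator manifest exactly", {
  p <- pipeline_fixture()
  man <- p$data$manifest
  # undigested view over all mapped candidates
  dig_all <- digest_catalog(p$catalog, p$data$proteome)
  st <- per_chromosome_summary(p$catalog, dig_all)

  planted <- man$planted
  chrom <- setNames(man$proteins$chromosome, man$proteins$id)
  planted$chromosome <- chrom[planted$protein_id]
  for (i in seq_len(nrow(st$rows))) {
    row <- st$rows[i, ]
    cell <- planted[planted$disease == row$disease &
                      planted$chromosome == row$chromosome, ]
    expect_equal(row$n_proteins, length(unique(cell$protein_id)),
                 label = paste("proteins", row$disease, row$chromosome))
    expect_equal(row$epitopes,
                 paste(sort(unique(cell$peptide)), collapse = ","),
                 label = paste("epitopes", row$disease, row$chromosome))
    expect_equal(row$n_resistant,
                 length(unique(cell$protein_id[cell$intact])),
                 label = paste("resistant", row$disease, row$chromosome))
  }
  expect_equal(st$union_candidates, length(unique(planted$protein_id)))
})

test_that("summary totals and invariants hold", {
  p <- pipeline_fixture()
  st <- per_chromosome_summary(p$expressed, p$digest)
  for (d in st$totals$disease) {
    rows <- st$rows[st$rows$disease == d, ]
    expect_equal(sum(rows$n_proteins),
                 st$totals$n_proteins[st$totals$disease == d])
    expect_true(all(rows$n_resistant <= rows$n_proteins))
  }
  expect_lte(st$union_candidates, sum(st$totals$n_proteins))

  pct <- percentages(st)
  for (d in st$totals$disease) {
    shares <- pct$value[pct$measure == "chromosome_share" & pct$disease == d]
    expect_lte(abs(sum(shares) - 100), 0.1 * length(shares))
  }
})

test_that("one protein with both disease classes is counted in each block", {
  eps <- as_epitope_set(
    id = c("c1", "w1"), peptide = c("QQQP", "ADINNE"),
    disease = c("CD", "WA"), host = "Homo sapiens",
    is_pollen = FALSE, is_linear = TRUE
  )
  prots <- Biostrings::AAStringSet(c(Bradi1g1 = "AAAQQQPAAADINNEAAA"))
  cat_ <- map_epitopes(eps, prots)
  dig <- digest_catalog(cat_, prots)
  st <- per_chromosome_summary(cat_, dig)
  expect_equal(nrow(st$rows), 2)
  expect_equal(st$rows$n_proteins, c(1, 1))
  expect_equal(st$union_candidates, 1)
})

test_that("an empty catalog yields an all-zero summary", {
  eps <- as_epitope_set(id = "c1", peptide = "WWWWW", disease = "CD",
                        host = "Homo sapiens", is_pollen = FALSE,
                        is_linear = TRUE)
  prots <- Biostrings::AAStringSet(c(Bradi1g1 = "AAAAAAA"))
  cat_ <- map_epitopes(eps, prots)
  st <- per_chromosome_summary(cat_, digest_catalog(cat_, prots))
  expect_equal(nrow(st$rows), 0)
  expect_equal(st$union_candidates, 0)
  # zero totals give absent percentages, not zeros
  pct <- percentages(st)
  expect_equal(nrow(pct[pct$measure == "chromosome_share", ]), 0)
})

test_that("published per-chromosome counts reproduce printed percentages", {
  counts <- read_summary_counts(
    system.file("extdata", "table1_counts.tsv", package = "allerscreen")
  )
  expect_equal(counts$totals$n_proteins[counts$totals$disease == "CD"], 167)
  expect_equal(counts$totals$n_proteins[counts$totals$disease == "WA"], 47)
  expect_equal(counts$totals$n_resistant[counts$totals$disease == "CD"], 138)
  expect_equal(counts$union_candidates, 206)

  pct <- percentages(counts)
  val <- function(measure, disease, chromosome = "") {
    pct$value[pct$measure == measure & pct$disease == disease &
                pct$chromosome == chromosome]
  }
  expect_equal(val("chromosome_share", "CD", "1"), 33.5)
  expect_equal(val("chromosome_share", "CD", "2"), 21.0)
  expect_equal(val("chromosome_share", "CD", "3"), 23.4)
  expect_equal(val("chromosome_share", "WA", "1"), 23.4)
  expect_equal(val("chromosome_share", "WA", "2"), 42.6)
  expect_equal(val("digest_resistant_share", "WA"), 63.83)
  expect_equal(val("disease_share_of_candidates", "CD"), 81)
})

test_that("report rendering is deterministic and locale-independent", {
  p <- pipeline_fixture()
  st <- per_chromosome_summary(p$expressed, p$digest)
  pct <- percentages(st)
  d1 <- tempfile()
  d2 <- tempfile()
  render_report(st, pct, d1, params = list(alpha = 0.05))
  render_report(st, pct, d2, params = list(alpha = 0.05))
  for (f in c("summary.tsv", "percentages.tsv", "footnotes.txt")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), label = f)
  }
  # header-only rendering for an empty table
  empty_rows <- st
  empty_rows$rows <- st$rows[0, ]
  d3 <- tempfile()
  render_report(empty_rows, pct[0, ], d3)
  expect_length(readLines(file.path(d3, "summary.tsv")), 1)
})
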