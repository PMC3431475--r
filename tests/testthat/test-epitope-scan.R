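test_that("inclusion criteria keep human, non-pollen, linear epitopes", {
  eps <- tiny_epitopes()
  kept <- filter_epitopes(eps)
  expect_equal(kept$id, c("e1", "e2", "e4")) # pollen e3 and mouse e5 out
  expect_equal(filter_epitopes(eps, diseases = "CD")$id, c("e1", "e2"))
  expect_equal(filter_epitopes(eps, exclude_pollen = FALSE)$id,
               c("e1", "e2", "e3", "e4"))
  expect_error(filter_epitopes(eps, diseases = character(0)), "non-empty")
})

test_that("window identity counts identical positions and X matches nothing", {
  expect_equal(window_identity("IPEQ", "IPEQ"), 1.0)
  expect_equal(window_identity("IPEQ", "IPEG"), 0.75)
  expect_equal(window_identity("QQ", "XX"), 0.0)
  expect_equal(window_identity("XQ", "XQ"), 0.5) # X-X is not a match
  expect_error(window_identity("IPEQ", "IPE"), "equal-length")
})

test_that("find_matches reports every qualifying window in order", {
  m <- find_matches("QQQP", "AAQQQPAA", 1.0)
  expect_equal(m$start, 2)
  expect_equal(m$end, 6)
  expect_equal(m$identity, 1.0)

  m2 <- find_matches("IPEQ", "IPEGIPEQ", 0.75)
  expect_equal(m2$start, c(0, 4))
  expect_equal(m2$identity, c(0.75, 1.0))

  m3 <- find_matches("QQQQ", "QQQQQ", 1.0) # overlaps all reported
  expect_equal(m3$start, c(0, 1))

  expect_equal(nrow(find_matches("QQQP", "QP", 1.0)), 0)
})

test_that("scanning at threshold 1 equals exhaustive substring search", {
  withr::with_seed(101, {
    for (i in 1:300) {
      pep <- random_peptide(sample(3:8, 1), c("A", "Q", "P", "K"))
      prot <- random_peptide(sample(10:60, 1), c("A", "Q", "P", "K", "X"))
      got <- find_matches(pep, prot, 1.0)$start
      expect_identical(got, oracle_substring_starts(pep, prot),
                       label = paste(pep, prot))
    }
  })
})

test_that("sub-threshold scanning equals the exhaustive window oracle", {
  withr::with_seed(102, {
    for (i in 1:150) {
      pep <- random_peptide(sample(4:10, 1), c("A", "Q", "P", "K"))
      prot <- random_peptide(sample(12:50, 1), c("A", "Q", "P", "K", "X"))
      th <- sample(c(0.6, 0.75, 0.9, 1.0), 1)
      expect_identical(find_matches(pep, prot, th)$start,
                       oracle_window_starts(pep, prot, th),
                       label = paste(pep, prot, th))
    }
  })
})

test_that("match counts are monotone non-increasing in the threshold", {
  withr::with_seed(103, {
    for (i in 1:40) {
      pep <- random_peptide(5, c("A", "Q", "P"))
      prot <- random_peptide(60, c("A", "Q", "P"))
      counts <- vapply(c(0.4, 0.6, 0.8, 1.0), function(th) {
        nrow(find_matches(pep, prot, th))
      }, numeric(1))
      expect_true(all(diff(counts) <= 0))
    }
  })
})

test_that("conservancy is the matched-protein fraction", {
  prots <- c(a = "AAQQQPAA", b = "AAAA", c = "QQQPQQ", d = "CCCC")
  r <- conservancy("QQQP", prots)
  expect_equal(r$fraction, 0.5)
  expect_setequal(r$protein_ids, c("a", "c"))

  r0 <- conservancy("WWWW", prots)
  expect_equal(r0$fraction, 0.0)
  expect_length(r0$protein_ids, 0)

  # relaxing the threshold can only add proteins
  r75 <- conservancy("QQQP", prots, 0.75)
  expect_gte(r75$fraction, r$fraction)
  expect_error(conservancy("QQQP", character(0)), "non-empty")
})

test_that("map_epitopes builds a catalog with non-exclusive disease views", {
  eps <- as_epitope_set(
    id = c("c1", "w1"), peptide = c("QQQP", "ADINNE"),
    disease = c("CD", "WA"), host = "Homo sapiens",
    is_pollen = FALSE, is_linear = TRUE
  )
  prots <- Biostrings::AAStringSet(c(
    Bradi1g1 = "AAAQQQPAAADINNEAAA", # both diseases
    Bradi2g2 = "CCCQQQPCCC",
    scaffold_9 = "GGADINNEGG",       # no chromosome label
    Bradi3g3 = "MMMMMMMM"
  ))
  cat_ <- map_epitopes(eps, prots)
  expect_s3_class(cat_, "match_catalog")
  expect_equal(nrow(cat_$matches), 4)
  expect_setequal(candidate_proteins(cat_, "CD"), c("Bradi1g1", "Bradi2g2"))
  expect_setequal(candidate_proteins(cat_, "WA"), c("Bradi1g1", "scaffold_9"))
  expect_true("Bradi1g1" %in% candidate_proteins(cat_, "CD") &&
                "Bradi1g1" %in% candidate_proteins(cat_, "WA"))

  # unlabelled proteins stay in the catalog but not in per-chromosome views
  by_chr <- epitopes_by_chromosome(cat_)
  expect_false("scaffold_9" %in% by_chr$chromosome)
  expect_true("ADINNE" %in% cat_$matches$peptide)

  # display export is 1-based inclusive
  out <- tempfile(fileext = ".tsv")
  export_matches(cat_, out)
  tab <- read.delim(out)
  expect_equal(tab$start_1based[tab$protein_id == "Bradi1g1" &
                                  tab$peptide == "QQQP"], 4)
  expect_equal(tab$end_1based[tab$protein_id == "Bradi1g1" &
                                tab$peptide == "QQQP"], 7)
})

test_that("planted epitope recovery on synthetic data is exact", {
  p <- pipeline_fixture()
  want <- p$data$manifest$planted
  got <- p$catalog$matches
  key <- function(df) {
    df <- df[order(df$protein_id, df$peptide, df$start),
             c("protein_id", "peptide", "start", "end")]
    rownames(df) <- NULL
    df
  }
  expect_identical(key(got), key(want))
})
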