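test_that("six-frame translation follows the standard code", {
  tf <- translate_six_frames("ATGAAA")
  expect_equal(tf[["+1"]], "MK")
  expect_equal(tf[["-1"]], "FH") # reverse complement TTTCAT
  tf2 <- translate_six_frames("ATGA")
  expect_equal(tf2[["+1"]], "M")   # trailing partial codon dropped
  expect_equal(tf2[["+2"]], "*")   # TGA is a complete stop codon
  expect_equal(tf2[["+3"]], "")    # two leftover nucleotides
  expect_equal(translate_six_frames("ATGTAAAAA")[["+1"]], "M*K")
  expect_equal(translate_six_frames("ATGANAAAA")[["+1"]], "MXK")
  expect_error(translate_six_frames("ATGU"), "illegal")
})

test_that("translation agrees with a per-codon oracle on random reads", {
  withr::with_seed(301, {
    for (i in 1:100) {
      nt <- random_dna(sample(3:60, 1))
      expect_identical(translate_six_frames(nt), oracle_six_frames(nt),
                       label = nt)
    }
  })
})

test_that("frame -k equals frame +k of the reverse complement", {
  withr::with_seed(302, {
    for (i in 1:50) {
      nt <- random_dna(sample(6:60, 1))
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(nt)))
      fwd_of_rc <- translate_six_frames(rc)
      rev_of_nt <- translate_six_frames(nt)
      expect_identical(rev_of_nt[c("-1", "-2", "-3")],
                       setNames(fwd_of_rc[c("+1", "+2", "+3")],
                                c("-1", "-2", "-3")))
    }
  })
})

test_that("local alignment identity counts gaps in the denominator", {
  a <- strrep("MKVLAATEGF", 3)
  r <- local_align(a, a)
  expect_true(r$hit)
  expect_equal(r$identity, 1.0)
  expect_equal(r$aligned_cols, 30)

  # one conservative substitution inside a 60-mer forces a full-length
  # alignment with 59/60 identity
  b <- strrep("MKVLAATEGF", 6)
  bb <- paste0(substr(b, 1, 29), "R", substr(b, 31, 60)) # K -> R (+2)
  r2 <- local_align(b, bb)
  expect_equal(r2$aligned_cols, 60)
  expect_equal(r2$identity, 59 / 60)

  # all pairwise scores negative: no local alignment at all
  r3 <- local_align("GGGG", "WWWW")
  expect_false(r3$hit)
  expect_equal(r3$aligned_cols, 0)
  expect_true(is.na(r3$identity))
})

test_that("alignment scores equal a quadratic-space Gotoh reference", {
  mat <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  withr::with_seed(303, {
    for (i in 1:40) {
      a <- random_peptide(sample(10:60, 1))
      b <- random_peptide(sample(10:60, 1))
      got <- local_align(a, b)
      expect_equal(got$score, oracle_sw_score(a, b, mat),
                   label = paste(a, b))
    }
  })
})

test_that("expression calls respect threshold, coverage and comparison", {
  withr::with_seed(304, {
    prot <- random_peptide(120)
    # exact reverse-translated 60-residue segment
    seg <- substr(prot, 31, 90)
    est_exact <- reverse_translate(seg)
    r <- is_expressed(prot, c(e1 = est_exact))
    expect_true(r$expressed)
    expect_equal(r$best$identity, 1.0)

    # two substitutions in a 60-column alignment: 58/60 < 0.98
    seg2 <- seg
    substr(seg2, 20, 20) <- "A"
    substr(seg2, 40, 40) <- "G"
    if (window_identity(seg, seg2) == 58 / 60) {
      r2 <- is_expressed(prot, c(e1 = reverse_translate(seg2)))
      expect_false(r2$expressed)
    }

    # boundary: 49/50 = 0.98 accepted under >=, rejected under strict >
    seg3 <- substr(prot, 1, 50)
    seg3_mut <- seg3
    substr(seg3_mut, 25, 25) <- if (substr(seg3, 25, 25) == "A") "G" else "A"
    est3 <- reverse_translate(seg3_mut)
    r3 <- is_expressed(prot, c(e1 = est3), min_aligned = 30)
    if (!is.null(r3$best) && r3$best$aligned_cols == 50) {
      expect_equal(r3$best$identity, 49 / 50)
      expect_true(r3$expressed)
      expect_false(is_expressed(prot, c(e1 = est3), strict = TRUE)$expressed)
    }

    # coverage floor: a perfect but short hit is not evidence
    est_short <- reverse_translate(substr(prot, 10, 29))
    expect_false(is_expressed(prot, c(e1 = est_short),
                              min_aligned = 30)$expressed)
    expect_true(is_expressed(prot, c(e1 = est_short),
                             min_aligned = 10)$expressed)

    # no ESTs at all is a valid, negative outcome
    r4 <- is_expressed(prot, Biostrings::DNAStringSet())
    expect_false(r4$expressed)
    expect_null(r4$best)
  })
})

test_that("filter_expressed retains exactly the manifest's expressed set", {
  p <- pipeline_fixture()
  man <- p$data$manifest
  cand <- unique(p$catalog$matches$protein_id)
  truth <- intersect(man$proteins$id[man$proteins$expressed], cand)
  got <- p$expressed$expression$protein_id[p$expressed$expression$accepted]
  expect_setequal(got, truth)

  # decoy-only genes (5% diverged ESTs) are never retained
  decoys <- man$proteins$id[man$proteins$decoy_est]
  expect_length(intersect(got, decoys), 0)

  # an empty EST collection empties the catalog
  none <- filter_expressed(p$catalog, p$data$proteome,
                           Biostrings::DNAStringSet())
  expect_equal(nrow(none$matches), 0)
})

test_that("retained set is monotone in threshold and coverage floor", {
  p <- pipeline_fixture()
  d <- p$data
  n_at <- function(th, ma) {
    length(candidate_proteins(
      filter_expressed(p$catalog, d$proteome, d$ests, threshold = th,
                       min_aligned = ma)))
  }
  counts_th <- vapply(c(0.90, 0.98, 1.0), n_at, numeric(1), ma = 30)
  expect_true(all(diff(counts_th) <= 0))
  counts_ma <- vapply(c(10, 30, 60), function(m) n_at(0.98, m), numeric(1))
  expect_true(all(diff(counts_ma) <= 0))
})
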