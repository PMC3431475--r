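rules <- load_cleavage_rules()

test_that("rule loading validates enzymes and accepts custom tables", {
  expect_s3_class(rules, "cleavage_ruleset")
  expect_setequal(names(rules),
                  c("trypsin", "pepsin_ph1.3", "chymotrypsin_high"))
  expect_error(load_cleavage_rules(enzymes = "papain"), "unknown enzyme")

  empty <- tempfile(fileext = ".tsv")
  writeLines("enzyme\tline\tkind\tP4\tP3\tP2\tP1\tP1p\tP2p", empty)
  expect_error(load_cleavage_rules(empty), "no enzymes")

  custom <- tempfile(fileext = ".tsv")
  writeLines(c(
    "enzyme\tline\tkind\tP4\tP3\tP2\tP1\tP1p\tP2p",
    "argc_like\ta1\trequire\t-\t-\t-\tR\t-\t-"
  ), custom)
  both <- c(rules, load_cleavage_rules(custom))
  expect_length(both, 4)
  expect_equal(cleavage_sites("ARAA", structure(both["argc_like"],
                                                class = "cleavage_ruleset")),
               2)
})

test_that("hand-derived cleavage examples hold", {
  expect_equal(cleavage_sites("AKAA", rules, "trypsin"), 2)
  expect_equal(cleavage_sites("AKPA", rules, "trypsin"), integer(0))
  expect_equal(cleavage_sites("AWKPA", rules, "trypsin"), 3) # WKP cleaves
  expect_equal(cleavage_sites("AMRPA", rules, "trypsin"), 3) # MRP cleaves
  expect_equal(cleavage_sites("ACKDA", rules, "trypsin"), integer(0))
  expect_equal(cleavage_sites("ACKHA", rules, "trypsin"), integer(0))
  expect_equal(cleavage_sites("AAKHA", rules, "trypsin"), 3)
  expect_equal(cleavage_sites("ACRKA", rules, "trypsin"), 4) # CRK blocks R|K
  expect_equal(cleavage_sites("ARRHA", rules, "trypsin"), 2) # only RR|H blocked

  expect_equal(cleavage_sites("AAFAA", rules, "pepsin_ph1.3"), 3)
  expect_equal(cleavage_sites("AAAFA", rules, "pepsin_ph1.3"), 3)
  expect_equal(cleavage_sites("HAAFA", rules, "pepsin_ph1.3"), integer(0))

  expect_equal(cleavage_sites("AAYAA", rules, "chymotrypsin_high"), 3)
  expect_equal(cleavage_sites("AAYPA", rules, "chymotrypsin_high"),
               integer(0))
  expect_equal(cleavage_sites("AAWMA", rules, "chymotrypsin_high"),
               integer(0))

  # X enables nothing and blocks nothing it should not
  expect_equal(cleavage_sites("AXAA", rules), integer(0))
  expect_equal(cleavage_sites("AKXA", rules), integer(0)) # P1'=X fails ^P
})

test_that("reported digestion-resistant peptides have no cleavage sites", {
  resistant <- c("IPEQ", "AASVPE", "ADINNE", "GSQVPE", "QQPGQ", "QQPPQQ",
                 "QQQPP", "QQQP")
  for (pep in resistant) {
    expect_equal(cleavage_sites(pep, rules), integer(0), label = pep)
  }
})

test_that("peptides without K/R/F/Y/W/L are never cleaved", {
  quiet <- setdiff(c("A", "C", "D", "E", "G", "H", "I", "M", "N", "P", "Q",
                     "S", "T", "V"), character(0))
  withr::with_seed(201, {
    for (i in 1:100) {
      pep <- random_peptide(sample(4:30, 1), quiet)
      expect_equal(cleavage_sites(pep, rules), integer(0), label = pep)
    }
  })
})

test_that("engine output equals the independent per-bond regex oracle", {
  withr::with_seed(202, {
    for (i in 1:300) {
      pep <- random_peptide(sample(6:40, 1))
      expect_identical(cleavage_sites(pep, rules),
                       oracle_cleavage_sites(pep), label = pep)
      enz <- sample(names(rules), sample(1:2, 1))
      expect_identical(cleavage_sites(pep, rules, enz),
                       oracle_cleavage_sites(pep, enz),
                       label = paste(pep, paste(enz, collapse = "+")))
    }
  })
})

test_that("simultaneous digestion is the union of per-enzyme site sets", {
  withr::with_seed(203, {
    for (i in 1:150) {
      pep <- random_peptide(sample(6:40, 1))
      per_enzyme <- lapply(names(rules), function(e) {
        cleavage_sites(pep, rules, e)
      })
      expect_identical(cleavage_sites(pep, rules),
                       sort(unique(unlist(per_enzyme))), label = pep)
    }
  })
})

test_that("fragments partition the sequence exactly", {
  expect_equal(fragments("AKAA", 2), c("AK", "AA"))
  expect_equal(fragments("MKQ", integer(0)), "MKQ")
  expect_equal(fragments("ARND", c(1, 2, 3)), c("A", "R", "N", "D"))
  expect_error(fragments("ARND", 4), "out of range")
  expect_error(fragments("ARND", 0), "out of range")

  withr::with_seed(204, {
    for (i in 1:50) {
      pep <- random_peptide(sample(5:60, 1))
      bonds <- cleavage_sites(pep, rules)
      fr <- fragments(pep, bonds)
      expect_equal(paste(fr, collapse = ""), pep)
      expect_length(fr, length(bonds) + 1)
    }
  })
})

test_that("intactness is boundary-exclusive", {
  expect_true(epitope_intact(2, 6, c(1, 7)))
  expect_false(epitope_intact(2, 6, 4))
  expect_true(epitope_intact(2, 6, c(2, 6))) # boundary bonds excise whole
})

test_that("intact calls agree with the single-fragment oracle", {
  withr::with_seed(205, {
    for (i in 1:100) {
      prot <- random_peptide(sample(20:80, 1))
      bonds <- cleavage_sites(prot, rules)
      s <- sample(0:(nchar(prot) - 5), 1)
      e <- s + sample(3:5, 1)
      expect_equal(epitope_intact(s, e, bonds),
                   oracle_intact_by_fragments(prot, s, e, bonds),
                   label = paste(prot, s, e))
    }
  })
})

test_that("digest_catalog flags matches and derives resistant proteins", {
  eps <- as_epitope_set(
    id = c("c1", "c2"), peptide = c("FFQP", "IPEQ"),
    disease = c("CD", "CD"), host = "Homo sapiens",
    is_pollen = FALSE, is_linear = TRUE
  )
  prots <- Biostrings::AAStringSet(c(
    Bradi1g1 = "AAAFFQPAAA",  # chymotrypsin cuts inside FFQP
    Bradi1g2 = "AAAIPEQAAA"   # nothing cuts inside IPEQ
  ))
  cat_ <- map_epitopes(eps, prots)
  dig <- digest_catalog(cat_, prots)
  m <- dig$matches
  expect_false(m$intact[m$protein_id == "Bradi1g1"])
  expect_true(m$intact[m$protein_id == "Bradi1g2"])
  expect_equal(dig$resistant$protein_id, "Bradi1g2")

  expect_error(
    digest_catalog(cat_, prots[1]),
    "absent from the proteome"
  )
})
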