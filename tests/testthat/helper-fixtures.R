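# Shared fixtures, built in code. The synthetic dataset is generated once
# per test run and memoised; its manifest is the ground-truth oracle for the
# pipeline-level tests.

.fixture_env <- new.env(parent = emptyenv())

synthetic_fixture <- function() {
  if (is.null(.fixture_env$data)) {
    .fixture_env$data <- generate_synthetic_data(
      synthetic_config(n_proteins = 120), seed = 7
    )
  }
  .fixture_env$data
}

# The same dataset pushed through scan -> expression -> digest, memoised.
pipeline_fixture <- function() {
  if (is.null(.fixture_env$pipeline)) {
    d <- synthetic_fixture()
    kept <- filter_epitopes(d$epitopes)
    catalog <- map_epitopes(kept, d$proteome)
    expressed <- filter_expressed(catalog, d$proteome, d$ests)
    digest <- digest_catalog(expressed, d$proteome)
    .fixture_env$pipeline <- list(data = d, kept = kept, catalog = catalog,
                                  expressed = expressed, digest = digest)
  }
  .fixture_env$pipeline
}

write_epitope_fixture <- function(path, rows) {
  header <- paste(c("id", "peptide", "disease", "host", "is_pollen",
                    "is_linear", "source_protein", "source_species"),
                  collapse = "\t")
  writeLines(c("# fixture", header, rows), path)
}

tiny_epitopes <- function() {
  as_epitope_set(
    id = c("e1", "e2", "e3", "e4", "e5"),
    peptide = c("QQQP", "IPEQ", "FFQP", "AASVPE", "CRAMVK"),
    disease = c("CD", "CD", "CD", "WA", "WA"),
    host = c(rep("Homo sapiens", 4), "Mus musculus"),
    is_pollen = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    is_linear = c(TRUE, TRUE, TRUE, TRUE, TRUE)
  )
}
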