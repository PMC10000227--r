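# small study configuration used throughout: full-size generation is
# exercised once in the pipeline tests
small_config <- function(seed = 1L, ...) {
  study_config(n_wild = 60L, n_domestic = 30L, n_admixed = 12L,
               seq_length = 300L, seed = seed, ...)
}

test_that("class composition matches the configuration exactly", {
  ds <- generate_dataset(study_config(n_wild = 430L, n_domestic = 213L,
                                      n_admixed = 72L, seed = 2))
  expect_equal(as.vector(table(ds$metadata$class)[c("wild", "domestic", "admixed")]),
               c(430L, 213L, 72L))
  expect_equal(nrow(ds$alignment), 715L)
  expect_equal(ncol(ds$alignment), 669L)
  lin <- ds$truth$true_lineage_of_sample
  expect_equal(sum(lin == "D" & ds$metadata$class == "wild"),
               round(0.414 * 430))
  expect_true(all(lin[ds$metadata$class == "domestic"] == "D"))
})

test_that("zero discordance leaves every nuclear-wild sample on lineage W", {
  ds <- generate_dataset(small_config(seed = 3, discordance_fraction = 0))
  lin <- ds$truth$true_lineage_of_sample
  expect_true(all(lin[ds$metadata$class == "wild"] == "W"))
})

test_that("identical configuration and seed give byte-identical FASTA", {
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_fasta(generate_dataset(small_config(seed = 9))$alignment, f1)
  write_fasta(generate_dataset(small_config(seed = 9))$alignment, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("lineages stay separated by at least the diagnostic panel", {
  ds <- generate_dataset(small_config(seed = 4))
  lin <- ds$truth$true_lineage_of_sample
  m <- mitophylo:::.aln_int(ds$alignment)
  dm <- m[lin == "D", , drop = FALSE]
  wm <- m[lin == "W", , drop = FALSE]
  mind <- min(vapply(seq_len(nrow(dm)), function(i)
    min(colSums(t(wm) != dm[i, ])), numeric(1)))
  expect_gte(mind, ds$config$n_diagnostic_sites)
  # the panel describes the fixed differences
  pan <- ds$truth$panel
  expect_equal(nrow(pan), ds$config$n_diagnostic_sites)
  expect_true(all(pan$D != pan$W))
  for (i in seq_len(nrow(pan))) {
    expect_true(all(ds$alignment[lin == "D", pan$pos[i]] == pan$D[i]))
    expect_true(all(ds$alignment[lin == "W", pan$pos[i]] == pan$W[i]))
  }
})

test_that("every lineage keeps recoverable haplotype variation across seeds", {
  for (seed in 1:20) {
    ds <- generate_dataset(small_config(seed = 1000 + seed))
    hap <- collapse_haplotypes(ds$alignment)
    lin_of_hap <- ds$truth$true_lineage_of_haplotype
    expect_gte(sum(lin_of_hap == "D"), 2)
    expect_gte(sum(lin_of_hap == "W"), 2)
  }
})

test_that("metadata, ground truth and panel are mutually consistent", {
  ds <- generate_dataset(small_config(seed = 5))
  md <- ds$metadata
  expect_setequal(md$sample_id, rownames(ds$alignment))
  expect_setequal(names(ds$truth$true_haplotype_of_sample), md$sample_id)
  # every sub-region mapped to a scenario deme
  expect_true(all(md$sub_region %in% names(ds$truth$true_partition)))
  expect_true(all(ds$truth$true_partition %in% ds$config$scenario$demes))
  # assign_lineage on each haplotype agrees with the recorded truth
  hap <- collapse_haplotypes(ds$alignment)
  for (h in names(hap$haplotypes)) {
    got <- assign_lineage(hap$haplotypes[[h]], ds$truth$panel)$lineage
    expect_equal(got, unname(ds$truth$true_lineage_of_haplotype[h]))
  }
})

test_that("a layout cluster absent from the scenario is a structured error", {
  lay <- default_region_layout()
  lay$cluster[1] <- "c9"
  expect_error(generate_dataset(small_config(seed = 6, region_layout = lay)),
               "c9")
})

test_that("written datasets round-trip through the readers", {
  ds <- generate_dataset(small_config(seed = 7))
  dir <- tempfile("synds_")
  paths <- write_dataset(ds, dir)
  aln <- read_fasta(paths[["fasta"]])
  expect_identical(aln, ds$alignment[rownames(aln), , drop = FALSE])
  md <- read_metadata(paths[["metadata"]])
  expect_equal(md$sample_id, ds$metadata$sample_id)
  tr <- jsonlite::read_json(paths[["truth"]])
  expect_equal(length(tr$true_lineage_of_sample), nrow(ds$metadata))
})
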