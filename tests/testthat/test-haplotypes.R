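test_that("identical sequences collapse to haplotypes with exact counts", {
  aln <- as_alignment(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGA"))
  h <- collapse_haplotypes(aln)
  expect_length(h$haplotypes, 2L)
  expect_equal(sort(unname(h$counts)), c(1L, 3L))
  expect_equal(h$S, 1L)
  expect_equal(h$PI, 0L)

  # a column with states A,A,T,T is both segregating and parsimony-informative
  aln2 <- as_alignment(c(a = "AC", b = "AC", c = "TC", d = "TC"))
  h2 <- collapse_haplotypes(aln2)
  expect_equal(h2$S, 1L)
  expect_equal(h2$PI, 1L)

  expect_error(collapse_haplotypes(as_alignment(c(a = "ACG", b = "AC"))),
               "unequal")
})

test_that("haplotype count equals an independent string-set oracle", {
  aln <- mutated_family(200, 120, n_mut = 4, seed = 31)
  h <- collapse_haplotypes(aln)
  oracle <- length(unique(apply(aln, 1, paste, collapse = "")))
  expect_equal(length(h$haplotypes), oracle)
  expect_equal(sum(h$counts), 200L)
  expect_equal(sort(unname(unlist(h$carriers))), sort(rownames(aln)))
})

test_that("collapsing is idempotent and order-invariant", {
  aln <- mutated_family(60, 80, seed = 7)
  h1 <- collapse_haplotypes(aln)
  perm <- sample(nrow(aln))
  h2 <- collapse_haplotypes(aln[perm, , drop = FALSE])
  expect_equal(h1$haplotypes, h2$haplotypes)
  expect_equal(h1$counts, h2$counts)
  expect_equal(h1$S, h2$S)
  # collapsing the unique haplotypes again changes nothing (as a set:
  # canonical ids re-rank by count, which is uniform the second time)
  h3 <- collapse_haplotypes(h1$seq_matrix)
  expect_setequal(unname(h3$haplotypes), unname(h1$haplotypes))
})

test_that("carrier categories split into d / dw / w", {
  aln <- as_alignment(c(s1 = "AAAA", s2 = "AAAA", s3 = "CCCC", s4 = "GGGG",
                        s5 = "GGGG"))
  md <- data.frame(sample_id = paste0("s", 1:5),
                   class = c("domestic", "wild", "domestic", "wild", "admixed"))
  h <- collapse_haplotypes(aln, md)
  seq_of <- function(cat) unname(h$haplotypes[h$category == cat])
  expect_equal(seq_of("dw"), "AAAA")
  expect_equal(seq_of("d"), "CCCC")
  expect_equal(seq_of("w"), "GGGG")
})

test_that("haplotype diversity matches closed forms and the Nei oracle", {
  expect_equal(haplotype_diversity(c(2, 2))$Hd, 2 / 3)
  expect_equal(haplotype_diversity(c(1, 1, 1, 1))$Hd, 1.0)

  # independent direct evaluation of Nei's estimator and variance
  counts <- c(5, 3, 2)
  n <- sum(counts); p <- counts / n
  hd_o <- n * (1 - sum(p^2)) / (n - 1)
  v_o <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - sum(p^2)^2) + sum(p^2) - sum(p^2)^2)
  got <- haplotype_diversity(counts)
  expect_equal(got$Hd, hd_o, tolerance = 1e-12)
  expect_equal(got$sd, sqrt(v_o), tolerance = 1e-12)
  expect_error(haplotype_diversity(1), "fewer than 2")
})

test_that("nucleotide diversity matches the all-pairs brute force", {
  two <- as_alignment(c(a = paste(rep("A", 669), collapse = ""),
                        b = paste(c(rep("A", 668), "T"), collapse = "")))
  nd <- nucleotide_diversity(two)
  expect_equal(nd$pi, 1 / 669)
  expect_equal(nd$k, 1)

  same <- as_alignment(c(a = "ACGTACGT", b = "ACGTACGT"))
  nd0 <- nucleotide_diversity(same)
  expect_equal(nd0$pi, 0)
  expect_equal(nd0$sd, 0)

  aln <- mutated_family(30, 90, n_mut = 5, seed = 13)
  expect_equal(nucleotide_diversity(aln)$pi, pi_oracle(aln), tolerance = 1e-12)

  # k / L == pi exactly without ambiguous sites
  nd2 <- nucleotide_diversity(aln)
  expect_equal(nd2$k / nd2$L, nd2$pi, tolerance = 1e-12)
})

test_that("sequences with N collapse only on exact identity and pairs skip N sites", {
  aln <- as_alignment(c(a = "ACGN", b = "ACGN", c = "ACGT"))
  h <- collapse_haplotypes(aln)
  expect_length(h$haplotypes, 2L)
  # pairwise deletion: a vs c compares only first three (identical) sites
  nd <- nucleotide_diversity(as_alignment(c(a = "ACGN", b = "ACGT")))
  expect_equal(nd$pi, 0)
})

test_that("diversity table mirrors the per-group layout", {
  aln <- mutated_family(40, 60, seed = 3)
  grp <- rep(c("north", "south"), each = 20)
  tab <- diversity_table(aln, grp)
  expect_setequal(tab$group, c("overall", "north", "south"))
  expect_equal(tab$N[tab$group == "overall"], 40L)
  expect_equal(tab$pi_x100, 100 * tab$pi)
})
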