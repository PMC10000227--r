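test_that("Tajima's D matches an independent transliteration of the formula", {
  aln <- as_alignment(c(a = "AAAAAAAAAA", b = "AAAAAAAAAT",
                        c = "AAAAAAAATT", d = "AAAAATAATT"))
  got <- tajimas_d(aln)
  expect_true(got$defined)
  expect_equal(got$D, tajima_oracle(got$n, got$S, got$k), tolerance = 1e-12)

  for (seed in 1:5) {
    aln2 <- mutated_family(12, 60, n_mut = 3, seed = 200 + seed)
    g <- tajimas_d(aln2)
    if (g$defined)
      expect_equal(g$D, tajima_oracle(g$n, g$S, g$k), tolerance = 1e-10)
  }
})

test_that("no variation leaves the statistics undefined and flagged", {
  mono <- as_alignment(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT"))
  td <- tajimas_d(mono)
  expect_false(td$defined)
  expect_true(is.na(td$D))
  fl <- fu_li(mono)
  expect_false(fl$defined)
  expect_true(is.na(fl$D_star))
})

test_that("Fu & Li starred statistics match the oracle and go negative on stars", {
  # star-like: every segregating site is a singleton
  L <- 60
  root <- rep("A", L)
  seqs <- vapply(1:6, function(i) {
    s <- root; s[i * 5] <- "T"; paste(s, collapse = "")
  }, character(1))
  aln <- as_alignment(stats::setNames(seqs, paste0("s", 1:6)))
  fl <- fu_li(aln)
  expect_equal(fl$eta_s, fl$eta)          # all mutations are singletons
  expect_lt(fl$D_star, 0)
  expect_lt(fl$F_star, 0)
  o <- fu_li_oracle(fl$n, fl$eta, fl$eta_s, fl$k)
  expect_equal(fl$D_star, o[["D_star"]], tolerance = 1e-12)
  expect_equal(fl$F_star, o[["F_star"]], tolerance = 1e-12)
})

test_that("outgroup-based Fu & Li D and F use derived singletons", {
  aln <- as_alignment(c(a = "AAAAAAAAAT", b = "AAAAAAAAAA", c = "AAAATAAAAA",
                        d = "AAAAAAAAAA"))
  fl <- fu_li(aln, outgroup = "AAAAAAAAAA")
  expect_equal(fl$eta_e, 2L)              # both variants absent in the outgroup
  expect_true(is.finite(fl$D) && is.finite(fl$F))
  expect_error(fu_li(aln, outgroup = "AAA"), "length")
})

test_that("statistics are invariant to sequence order and site relabeling", {
  aln <- mutated_family(15, 80, n_mut = 4, seed = 55)
  t1 <- tajimas_d(aln)
  perm <- sample(nrow(aln))
  t2 <- tajimas_d(aln[perm, , drop = FALSE])
  expect_equal(t1$D, t2$D, tolerance = 1e-12)
  cperm <- sample(ncol(aln))
  t3 <- tajimas_d(aln[, cperm, drop = FALSE])
  expect_equal(t1$D, t3$D, tolerance = 1e-12)
  f1 <- fu_li(aln); f2 <- fu_li(aln[perm, , drop = FALSE])
  expect_equal(f1$F_star, f2$F_star, tolerance = 1e-12)
})

test_that("mismatch distribution conserves the pair count", {
  two <- as_alignment(c(a = "AAATTT", b = "AAAAAA"))
  mm <- mismatch_distribution(two)
  expect_equal(unname(mm$histogram[["3"]]), 1)
  expect_equal(sum(mm$histogram), 1)

  aln <- mutated_family(14, 50, n_mut = 4, seed = 66)
  mm2 <- mismatch_distribution(aln)
  expect_equal(sum(mm2$histogram), choose(14, 2))
  expect_gte(mm2$raggedness, 0)
  expect_equal(raggedness(as.numeric(mm2$histogram)), mm2$raggedness,
               tolerance = 1e-12)
})

test_that("expansion-like genealogies are smoother than constant-size ones", {
  # star genealogy (simultaneous coalescence) vs constant size at equal theta
  set.seed(91)
  L <- 300; n <- 20
  star_r <- replicate(40, {
    root <- sample.int(4, L, replace = TRUE)
    m <- matrix(rep(root, n), nrow = n, byrow = TRUE)
    for (i in seq_len(n)) {
      k <- stats::rpois(1, 3)
      if (k > 0) for (p in sample.int(L, min(k, L)))
        m[i, p] <- sample(setdiff(1:4, m[i, p]), 1)
    }
    aln <- as_alignment(stats::setNames(
      apply(matrix(c("A", "C", "G", "T")[m], nrow = n), 1, paste, collapse = ""),
      paste0("s", 1:n)))
    mismatch_distribution(aln)$raggedness
  })
  dem <- demography(sizes = c(p = 5000))
  mut <- mutation_model(L = L, mu = 6 / (2 * 5000 * L), gamma_shape = NULL)
  const_r <- replicate(40, {
    sim <- simulate_coalescent(dem, c(p = n), mut)
    mismatch_distribution(sim_to_alignment(sim))$raggedness
  })
  expect_lt(stats::median(star_r), stats::median(const_r))
})

test_that("simulation p-values are valid and reusable across datasets", {
  set.seed(17)
  dem <- demography(sizes = c(p = 8000))
  mut <- mutation_model(L = 200, mu = 4 / (2 * 8000 * 200), gamma_shape = NULL)
  aln <- sim_to_alignment(simulate_coalescent(dem, c(p = 12), mut))
  null <- simulate_null_stats("tajima_d", n = 12, theta = 4, L = 200,
                              n_sims = 300, seed = 9)
  out <- neutrality_test(aln, "tajima_d", theta = 4, null_stats = null)
  expect_true(out$p >= 0 && out$p <= 1)
  out2 <- neutrality_test(aln, "tajima_d", theta = 4, null_stats = null)
  expect_equal(out$p, out2$p)             # shared null is deterministic
  mono <- as_alignment(c(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAA"))
  expect_false(neutrality_test(mono, "tajima_d", n_sims = 10)$defined)
})
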