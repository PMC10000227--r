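test_that("identical seed and configuration reproduce the simulation exactly", {
  dem1 <- demography(sizes = c(p = 2000))
  mut <- mutation_model(L = 300, mu = 1e-6)
  s1 <- simulate_coalescent(dem1, c(p = 8), mut, seed = 77)
  s2 <- simulate_coalescent(dem1, c(p = 8), mut, seed = 77)
  expect_identical(s1$seqs, s2$seqs)
  expect_identical(s1$tmrca, s2$tmrca)

  dem2 <- demography(sizes = c(a = 1000, b = 1000, anc = 1000),
                     events = list(ev_merge(500, "a", "anc"),
                                   ev_merge(500, "b", "anc")))
  t1 <- simulate_coalescent(dem2, c(a = 4, b = 4), mut, seed = 5)
  t2 <- simulate_coalescent(dem2, c(a = 4, b = 4), mut, seed = 5)
  expect_identical(t1$seqs, t2$seqs)
})

test_that("one-deme expectations match coalescent theory", {
  set.seed(41)
  N <- 1500; L <- 400; mu <- 2e-6
  dem <- demography(sizes = c(p = N))
  mut <- mutation_model(L = L, mu = mu, gamma_shape = NULL)
  k <- replicate(1500, mean_pairwise_differences(
    simulate_coalescent(dem, c(p = 2), mut)))
  se <- stats::sd(k) / sqrt(length(k))
  expect_lt(abs(mean(k) - 2 * N * mu * L), 4 * se)

  tm <- replicate(1500, simulate_coalescent(dem, c(p = 10), NULL)$tmrca)
  se_t <- stats::sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 2 * N * (1 - 1 / 10)), 4 * se_t)
})

test_that("two demes merging at time zero behave panmictically", {
  set.seed(42)
  dem <- demography(sizes = c(a = 1000, b = 1000, anc = 1000),
                    events = list(ev_merge(0, "a", "anc"),
                                  ev_merge(0, "b", "anc")))
  mut <- mutation_model(L = 400, mu = 3e-6, gamma_shape = NULL)
  phis <- replicate(150, {
    sim <- simulate_coalescent(dem, c(a = 6, b = 6), mut)
    unname(summary_stats(sim$seqs, sim$deme)["a.b_phist"])
  })
  expect_lt(abs(mean(phis)), 0.05)
})

test_that("admixture events route lineages to both donors", {
  set.seed(43)
  dem <- demography(sizes = c(a = 500, b = 500, c = 500, anc = 500),
                    events = list(ev_admixture(100, "c", "a", "b", 0.5),
                                  ev_merge(5000, "a", "anc"),
                                  ev_merge(5000, "b", "anc")))
  mut <- mutation_model(L = 300, mu = 2e-6, gamma_shape = NULL)
  sim <- simulate_coalescent(dem, c(a = 5, b = 5, c = 5), mut)
  expect_equal(sum(sim$deme == "c"), 5L)
  expect_true(is.finite(sim$tmrca) && sim$tmrca > 100)
  expect_error(ev_admixture(100, "c", "a", "b", 1.2), "proportion")
})

test_that("malformed scenarios fail loudly", {
  dem <- demography(sizes = c(a = 100, b = 100))
  expect_error(simulate_coalescent(dem, c(a = 2, b = 2), NULL),
               "stranded")
  expect_error(simulate_coalescent(dem, c(a = 2, zz = 2), NULL),
               "unknown deme")
  expect_error(demography(sizes = c(a = 100),
                          events = list(ev_merge(10, "a", "xx"))),
               "unknown deme")
  expect_error(demography(sizes = c(-5)), "named")
})

test_that("masked sites never mutate and the root sequence is respected", {
  root <- paste(rep(c("A", "C", "G", "T"), 25), collapse = "")
  mask <- c(3L, 50L, 97L)
  dem <- demography(sizes = c(p = 5000))
  mut <- mutation_model(L = 100, mu = 2e-4, root = root, site_mask = mask)
  root_int <- mitophylo:::.aln_int(as_alignment(c(r = root)))[1, ]
  for (seed in 1:5) {
    sim <- simulate_coalescent(dem, c(p = 6), mut, seed = seed)
    expect_true(all(sim$seqs[, mask] ==
                      matrix(root_int[mask], 6, 3, byrow = TRUE)))
  }
})

test_that("gamma site rates concentrate mutations on fast sites", {
  # with a tiny shape, site rates are extremely skewed: most mutations
  # should recur at few sites, giving fewer distinct polymorphic columns
  set.seed(60)
  dem <- demography(sizes = c(p = 5000))
  mut_flat <- mutation_model(L = 500, mu = 1e-5, gamma_shape = NULL)
  mut_skew <- mutation_model(L = 500, mu = 1e-5, gamma_shape = 0.05)
  cols <- function(mm) mean(replicate(60, {
    sim <- simulate_coalescent(dem, c(p = 10), mm)
    mitophylo:::.site_counts(sim$seqs)$S
  }))
  expect_lt(cols(mut_skew), cols(mut_flat))
})
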