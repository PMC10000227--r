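test_that("summary statistics agree with the haplotype/diversity modules", {
  aln <- mutated_family(20, 120, n_mut = 4, seed = 14)
  deme <- rep("a", 20)
  st <- summary_stats(mitophylo:::.aln_int(aln), deme)
  hap <- collapse_haplotypes(aln)
  nd <- nucleotide_diversity(aln)
  hd <- haplotype_diversity(hap$counts)
  expect_equal(unname(st["a_nhap"]), length(hap$haplotypes))
  expect_equal(unname(st["a_S"]), hap$S)
  expect_equal(unname(st["a_Hd"]), hd$Hd, tolerance = 1e-12)
  expect_equal(unname(st["a_pi"]), nd$pi, tolerance = 1e-12)
  td <- tajimas_d(aln)
  expect_equal(unname(st["a_tajD"]), td$D, tolerance = 1e-12)
})

test_that("degenerate demes and fixed differences hit the boundary values", {
  m <- mitophylo:::.aln_int(as_alignment(
    c(a1 = "AAAA", a2 = "AAAA", a3 = "AAAA", b1 = "TTTT", b2 = "TTTT")))
  st <- summary_stats(m, c("a", "a", "a", "b", "b"))
  expect_equal(unname(st["a_nhap"]), 1)
  expect_equal(unname(st["a_S"]), 0)
  expect_equal(unname(st["a_Hd"]), 0)
  expect_equal(unname(st["a_pi"]), 0)
  expect_equal(unname(st["a_tajD"]), 0)   # masked-to-zero convention
  expect_equal(unname(st["a.b_phist"]), 1)
  expect_false(any(!is.finite(st)))
})

test_that("identical scenarios get symmetric posteriors that sum to one", {
  dup <- builtin_scenarios("DW")["dw1_recent_simultaneous"]
  twins <- list(s_one = dup[[1]], s_two = dup[[1]])
  twins$s_one$name <- "s_one"; twins$s_two$name <- "s_two"
  mut <- mutation_model(L = 300, mu = 5e-7, gamma_shape = NULL)
  sizes <- c(sco = 5, ibe = 5, eur = 8)
  ref <- abc_reference_table(twins, 400, sizes, mut, seed = 21)
  obs_sim <- simulate_coalescent(
    twins$s_one$build(c(Nsco = 5000, Nibe = 5000, Neur = 5000, Nanc = 5000,
                        t = 2000)), sizes, mut, seed = 33)
  obs <- summary_stats(obs_sim$seqs, obs_sim$deme)
  mc <- abc_model_choice(obs, ref = ref, keep = 0.05, seed = 3)
  expect_equal(sum(mc$posterior), 1, tolerance = 1e-9)
  expect_equal(sum(mc$rejection), 1, tolerance = 1e-9)
  expect_lt(abs(mc$rejection[["s_one"]] - 0.5), 0.25)
})

test_that("parameter posteriors respect prior bounds and year conversion", {
  sc <- builtin_scenarios("DW")$dw1_recent_simultaneous
  mut <- mutation_model(L = 300, mu = 5e-7, gamma_shape = NULL)
  sizes <- c(sco = 5, ibe = 5, eur = 8)
  ref <- abc_reference_table(stats::setNames(list(sc), sc$name), 500, sizes,
                             mut, seed = 8)
  obs_sim <- simulate_coalescent(
    sc$build(c(Nsco = 5000, Nibe = 5000, Neur = 5000, Nanc = 5000, t = 2500)),
    sizes, mut, seed = 12)
  obs <- summary_stats(obs_sim$seqs, obs_sim$deme)
  pp <- abc_parameter_posterior(obs, sc, ref = ref, keep = 0.05, seed = 2)
  for (i in seq_len(nrow(pp$summary))) {
    b <- sc$priors[[pp$summary$parameter[i]]]
    expect_gte(pp$summary$q5[i], b[1])
    expect_lte(pp$summary$q95[i], b[2])
    expect_true(pp$summary$q5[i] <= pp$summary$median[i] &&
                  pp$summary$median[i] <= pp$summary$q95[i])
  }
  tt <- pp$summary[pp$summary$parameter == "t", ]
  expect_equal(tt$median_years, tt$median * 2)   # 2 years per generation
})

test_that("posterior predictive checks report bounded, Bonferroni-adjusted p", {
  sc <- builtin_scenarios("DW")$dw1_recent_simultaneous
  mut <- mutation_model(L = 300, mu = 5e-7, gamma_shape = NULL)
  sizes <- c(sco = 5, ibe = 5, eur = 8)
  ref <- abc_reference_table(stats::setNames(list(sc), sc$name), 300, sizes,
                             mut, seed = 44)
  obs_sim <- simulate_coalescent(
    sc$build(c(Nsco = 4000, Nibe = 4000, Neur = 4000, Nanc = 4000, t = 2000)),
    sizes, mut, seed = 45)
  obs <- summary_stats(obs_sim$seqs, obs_sim$deme)
  pp <- abc_parameter_posterior(obs, sc, ref = ref, keep = 0.1, seed = 46)
  ck <- posterior_predictive_check(sc, pp, obs, n_draws = 60,
                                   sample_sizes = sizes, mut = mut, seed = 47)
  expect_true(all(ck$p >= 0 & ck$p <= 1))
  expect_true(all(ck$p_bonferroni >= ck$p - 1e-12))
  expect_type(ck$flagged, "logical")
})

test_that("built-in scenario libraries have the documented structure", {
  w <- builtin_scenarios("W")
  dw <- builtin_scenarios("DW")
  expect_length(w, 4L)
  expect_length(dw, 3L)
  for (sc in c(w, dw)) expect_true(validate_scenario(sc))
  # simultaneous scenario: one shared split time; sequential: three ordered
  expect_true("t" %in% names(w$w2_simultaneous$priors))
  expect_false("t1" %in% names(w$w2_simultaneous$priors))
  expect_true(all(c("t1", "t2", "t3") %in% names(w$w1_sequential$priors)))
  X <- sample_priors(w$w1_sequential, 200, seed = 6)
  expect_true(all(X[, "t1"] < X[, "t2"] & X[, "t2"] < X[, "t3"]))
  for (p in colnames(X)) {
    b <- w$w1_sequential$priors[[p]]
    expect_true(all(X[, p] >= b[1] & X[, p] <= b[2]))
  }
  # the admixture scenario routes cluster 4 through clusters 1 and 2
  dem <- w$w4_simultaneous_admix$build(
    c(N1 = 1000, N2 = 1000, N3 = 1000, N4 = 1000, Nanc = 1000,
      t_adm = 100, t = 5000, ra = 0.5))
  types <- vapply(dem$events, `[[`, character(1), "type")
  expect_equal(sum(types == "admixture"), 1L)
})

test_that("reference tables are reproducible and well-formed", {
  sc <- builtin_scenarios("DW")[c("dw1_recent_simultaneous", "dw2_sequential")]
  mut <- mutation_model(L = 200, mu = 1e-6, gamma_shape = NULL)
  sizes <- c(sco = 4, ibe = 4, eur = 6)
  r1 <- abc_reference_table(sc, 50, sizes, mut, seed = 10)
  r2 <- abc_reference_table(sc, 50, sizes, mut, seed = 10)
  expect_identical(r1$stats, r2$stats)
  expect_equal(nrow(r1$stats), 100L)
  expect_equal(table(r1$scenario)[["dw2_sequential"]], 50L)
  expect_false(any(!is.finite(r1$stats)))
})
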