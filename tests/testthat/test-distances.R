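test_that("K80 closed form matches independent evaluation", {
  expect_equal(k80_distance("ACGTACGT", "ACGTACGT")$d, 0)

  # direct evaluation of -0.5 ln(1-2P-Q) - 0.25 ln(1-2Q)
  got <- k80_from_pq(0.1, 0.05)
  expect_equal(got$d, -0.5 * log(1 - 0.2 - 0.05) - 0.25 * log(1 - 0.1),
               tolerance = 1e-12)
  expect_equal(round(got$d, 5), 0.17018)

  sat <- k80_from_pq(0.5, 0)
  expect_true(sat$saturated)
  expect_false(is.finite(sat$d))
})

test_that("K80 distance matrix agrees with the ape reference", {
  aln <- mutated_family(12, 300, n_mut = 8, seed = 5)
  D <- dist_model(aln, "K80")
  Dref <- as.matrix(ape::dist.dna(ape::as.DNAbin(
    matrix(tolower(aln), nrow = nrow(aln),
           dimnames = list(rownames(aln), NULL))), model = "K80",
    pairwise.deletion = TRUE))
  expect_equal(unname(D), unname(Dref[rownames(D), colnames(D)]),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("NJ recovers an additive four-taxon tree exactly", {
  # tree ((a:2,b:3):1,(c:4,d:5)) -> additive distances
  lab <- c("a", "b", "c", "d")
  D <- matrix(0, 4, 4, dimnames = list(lab, lab))
  D["a", "b"] <- D["b", "a"] <- 5
  D["a", "c"] <- D["c", "a"] <- 7
  D["a", "d"] <- D["d", "a"] <- 8
  D["b", "c"] <- D["c", "b"] <- 8
  D["b", "d"] <- D["d", "b"] <- 9
  D["c", "d"] <- D["d", "c"] <- 9
  tr <- nj_tree(D)
  # generating topology recovered ...
  truth <- ape::read.tree(text = "((a:2,b:3):1,(c:4,d:5):0);")
  expect_equal(ape::dist.topo(ape::unroot(truth), ape::unroot(tr)), 0,
               ignore_attr = TRUE)
  # ... with exact branch lengths (total and per-tip path a-b, c-d)
  expect_equal(sum(tr$edge.length), 15)
  ct <- ape::cophenetic.phylo(tr)
  expect_equal(unname(ct[lab, lab]), unname(D), tolerance = 1e-12)
})

test_that("three-taxon NJ solves the linear branch equations", {
  lab <- c("x", "y", "z")
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, dimnames = list(lab, lab))
  tr <- nj_tree(D)
  # d(xy)=3, d(xz)=4, d(yz)=5 -> branches x=1, y=2, z=3
  bl <- stats::setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                        tr$tip.label)
  expect_equal(bl[["x"]], 1)
  expect_equal(bl[["y"]], 2)
  expect_equal(bl[["z"]], 3)
})

test_that("non-finite distances abort with the offending pair named", {
  lab <- c("a", "b", "c")
  D <- matrix(0, 3, 3, dimnames = list(lab, lab))
  D["a", "b"] <- D["b", "a"] <- NaN
  D["a", "c"] <- D["c", "a"] <- 1
  D["b", "c"] <- D["c", "b"] <- 1
  expect_error(nj_tree(D), "a~b")
})

test_that("bootstrap support is unanimous when every site backs one split", {
  base <- rep("A", 40)
  a <- base; b <- base; c2 <- base; d <- base
  c2[1:6] <- "G"; d[1:6] <- "G"       # six transition sites back ab | cd
  b[39] <- "C"; d[40] <- "C"          # private sites keep tips distinct
  aln <- as_alignment(c(a = paste(a, collapse = ""), b = paste(b, collapse = ""),
                        c = paste(c2, collapse = ""), d = paste(d, collapse = "")))
  tr <- nj_tree(dist_model(aln, "K80"))
  supp <- bootstrap_support(aln, tree = tr, B = 100, seed = 4)
  # the single internal edge (ab | cd) must appear in every replicate
  expect_equal(max(supp, na.rm = TRUE), 1.0)
})

test_that("NJ on ultrametric distances matches the UPGMA topology", {
  set.seed(11)
  true <- ape::rcoal(8)
  D <- ape::cophenetic.phylo(true)
  tr <- nj_tree(D)
  up <- phangorn::upgma(stats::as.dist(D))
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(up)), 0,
               ignore_attr = TRUE)
})

test_that("clock dating gives t = d/(2r) against an ape-based oracle", {
  aln <- mutated_family(10, 400, n_mut = 6, seed = 21)
  ga <- rownames(aln)[1:5]; gb <- rownames(aln)[6:10]
  rate <- 2.28e-8
  got <- clock_date_split(aln, ga, gb, rate = rate, n_boot = 0)
  Dref <- as.matrix(ape::dist.dna(ape::as.DNAbin(
    matrix(tolower(aln), nrow = nrow(aln),
           dimnames = list(rownames(aln), NULL))), model = "K80",
    pairwise.deletion = TRUE))
  d_oracle <- mean(Dref[ga, gb])
  expect_equal(got$d_mean, d_oracle, tolerance = 1e-10)
  expect_equal(got$age, d_oracle / (2 * rate), tolerance = 1e-10)

  # doubling the rate halves every age exactly; zero divergence dates to 0
  got2 <- clock_date_split(aln, ga, gb, rate = 2 * rate, n_boot = 0)
  expect_equal(got2$age, got$age / 2, tolerance = 1e-12)
  same <- as_alignment(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_equal(clock_date_split(same, "a", "b", rate, n_boot = 0)$age, 0)
})

test_that("root calibration rescales to the interval midpoint", {
  ages <- c(100000, 60000, 20000)
  out <- calibrate_root(ages, 173000, 230000)
  expect_equal(out[[1]], 201500)
  expect_equal(attr(out, "calibration")$factor, 2.015)
  expect_error(calibrate_root(ages, 230000, 173000), "t_min")
})

test_that("calibration preserves relative node depths on a dated tree", {
  aln <- mutated_family(8, 500, n_mut = 10, seed = 33)
  tr <- root_tree(nj_tree(dist_model(aln, "K80")))
  dated <- clock_date_tree(tr, aln, rate = 2.28e-8)
  cal <- calibrate_root(dated, 173000, 230000)
  pos <- dated$ages > 0
  expect_equal(unname(cal$ages[pos] / dated$ages[pos]),
               rep(cal$calibration$factor, sum(pos)), tolerance = 1e-12)
  ntip <- length(tr$tip.label)
  expect_equal(cal$ages[[as.character(ntip + 1)]], (173000 + 230000) / 2,
               tolerance = 1e-9)
  # dated tree is age-monotone: every parent at least as old as its children
  for (nd in as.integer(names(cal$ages))) {
    ch <- tr$edge[tr$edge[, 1] == nd, 2]
    ch <- ch[ch > ntip]
    if (length(ch))
      expect_true(all(cal$ages[as.character(ch)] <=
                        cal$ages[[as.character(nd)]] + 1e-9))
  }
})
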