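test_that("a star triplet yields its quasi-median with three unit edges", {
  net <- mj_network(c(h1 = "AAT", h2 = "ATA", h3 = "TAA"), epsilon = 0,
                    weights = c(ts = 1, tv = 1))
  med <- net$nodes$id[net$nodes$type == "median"]
  expect_length(med, 1L)
  expect_equal(paste(c("N", "A", "C", "G", "T")[net$seqs[med, ] + 1],
                     collapse = ""), "AAA")
  expect_equal(nrow(net$edges), 3L)
  expect_true(all(net$edges$cost == 1))
  expect_setequal(c(net$edges$from, net$edges$to),
                  c("h1", "h2", "h3", med, med, med))
})

test_that("two haplotypes give one weighted edge and no medians", {
  # A->G transition (x2) costs 1 each, A->T transversion costs 3
  net <- mj_network(c(a = "AAAA", b = "GGTA"), epsilon = 5,
                    weights = c(ts = 1, tv = 3))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$cost, 5)
  expect_equal(net$edges$n_sites, 3L)
  expect_equal(sum(net$nodes$type == "median"), 0L)
})

test_that("the epsilon=0 network contains a minimum spanning tree", {
  for (seed in c(2, 9, 17)) {
    aln <- mutated_family(8, 30, n_mut = 4, seed = seed)
    hap <- collapse_haplotypes(aln)
    m <- mitophylo:::.aln_int(hap$seq_matrix)
    D <- mitophylo:::.wdist_matrix(m, c(ts = 1, tv = 1))
    ed <- msn_edges(D, epsilon = 0)
    H <- nrow(m)
    # oracle MST weight on the complete graph
    gfull <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                                 weighted = TRUE)
    w_full <- sum(igraph::E(igraph::mst(gfull))$weight)
    # MST restricted to MSN edges must reach the same weight (and span)
    gmsn <- igraph::graph_from_data_frame(
      data.frame(from = ed[, 1], to = ed[, 2], weight = D[ed]),
      directed = FALSE, vertices = data.frame(name = as.character(1:H)))
    mst_msn <- igraph::mst(gmsn)
    expect_true(igraph::is_connected(gmsn))
    expect_equal(sum(igraph::E(mst_msn)$weight), w_full)
  }
})

test_that("network construction is invariant to haplotype input order", {
  seqs <- c(a = "AATTC", b = "AATAC", c = "TATAC", d = "AACTC", e = "GATTC")
  n1 <- mj_network(seqs, epsilon = 1, weights = c(ts = 1, tv = 2))
  n2 <- mj_network(seqs[c(3, 5, 1, 4, 2)], epsilon = 1, weights = c(ts = 1, tv = 2))
  key <- function(n) {
    ed <- n$edges
    sort(paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to), ed$cost))
  }
  expect_equal(key(n1), key(n2))
  expect_equal(sort(n1$nodes$id), sort(n2$nodes$id))
})

test_that("median vectors keep degree >= 3 after cleanup", {
  aln <- mutated_family(10, 40, n_mut = 5, seed = 12)
  net <- mj_network(collapse_haplotypes(aln), epsilon = 2,
                    weights = c(ts = 1, tv = 3))
  deg <- table(factor(c(net$edges$from, net$edges$to),
                      levels = net$nodes$id))
  med <- net$nodes$id[net$nodes$type == "median"]
  if (length(med)) expect_true(all(deg[med] >= 3))
  # every observed haplotype present and connected
  obs <- net$nodes$id[net$nodes$type == "observed"]
  expect_true(all(obs %in% c(net$edges$from, net$edges$to)))
})

test_that("edge costs equal the summed site weights over differing sites", {
  aln <- mutated_family(8, 25, n_mut = 3, seed = 40)
  wts <- c(ts = 1, tv = 3)
  net <- mj_network(collapse_haplotypes(aln), epsilon = 4, weights = wts)
  for (e in seq_len(nrow(net$edges))) {
    u <- net$seqs[net$edges$from[e], ]
    v <- net$seqs[net$edges$to[e], ]
    expect_equal(net$edges$cost[e], mitophylo:::.whamming(u, v, wts))
  }
  expect_error(mj_network(c(a = "AC", b = "AG"), epsilon = -1), "epsilon")
})

test_that("diagnostic panels assign lineages and flag conflicts", {
  panel <- data.frame(pos = c(2, 5, 8), D = c("A", "C", "G"),
                      W = c("T", "T", "T"))
  expect_equal(assign_lineage("CTGGTCCTC", panel)$lineage, "W")
  expect_equal(assign_lineage("CAGGCCCGC", panel)$lineage, "D")
  mix <- assign_lineage("CAGGTCCGC", panel)    # 2 D-state + 1 W-state
  expect_equal(mix$lineage, "conflict")
  expect_equal(nrow(mix$states), 3L)
  amb <- assign_lineage("CNGGCCCGC", panel)
  expect_equal(amb$lineage, "conflict")
  expect_equal(amb$reason, "ambiguous")
  expect_error(assign_lineage("CA", panel), "cover")
  bad <- data.frame(pos = c(1, 1), D = c("A", "C"), W = c("T", "T"))
  expect_error(assign_lineage("ACGT", bad), "unique")
})

test_that("GML and edge-list exports round-trip the network structure", {
  net <- mj_network(c(h1 = "AAT", h2 = "ATA", h3 = "TAA"), epsilon = 0,
                    weights = c(ts = 1, tv = 1))
  gml <- tempfile(fileext = ".gml")
  tsv <- tempfile(fileext = ".tsv")
  write_gml(net, gml)
  write_edge_list(net, tsv)
  txt <- readLines(gml)
  expect_equal(sum(grepl("^  node \\[", txt)), nrow(net$nodes))
  expect_equal(sum(grepl("^  edge \\[", txt)), nrow(net$edges))
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(net$edges))
})
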