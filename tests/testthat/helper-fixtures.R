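# shared fixture builders (everything generated in code; no data files)

random_alignment <- function(n, L, seed = NULL, ids = sprintf("s%03d", seq_len(n))) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), nrow = n)
  rownames(m) <- ids
  as_alignment(m)
}

# n sequences derived from one root with a few random substitutions each:
# realistic low-diversity mtDNA-like data
mutated_family <- function(n, L, n_mut = 3L, seed = NULL,
                           ids = sprintf("s%03d", seq_len(n))) {
  if (!is.null(seed)) set.seed(seed)
  root <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  m <- matrix(rep(root, n), nrow = n, byrow = TRUE)
  for (i in seq_len(n)) {
    k <- sample.int(n_mut + 1L, 1L) - 1L
    if (k > 0L) {
      pos <- sample.int(L, k)
      for (p in pos) m[i, p] <- sample(setdiff(c("A", "C", "G", "T"), m[i, p]), 1L)
    }
  }
  rownames(m) <- ids
  as_alignment(m)
}

# pop-level haplotype data with a known cluster structure: each cluster has
# its own dominant haplotype set, populations draw mostly from their
# cluster's set with a little shared noise
clustered_pops <- function(n_pops, k_true, n_per_pop = 6L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cl <- sort(rep_len(seq_len(k_true), n_pops))
  L <- 40L
  base <- random_alignment(k_true + 1L, L, ids = paste0("hseed", seq_len(k_true + 1L)))
  # cluster haplotypes: 12+ fixed differences between clusters, noise shared
  haps <- character(0)
  for (c2 in seq_len(k_true)) {
    h <- base[c2, ]
    haps <- c(haps, paste(h, collapse = ""))
    h2 <- h; h2[1:2] <- ifelse(h2[1:2] == "A", "C", "A")
    haps <- c(haps, paste(h2, collapse = ""))
  }
  shared <- paste(base[k_true + 1L, ], collapse = "")
  hap_ids <- c(paste0("h", seq_along(haps)), "shared")
  hap_seqs <- stats::setNames(c(haps, shared), hap_ids)
  pop <- rep(sprintf("p%02d", seq_len(n_pops)), each = n_per_pop)
  hap <- character(length(pop))
  for (i in seq_len(n_pops)) {
    own <- hap_ids[c(2L * cl[i] - 1L, 2L * cl[i])]
    draw <- sample(c(own, "shared"), n_per_pop, replace = TRUE,
                   prob = c(0.55, 0.3, 0.15))
    hap[pop == sprintf("p%02d", i)] <- draw
  }
  coords <- cbind(lon = cl * 10 + stats::runif(n_pops, -2, 2),
                  lat = cl * 5 + stats::runif(n_pops, -2, 2))
  rownames(coords) <- sprintf("p%02d", seq_len(n_pops))
  list(hap = hap, pop = pop, coords = coords, cluster = cl,
       d2 = hap_diff_squared(as_alignment(hap_seqs)))
}

# pop-level data with k_true crisp clusters. By default every population
# carries a fixed mix of its cluster's private haplotype plus a shared
# cosmopolitan one, so populations within a cluster are exchangeable and
# the true K is exactly k_true; with deterministic = FALSE compositions
# are drawn multinomially instead (noisier realized structure).
clustered_clean <- function(n_pops, k_true, n_per_pop = 20L, seed = NULL,
                            purity = 0.9, deterministic = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  cl <- sort(rep_len(seq_len(k_true), n_pops))
  L <- 40L
  base <- matrix(sample(c("A", "C", "G", "T"), (k_true + 1L) * L,
                        replace = TRUE), nrow = k_true + 1L)
  haps <- apply(base, 1L, paste, collapse = "")
  hap_ids <- c(paste0("h", seq_len(k_true)), "shared")
  pop <- rep(sprintf("p%02d", seq_len(n_pops)), each = n_per_pop)
  hap <- character(length(pop))
  for (i in seq_len(n_pops)) {
    if (deterministic) {
      n_own <- round(purity * n_per_pop)
      draw <- c(rep(hap_ids[cl[i]], n_own),
                rep("shared", n_per_pop - n_own))
    } else {
      pr <- rep((1 - purity) / (k_true - 1), k_true)
      pr[cl[i]] <- purity
      draw <- sample(hap_ids[seq_len(k_true)], n_per_pop, replace = TRUE,
                     prob = pr)
    }
    hap[pop == sprintf("p%02d", i)] <- draw
  }
  coords <- cbind(lon = cl * 10 + stats::runif(n_pops, -2, 2),
                  lat = (cl %% 2) * 8 + stats::runif(n_pops, -2, 2))
  rownames(coords) <- sprintf("p%02d", seq_len(n_pops))
  list(hap = hap, pop = pop, coords = coords, cluster = cl,
       d2 = hap_diff_squared(as_alignment(stats::setNames(haps, hap_ids))))
}

# individual-level brute-force AMOVA oracle: direct sums of squared
# deviations from the full N x N squared distance matrix
amova_oracle <- function(d2_ind, pop, group = NULL) {
  N <- nrow(d2_ind)
  pops <- sort(unique(pop))
  P <- length(pops)
  ssd_of <- function(idx) sum(d2_ind[idx, idx]) / (2 * length(idx))
  ssd_total <- ssd_of(seq_len(N))
  ssd_wp <- sum(vapply(pops, function(p) ssd_of(which(pop == p)), numeric(1)))
  np <- as.numeric(table(factor(pop, levels = pops)))
  if (is.null(group)) {
    ssd_ap <- ssd_total - ssd_wp
    df_ap <- P - 1; df_wp <- N - P
    sig_c <- ssd_wp / df_wp
    n0 <- (N - sum(np^2) / N) / df_ap
    sig_b <- (ssd_ap / df_ap - sig_c) / n0
    list(sigma = c(b = sig_b, c = sig_c), phi_st = sig_b / (sig_b + sig_c))
  } else {
    g <- as.character(group[pops])
    gl <- sort(unique(g))
    G <- length(gl)
    ssd_wg <- sum(vapply(gl, function(gg)
      ssd_of(which(pop %in% pops[g == gg])), numeric(1)))
    ssd_ag <- ssd_total - ssd_wg
    ssd_ap <- ssd_wg - ssd_wp
    df_ag <- G - 1; df_ap <- P - G; df_wp <- N - P
    sig_c <- ssd_wp / df_wp
    Ng <- vapply(gl, function(gg) sum(np[g == gg]), numeric(1))
    sum_np2_Ng <- sum(vapply(seq_along(gl), function(i)
      sum(np[g == gl[i]]^2) / Ng[i], numeric(1)))
    n1 <- (N - sum_np2_Ng) / df_ap
    sig_b <- (ssd_ap / df_ap - sig_c) / n1
    n2 <- (sum_np2_Ng - sum(np^2) / N) / df_ag
    n3 <- (N - sum(Ng^2) / N) / df_ag
    sig_a <- (ssd_ag / df_ag - sig_c - n2 * sig_b) / n3
    tot <- sig_a + sig_b + sig_c
    list(sigma = c(a = sig_a, b = sig_b, c = sig_c),
         phi_ct = sig_a / tot, phi_sc = sig_b / (sig_b + sig_c),
         phi_st = (sig_a + sig_b) / tot)
  }
}

# independent transliteration of Tajima's (1989) constants, from scalars
tajima_oracle <- function(n, S, k) {
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (k - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

# independent transliteration of the corrected Fu & Li D*/F* forms, from
# the scalar counts (n, eta, eta_s, k)
fu_li_oracle <- function(n, eta, eta_s, k) {
  an <- sum(1 / seq_len(n - 1)); bn <- sum(1 / seq_len(n - 1)^2)
  an1 <- an + 1 / n
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    2 / (n - 1) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vDs <- ((n / (n - 1))^2 * bn + an^2 * dn -
            2 * n * an * (an + 1) / (n - 1)^2) / (an^2 + bn)
  uDs <- n / (n - 1) * (an - n / (n - 1)) - vDs
  vFs <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
            2 * (n - 1) * an / n^2 - 8 * bn / n) / (an^2 + bn)
  uFs <- ((4 * n^2 + 19 * n + 3 - 12 * n * an1) / (3 * n * (n - 1))) / an - vFs
  c(D_star = (n / (n - 1) * eta - an * eta_s) / sqrt(uDs * eta + vDs * eta^2),
    F_star = (k - (n - 1) / n * eta_s) / sqrt(uFs * eta + vFs * eta^2))
}

# brute-force mean pairwise difference proportion (pairwise deletion)
pi_oracle <- function(aln) {
  ch <- as_alignment(aln)
  n <- nrow(ch)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- ch[i, ]; b <- ch[j, ]
    ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
    tot <- tot + sum(a[ok] != b[ok]) / sum(ok)
  }
  tot / (n * (n - 1) / 2)
}
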