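# Analysis of molecular variance (Excoffier, Smouse & Quattro 1992).
# All sums of squared deviations are computed from population-level
# cross-sums: with F the populations x haplotypes count matrix and D2 the
# squared inter-haplotype distance matrix, S = F D2 F' holds every
# Sum_{i in p, j in q} delta^2_ij, so evaluating a grouping is O(P^2).

#' Squared-difference matrix between haplotypes
#'
#' Pairwise counts of nucleotide differences (pairwise deletion), squared —
#' the default AMOVA distance.
#'
#' @param hap `haplotype_dataset` or alignment of distinct haplotypes.
#' @return squared distance matrix.
#' @export
hap_diff_squared <- function(hap) {
  m <- if (inherits(hap, "haplotype_dataset")) .aln_int(hap$seq_matrix)
       else .aln_int(as_alignment(hap))
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    ok <- m[i, ] > 0L & m[j, ] > 0L
    D[i, j] <- D[j, i] <- sum(m[i, ok] != m[j, ok])
  }
  D^2
}

# counts matrix: populations x haplotypes
.pop_hap_counts <- function(hap_idx, pop, hap_levels = NULL) {
  if (is.null(hap_levels)) hap_levels <- sort(unique(hap_idx))
  unclass(table(factor(pop), factor(hap_idx, levels = hap_levels)))
}

# core decomposition from cross-sums S (P x P), population sizes np and a
# group assignment g (integer per population). With every population its
# own group the three-level model collapses onto the two-level one.
.amova_components <- function(S, np, g) {
  N <- sum(np)
  P <- length(np)
  groups <- sort(unique(g))
  G <- length(groups)
  ssd_wp <- sum(diag(S) / (2 * np))
  ssd_total <- sum(S) / (2 * N)
  ssd_wg <- 0
  for (gg in groups) {
    sel <- which(g == gg)
    Ng <- sum(np[sel])
    ssd_wg <- ssd_wg + sum(S[sel, sel]) / (2 * Ng)
  }
  ssd_ag <- ssd_total - ssd_wg
  ssd_ap <- ssd_wg - ssd_wp

  df_ag <- G - 1L
  df_ap <- P - G
  df_wp <- N - P

  sig_c <- ssd_wp / df_wp
  Ng_of <- vapply(groups, function(gg) sum(np[g == gg]), numeric(1))
  sum_npsq_over_Ng <- sum(vapply(seq_along(groups), function(i) {
    sel <- g == groups[i]
    sum(np[sel]^2) / Ng_of[i]
  }, numeric(1)))

  if (df_ap > 0L) {
    n1 <- (N - sum_npsq_over_Ng) / df_ap
    sig_b <- (ssd_ap / df_ap - sig_c) / n1
  } else {
    n1 <- NA_real_; sig_b <- 0
  }
  if (df_ag > 0L) {
    n2 <- (sum_npsq_over_Ng - sum(np^2) / N) / df_ag
    n3 <- (N - sum(Ng_of^2) / N) / df_ag
    sig_a <- (ssd_ag / df_ag - sig_c - n2 * sig_b) / n3
  } else {
    n2 <- NA_real_; n3 <- NA_real_; sig_a <- 0
  }
  tot <- sig_a + sig_b + sig_c
  list(ssd = c(among_groups = ssd_ag, among_pops = ssd_ap, within_pops = ssd_wp),
       df = c(df_ag, df_ap, df_wp),
       sigma = c(a = sig_a, b = sig_b, c = sig_c),
       phi_ct = if (G > 1L) sig_a / tot else NA_real_,
       phi_sc = if (df_ap > 0L) sig_b / (sig_b + sig_c) else NA_real_,
       phi_st = if (G > 1L && df_ap > 0L) (sig_a + sig_b) / tot
                else if (G > 1L) sig_a / tot
                else sig_b / (sig_b + sig_c))
}

# two-level helper: every population its own group is NOT the two-level
# model; the two-level model treats populations as the only stratum.
.amova2 <- function(S, np) {
  N <- sum(np); P <- length(np)
  ssd_wp <- sum(diag(S) / (2 * np))
  ssd_total <- sum(S) / (2 * N)
  ssd_ap <- ssd_total - ssd_wp
  df_ap <- P - 1L; df_wp <- N - P
  sig_c <- ssd_wp / df_wp
  n0 <- (N - sum(np^2) / N) / df_ap
  sig_b <- (ssd_ap / df_ap - sig_c) / n0
  tot <- sig_b + sig_c
  list(ssd = c(among_pops = ssd_ap, within_pops = ssd_wp),
       df = c(df_ap, df_wp), sigma = c(b = sig_b, c = sig_c),
       phi_st = sig_b / tot)
}

#' Analysis of molecular variance (AMOVA) with permutation tests
#'
#' Two-level (among/within populations) or, when `group` is supplied,
#' three-level (among groups / among populations within groups / within
#' populations) decomposition of squared inter-haplotype distances, with
#' phi-statistics and permutation p-values (`+1` smoothing). Negative
#' variance components are reported as-is with a flag.
#'
#' Permutation schemes follow standard practice: Phi_ST permutes
#' individuals among populations; Phi_SC permutes individuals among
#' populations within their group; Phi_CT permutes whole populations among
#' groups.
#'
#' @param hap_idx per-sample haplotype id (character/factor/integer).
#' @param pop per-sample population label.
#' @param group optional named vector mapping population -> group.
#' @param d2 squared distance matrix between haplotypes, rows/cols ordered
#'   and named by haplotype id (see [hap_diff_squared()]).
#' @param nperm number of permutations (0 = no tests).
#' @param seed optional RNG seed for the permutations.
#' @return object of class `amova_result`: variance components, percentages
#'   (summing to 100), phi indices, p-values, df, SSD, and
#'   `negative_components` flag.
#' @export
amova <- function(hap_idx, pop, group = NULL, d2, nperm = 0L, seed = NULL) {
  hap_idx <- as.character(hap_idx)
  pop <- as.character(pop)
  stopifnot(length(hap_idx) == length(pop))
  hl <- rownames(d2)
  if (is.null(hl)) stop("d2 must have haplotype ids as dimnames")
  if (!all(hap_idx %in% hl)) stop("hap_idx contains ids missing from d2")
  pops <- sort(unique(pop))
  if (any(table(pop) == 0L)) stop("empty population")
  FF <- .pop_hap_counts(hap_idx, pop, hl)
  FF <- FF[pops, , drop = FALSE]
  np <- rowSums(FF)
  if (any(np == 0)) stop("population of size 0: ",
                         paste(pops[np == 0], collapse = ", "))
  S <- FF %*% d2 %*% t(FF)

  three_level <- !is.null(group)
  if (three_level) {
    if (is.null(names(group))) stop("group must be named by population")
    miss <- setdiff(pops, names(group))
    if (length(miss)) stop("group mapping missing population(s): ",
                           paste(miss, collapse = ", "))
    g <- as.integer(factor(as.character(group[pops])))
    res <- .amova_components(S, np, g)
  } else {
    res <- .amova2(S, np)
  }
  total <- sum(res$sigma)
  pct <- 100 * res$sigma / total

  pvals <- NULL
  if (nperm > 0L) {
    if (!is.null(seed)) set.seed(seed)
    stat_fun2 <- function(hidx_perm) {
      Fp <- .pop_hap_counts(hidx_perm, pop, hl)[pops, , drop = FALSE]
      Sp <- Fp %*% d2 %*% t(Fp)
      .amova2(Sp, np)$phi_st
    }
    if (!three_level) {
      obs <- res$phi_st
      cnt <- 0L
      for (b in seq_len(nperm))
        if (stat_fun2(sample(hap_idx)) >= obs - 1e-12) cnt <- cnt + 1L
      pvals <- c(phi_st = (cnt + 1) / (nperm + 1))
    } else {
      obs_ct <- res$phi_ct; obs_sc <- res$phi_sc; obs_st <- res$phi_st
      cnt_ct <- cnt_sc <- cnt_st <- 0L
      pop_of <- pop
      grp_of_pop <- g
      for (b in seq_len(nperm)) {
        # Phi_CT: permute populations among groups
        gp <- sample(grp_of_pop)
        r1 <- .amova_components(S, np, gp)
        if (r1$phi_ct >= obs_ct - 1e-12) cnt_ct <- cnt_ct + 1L
        # Phi_ST: permute individuals among all populations
        hp <- sample(hap_idx)
        Fp <- .pop_hap_counts(hp, pop, hl)[pops, , drop = FALSE]
        Sp <- Fp %*% d2 %*% t(Fp)
        r2 <- .amova_components(Sp, np, grp_of_pop)
        if (r2$phi_st >= obs_st - 1e-12) cnt_st <- cnt_st + 1L
        # Phi_SC: permute individuals among populations within groups
        hp2 <- hap_idx
        for (gg in unique(grp_of_pop)) {
          sel <- which(pop_of %in% pops[grp_of_pop == gg])
          hp2[sel] <- hp2[sample(sel)]
        }
        Fp2 <- .pop_hap_counts(hp2, pop, hl)[pops, , drop = FALSE]
        Sp2 <- Fp2 %*% d2 %*% t(Fp2)
        r3 <- .amova_components(Sp2, np, grp_of_pop)
        if (r3$phi_sc >= obs_sc - 1e-12) cnt_sc <- cnt_sc + 1L
      }
      pvals <- c(phi_ct = (cnt_ct + 1) / (nperm + 1),
                 phi_sc = (cnt_sc + 1) / (nperm + 1),
                 phi_st = (cnt_st + 1) / (nperm + 1))
    }
  }

  structure(list(three_level = three_level, ssd = res$ssd, df = res$df,
                 sigma = res$sigma, percent = pct,
                 phi_st = res$phi_st,
                 phi_sc = if (three_level) res$phi_sc else NA_real_,
                 phi_ct = if (three_level) res$phi_ct else NA_real_,
                 p = pvals,
                 negative_components = any(res$sigma < 0),
                 n = sum(np), n_pops = length(np)),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (", if (x$three_level) "three-level" else "two-level", "), n = ",
      x$n, ", populations = ", x$n_pops, "\n", sep = "")
  comp <- data.frame(component = names(x$sigma), sigma = x$sigma,
                     percent = x$percent)
  print(comp, row.names = FALSE)
  cat("Phi_ST =", round(x$phi_st, 4))
  if (x$three_level) cat("  Phi_SC =", round(x$phi_sc, 4),
                         " Phi_CT =", round(x$phi_ct, 4))
  cat("\n")
  if (!is.null(x$p)) {
    cat("permutation p:", paste(names(x$p), signif(x$p, 3), sep = "=",
                                collapse = "  "), "\n")
  }
  if (x$negative_components)
    cat("note: negative variance component(s) present (reported, not truncated)\n")
  invisible(x)
}

#' Write an AMOVA table TSV
#'
#' @param x an `amova_result`.
#' @param path output path.
#' @export
write_amova_table <- function(x, path) {
  df <- data.frame(source = names(x$ssd), df = x$df, SSD = x$ssd,
                   variance = x$sigma, percent = x$percent)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
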