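# Neutrality tests (Tajima 1989; Fu & Li 1993 with the later variance
# corrections) and mismatch-distribution summaries. Significance is
# assessed against neutral constant-size coalescent simulations rather
# than approximation tables.

# site counts used by the tests: S (segregating sites), eta (total
# mutations, k-1 per column with k states), eta_s (singleton mutations:
# states carried by exactly one sequence, at most k-1 per column).
.site_counts <- function(m) {
  S <- 0L; eta <- 0L; eta_s <- 0L
  # only columns that differ anywhere from row 1 can be polymorphic
  vary <- which(colSums(m != matrix(m[1L, ], nrow(m), ncol(m),
                                    byrow = TRUE)) > 0L)
  for (j in vary) {
    x <- m[, j]; x <- x[x > 0L]
    if (length(x) < 2L) next
    tab <- tabulate(x, 4L)
    k <- sum(tab > 0L)
    if (k >= 2L) {
      S <- S + 1L
      eta <- eta + (k - 1L)
      eta_s <- eta_s + min(sum(tab == 1L), k - 1L)
    }
  }
  list(S = S, eta = eta, eta_s = eta_s)
}

.harmonics <- function(n) {
  i <- seq_len(n - 1L)
  list(a1 = sum(1 / i), a2 = sum(1 / i^2))
}

#' Tajima's D
#'
#' \eqn{D = (k - S/a_1) / \sqrt{e_1 S + e_2 S(S-1)}} (Tajima 1989), where k
#' is the mean number of pairwise differences and S the number of
#' segregating sites. With `S = 0` the statistic is undefined and `NA` is
#' returned with `defined = FALSE`.
#'
#' @param aln alignment, or NULL when `n`, `S` and `k` are given directly.
#' @param n,S,k sample size, segregating sites and mean pairwise
#'   differences (used when `aln` is NULL).
#' @return list with `D`, `defined`, `n`, `S`, `k`.
#' @export
tajimas_d <- function(aln = NULL, n = NULL, S = NULL, k = NULL) {
  if (!is.null(aln)) {
    aln <- as_alignment(aln)
    m <- .aln_int(aln)
    n <- nrow(m)
    S <- .site_counts(m)$S
    k <- nucleotide_diversity(aln)$k
  }
  if (n < 2) stop("Tajima's D needs n >= 2")
  if (S == 0) return(list(D = NA_real_, defined = FALSE, n = n, S = S, k = k))
  h <- .harmonics(n)
  a1 <- h$a1; a2 <- h$a2
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  list(D = D, defined = TRUE, n = n, S = S, k = k)
}

#' Fu and Li's tests
#'
#' Without an outgroup, the starred statistics D* and F* based on
#' within-sample singletons; with an aligned outgroup sequence, also the
#' original D and F based on derived (external-branch) mutations, taking
#' the outgroup state as ancestral. Variance constants follow the
#' corrected forms in common use.
#'
#' @param aln alignment.
#' @param outgroup optional outgroup sequence (string) of the same length.
#' @return list with `D_star`, `F_star` (and `D`, `F` when an outgroup is
#'   given), `defined`, plus the counts `n`, `S`, `eta`, `eta_s` (and
#'   `eta_e`).
#' @export
fu_li <- function(aln, outgroup = NULL) {
  aln <- as_alignment(aln)
  m <- .aln_int(aln)
  n <- nrow(m)
  if (n < 3) stop("Fu and Li's tests need n >= 3")
  sc <- .site_counts(m)
  k <- nucleotide_diversity(aln)$k
  out <- list(n = n, S = sc$S, eta = sc$eta, eta_s = sc$eta_s, k = k)
  if (sc$S == 0) {
    out$defined <- FALSE
    out$D_star <- out$F_star <- NA_real_
    if (!is.null(outgroup)) out$D <- out$F <- NA_real_
    return(out)
  }
  out$defined <- TRUE
  st <- .fu_li_star(n, sc$eta, sc$eta_s, k)
  out$D_star <- st$D_star
  out$F_star <- st$F_star

  if (!is.null(outgroup)) {
    og <- .aln_int(as_alignment(c(og = paste(toupper(outgroup), collapse = ""))))
    if (ncol(og) != ncol(m)) stop("outgroup length differs from alignment")
    eta_e <- 0L
    for (j in seq_len(ncol(m))) {
      x <- m[, j]; x <- x[x > 0L]
      anc <- og[1L, j]
      if (length(x) < 2L || anc == 0L) next
      tab <- tabulate(x, 4L)
      if (sum(tab > 0L) < 2L) next
      der <- setdiff(which(tab == 1L), anc)
      eta_e <- eta_e + length(der)
    }
    out$eta_e <- eta_e
    og_st <- .fu_li_outgroup(n, sc$eta, eta_e, k)
    out$D <- og_st$D
    out$F <- og_st$F
  }
  out
}

# Fu & Li constants; corrected variance forms in common use
.fu_li_const <- function(n) {
  h <- .harmonics(n)
  an <- h$a1; bn <- h$a2
  an1 <- an + 1 / n                       # a_{n+1}
  cn <- if (n == 2) 1 else 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  list(an = an, bn = bn, an1 = an1, cn = cn, dn = dn)
}

.fu_li_star <- function(n, eta, eta_s, k) {
  cc <- .fu_li_const(n)
  an <- cc$an; bn <- cc$bn; an1 <- cc$an1; dn <- cc$dn
  vDs <- ((n / (n - 1))^2 * bn + an^2 * dn -
          2 * (n * an * (an + 1)) / (n - 1)^2) / (an^2 + bn)
  uDs <- (n / (n - 1)) * (an - n / (n - 1)) - vDs
  vFs <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
          (2 * (n - 1) * an) / n^2 - 8 * bn / n) / (an^2 + bn)
  uFs <- ((4 * n^2 + 19 * n + 3 - 12 * n * an1) / (3 * n * (n - 1))) / an - vFs
  list(D_star = ((n / (n - 1)) * eta - an * eta_s) /
         sqrt(uDs * eta + vDs * eta^2),
       F_star = (k - ((n - 1) / n) * eta_s) /
         sqrt(uFs * eta + vFs * eta^2))
}

.fu_li_outgroup <- function(n, eta, eta_e, k) {
  cc <- .fu_li_const(n)
  an <- cc$an; bn <- cc$bn; an1 <- cc$an1; cn <- cc$cn
  vD <- 1 + an^2 / (bn + an^2) * (cn - (n + 1) / (n - 1))
  uD <- an - 1 - vD
  vF <- (cn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) - 2 / (n - 1)) /
    (an^2 + bn)
  uF <- (1 + (n + 1) / (3 * (n - 1)) -
         4 * ((n + 1) / (n - 1)^2) * (an1 - 2 * n / (n + 1))) / an - vF
  list(D = (eta - an * eta_e) / sqrt(uD * eta + vD * eta^2),
       F = (k - eta_e) / sqrt(uF * eta + vF * eta^2))
}

#' Neutrality test p-values by coalescent simulation
#'
#' Simulates `n_sims` neutral constant-size single-deme coalescent
#' datasets conditioned on the sample size and on theta (Watterson's
#' estimate from the data unless given), computes the chosen statistic on
#' each, and returns the two-sided empirical p-value (with `+1`
#' smoothing). A precomputed vector of null statistics can be supplied to
#' share one null distribution across many datasets.
#'
#' @param aln alignment.
#' @param statistic `"tajima_d"`, `"fu_li_d_star"` or `"fu_li_f_star"`.
#' @param n_sims number of null simulations.
#' @param theta population mutation parameter for the null (default:
#'   Watterson's estimate S/a1).
#' @param null_stats optional precomputed null statistics.
#' @param L sequence length for the null simulations.
#' @param seed optional RNG seed.
#' @return list with `stat`, `p`, `defined`, `null_stats`.
#' @export
neutrality_test <- function(aln, statistic = c("tajima_d", "fu_li_d_star",
                                               "fu_li_f_star"),
                            n_sims = 1000L, theta = NULL, null_stats = NULL,
                            L = NULL, seed = NULL) {
  statistic <- match.arg(statistic)
  aln <- as_alignment(aln)
  n <- nrow(aln)
  if (is.null(L)) L <- ncol(aln)
  val <- switch(statistic,
                tajima_d = tajimas_d(aln),
                fu_li_d_star = { f <- fu_li(aln); list(D = f$D_star, defined = f$defined) },
                fu_li_f_star = { f <- fu_li(aln); list(D = f$F_star, defined = f$defined) })
  obs <- val[[1L]]
  if (!isTRUE(val$defined))
    return(list(stat = NA_real_, p = NA_real_, defined = FALSE,
                null_stats = null_stats))
  if (is.null(theta)) {
    S <- .site_counts(.aln_int(aln))$S
    theta <- S / .harmonics(n)$a1
  }
  if (is.null(null_stats)) {
    if (!is.null(seed)) set.seed(seed)
    null_stats <- simulate_null_stats(statistic, n = n, theta = theta,
                                      L = L, n_sims = n_sims)
  }
  ns <- null_stats[is.finite(null_stats)]
  p_lo <- (sum(ns <= obs) + 1) / (length(ns) + 1)
  p_hi <- (sum(ns >= obs) + 1) / (length(ns) + 1)
  list(stat = obs, p = min(1, 2 * min(p_lo, p_hi)), defined = TRUE,
       null_stats = null_stats)
}

#' Simulate the null distribution of a neutrality statistic
#'
#' @inheritParams neutrality_test
#' @param n sample size.
#' @return numeric vector of simulated statistics (undefined draws, S = 0,
#'   are returned as NA).
#' @export
simulate_null_stats <- function(statistic, n, theta, L = 669L,
                                n_sims = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N0 <- 10000
  mu <- theta / (2 * N0 * L)
  dem <- demography(sizes = c(pop = N0))
  mut <- mutation_model(L = L, mu = mu, kappa = 10, gamma_shape = NULL)
  vapply(seq_len(n_sims), function(i) {
    sim <- simulate_coalescent(dem, sample_sizes = c(pop = n), mut)
    m <- sim$seqs
    sc <- .site_counts(m)
    if (sc$S == 0L) return(NA_real_)
    k <- .mean_pairwise_diff(m)
    if (statistic == "tajima_d") {
      tajimas_d(n = n, S = sc$S, k = k)$D
    } else {
      st <- .fu_li_star(n, sc$eta, sc$eta_s, k)
      if (statistic == "fu_li_d_star") st$D_star else st$F_star
    }
  }, numeric(1))
}

# mean pairwise difference count on an integer alignment (pairwise
# deletion for uncalled sites)
.mean_pairwise_diff <- function(m) {
  if (!any(m == 0L)) return(.k_fast(m))
  n <- nrow(m)
  if (n < 2L) return(0)
  tot <- 0
  for (i in 1:(n - 1L)) for (j in (i + 1L):n)
    tot <- tot + sum(m[i, ] != m[j, ] & m[i, ] > 0L & m[j, ] > 0L)
  tot / (n * (n - 1) / 2)
}

# fast mean pairwise differences for complete matrices: collapse to
# distinct haplotypes over polymorphic columns and weight by counts
.k_fast <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(0)
  vary <- which(colSums(m != matrix(m[1L, ], n, ncol(m), byrow = TRUE)) > 0L)
  if (!length(vary)) return(0)
  mv <- m[, vary, drop = FALSE]
  keys <- apply(mv, 1L, paste, collapse = ".")
  uk <- unique(keys)
  H <- length(uk)
  mu <- mv[match(uk, keys), , drop = FALSE]
  f <- as.integer(table(factor(keys, levels = uk)))
  Dd <- matrix(0, H, H)
  if (H > 1L) for (i in 1:(H - 1L)) for (j in (i + 1L):H)
    Dd[i, j] <- Dd[j, i] <- sum(mu[i, ] != mu[j, ])
  as.numeric(f %*% Dd %*% f) / 2 / (n * (n - 1) / 2)
}

#' Mismatch distribution and raggedness index
#'
#' Histogram of pairwise difference counts over all sequence pairs, the
#' mean and variance of the differences, and Harpending's (1994)
#' raggedness index \eqn{r = \sum_{i=1}^{d+1} (x_i - x_{i-1})^2} computed
#' on relative frequencies with a trailing empty class.
#'
#' @param aln alignment.
#' @return object of class `mismatch_summary`: `histogram` (named counts
#'   for 0..max differences), `raggedness`, `mean`, `var`, `n_pairs`.
#' @export
mismatch_distribution <- function(aln) {
  aln <- as_alignment(aln)
  n <- nrow(aln)
  if (n < 2) stop("mismatch distribution needs n >= 2")
  # collapse to haplotypes for speed; weight pairs by carrier counts
  seqs <- .aln_strings(aln)
  uniq <- unique(seqs)
  cnt <- as.integer(table(factor(seqs, levels = uniq)))
  m <- .aln_int(as_alignment(stats::setNames(uniq, paste0("u", seq_along(uniq)))))
  H <- length(uniq)
  diffs <- integer(0); wts <- numeric(0)
  for (i in seq_len(H)) {
    if (cnt[i] > 1L) { diffs <- c(diffs, 0L); wts <- c(wts, cnt[i] * (cnt[i] - 1) / 2) }
    if (i < H) for (j in (i + 1L):H) {
      ok <- m[i, ] > 0L & m[j, ] > 0L
      diffs <- c(diffs, sum(m[i, ok] != m[j, ok]))
      wts <- c(wts, cnt[i] * cnt[j])
    }
  }
  dmax <- max(diffs)
  hist <- stats::setNames(numeric(dmax + 1L), 0:dmax)
  for (i in seq_along(diffs))
    hist[diffs[i] + 1L] <- hist[diffs[i] + 1L] + wts[i]
  npairs <- n * (n - 1) / 2
  x <- hist / npairs
  xx <- c(x, 0)
  r <- sum(diff(c(0, xx))[-1L]^2)  # classes 1..d+1 relative-frequency steps
  mu <- sum((0:dmax) * x)
  v <- sum((0:dmax)^2 * x) - mu^2
  structure(list(histogram = hist, raggedness = r, mean = mu, var = v,
                 n_pairs = npairs),
            class = "mismatch_summary")
}

#' @export
print.mismatch_summary <- function(x, ...) {
  cat("mismatch distribution over", x$n_pairs, "pairs: mean =",
      round(x$mean, 3), " var =", round(x$var, 3),
      " raggedness =", signif(x$raggedness, 4), "\n")
  invisible(x)
}

#' Per-group neutrality summary table
#'
#' One row per group with N, haplotype count, diversity, Tajima's D and
#' Fu & Li's F* with simulation p-values; groups with no variation are
#' reported with NA statistics.
#'
#' @param aln alignment.
#' @param groups group label per sequence.
#' @param n_sims null simulations per defined statistic.
#' @param seed optional RNG seed.
#' @return data frame.
#' @export
neutrality_table <- function(aln, groups, n_sims = 1000L, seed = NULL) {
  aln <- as_alignment(aln)
  grp <- as.character(groups)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(unique(grp), function(g) {
    sub <- aln[grp == g, , drop = FALSE]
    n <- nrow(sub)
    nh <- length(unique(.aln_strings(sub)))
    base <- data.frame(group = g, N = n, n_haplotypes = nh,
                       D = NA_real_, D_p = NA_real_,
                       F_star = NA_real_, F_star_p = NA_real_)
    if (n >= 4 && nh >= 2) {
      td <- neutrality_test(sub, "tajima_d", n_sims = n_sims)
      fs <- neutrality_test(sub, "fu_li_f_star", n_sims = n_sims)
      base$D <- td$stat; base$D_p <- td$p
      base$F_star <- fs$stat; base$F_star_p <- fs$p
    }
    base
  })
  do.call(rbind, rows)
}

#' Raggedness index of a pairwise-difference histogram
#'
#' @param x a `mismatch_summary` or a numeric histogram of counts for
#'   0..max differences.
#' @return the raggedness index.
#' @export
raggedness <- function(x) {
  if (inherits(x, "mismatch_summary")) return(x$raggedness)
  xr <- x / sum(x)
  xx <- c(xr, 0)
  sum(diff(c(0, xx))[-1L]^2)
}
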