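# Spatial analysis of molecular variance: find the partition of
# populations into K groups maximizing the among-group fixation index
# F_CT, by simulated annealing with geographically informed proposals
# (moves prefer reassigning a population to a group containing one of its
# Delaunay neighbors, so spatial cohesion emerges without being enforced).

#' Delaunay neighbor graph of population coordinates
#'
#' Brute-force Delaunay triangulation in the plane (empty-circumcircle
#' test), adequate for the tens of populations typical of a survey. Falls
#' back to a nearest-neighbor chain for (near-)collinear layouts, and
#' guarantees a connected graph.
#'
#' @param coords matrix/data frame with 2 columns (lon, lat or x, y), rows
#'   named by population.
#' @return logical adjacency matrix.
#' @export
delaunay_neighbors <- function(coords) {
  xy <- as.matrix(coords[, 1:2])
  n <- nrow(xy)
  A <- matrix(FALSE, n, n, dimnames = list(rownames(coords), rownames(coords)))
  if (n <= 2L) { A[] <- TRUE; diag(A) <- FALSE; return(A) }
  for (i in 1:(n - 2L)) for (j in (i + 1L):(n - 1L)) for (k in (j + 1L):n) {
    p1 <- xy[i, ]; p2 <- xy[j, ]; p3 <- xy[k, ]
    d <- 2 * (p1[1] * (p2[2] - p3[2]) + p2[1] * (p3[2] - p1[2]) +
              p3[1] * (p1[2] - p2[2]))
    if (abs(d) < 1e-12) next  # collinear triple
    ux <- ((sum(p1^2)) * (p2[2] - p3[2]) + (sum(p2^2)) * (p3[2] - p1[2]) +
           (sum(p3^2)) * (p1[2] - p2[2])) / d
    uy <- ((sum(p1^2)) * (p3[1] - p2[1]) + (sum(p2^2)) * (p1[1] - p3[1]) +
           (sum(p3^2)) * (p2[1] - p1[1])) / d
    r2 <- sum((p1 - c(ux, uy))^2)
    others <- setdiff(seq_len(n), c(i, j, k))
    if (all(rowSums((xy[others, , drop = FALSE] -
                     matrix(c(ux, uy), length(others), 2, byrow = TRUE))^2) >
            r2 - 1e-9)) {
      A[i, j] <- A[j, i] <- TRUE
      A[j, k] <- A[k, j] <- TRUE
      A[i, k] <- A[k, i] <- TRUE
    }
  }
  # connect any leftover components through nearest neighbors
  repeat {
    comp <- .graph_components(A)
    if (max(comp) == 1L) break
    dmat <- as.matrix(stats::dist(xy))
    best <- c(Inf, NA, NA)
    for (i in 1:(n - 1L)) for (j in (i + 1L):n)
      if (comp[i] != comp[j] && dmat[i, j] < best[1])
        best <- c(dmat[i, j], i, j)
    A[best[2], best[3]] <- A[best[3], best[2]] <- TRUE
  }
  A
}

.graph_components <- function(A) {
  n <- nrow(A)
  comp <- rep(0L, n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      nb <- which(A[u, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# fast F_CT objective closed over precomputed cross-sums
.make_fct <- function(S, np) {
  N <- sum(np)
  ssd_wp <- sum(diag(S) / (2 * np))
  ssd_total <- sum(S) / (2 * N)
  function(g) {
    .amova_components_fct(S, np, g, N, ssd_wp, ssd_total)
  }
}

.amova_components_fct <- function(S, np, g, N, ssd_wp, ssd_total) {
  groups <- unique(g)
  G <- length(groups)
  P <- length(np)
  ssd_wg <- 0
  sum_npsq_over_Ng <- 0
  Ngsq <- 0
  for (gg in groups) {
    sel <- g == gg
    Ng <- sum(np[sel])
    ssd_wg <- ssd_wg + sum(S[sel, sel]) / (2 * Ng)
    sum_npsq_over_Ng <- sum_npsq_over_Ng + sum(np[sel]^2) / Ng
    Ngsq <- Ngsq + Ng^2
  }
  ssd_ag <- ssd_total - ssd_wg
  ssd_ap <- ssd_wg - ssd_wp
  df_ag <- G - 1L; df_ap <- P - G; df_wp <- N - P
  sig_c <- ssd_wp / df_wp
  if (df_ap > 0L) {
    n1 <- (N - sum_npsq_over_Ng) / df_ap
    sig_b <- (ssd_ap / df_ap - sig_c) / n1
  } else sig_b <- 0
  n2 <- (sum_npsq_over_Ng - sum(np^2) / N) / df_ag
  n3 <- (N - Ngsq / N) / df_ag
  sig_a <- (ssd_ag / df_ag - sig_c - n2 * sig_b) / n3
  sig_a / (sig_a + sig_b + sig_c)
}

#' SAMOVA: annealing search for the best K-group geographic partition
#'
#' Populations are repeatedly reassigned between groups to maximize F_CT
#' (the among-group fixation index of a three-level AMOVA). Each restart
#' initializes groups as Voronoi cells around K randomly chosen seed
#' populations, then runs simulated annealing with geometric cooling;
#' proposals move one population to the group of one of its Delaunay
#' neighbors (with occasional fully random moves). The best partition over
#' all restarts is returned.
#'
#' @param hap_idx per-sample haplotype id.
#' @param pop per-sample population label.
#' @param d2 squared haplotype distance matrix (see [hap_diff_squared()]).
#' @param coords per-population coordinates (rows named by population).
#' @param K number of groups (2 <= K <= number of populations).
#' @param restarts annealing restarts (default 100).
#' @param n_steps proposals per restart (default 10000).
#' @param cooling multiplicative cooling factor applied every 100 proposals.
#' @param nperm permutations of populations among groups for the F_CT
#'   p-value (0 = none).
#' @param strict_contiguity if TRUE, only moves to Delaunay-neighbor groups
#'   are ever proposed.
#' @param seed optional RNG seed.
#' @return object of class `samova_result`: `K`, `partition` (named group
#'   id per population), `fct`, `p`, `history` (best objective per
#'   restart).
#' @export
samova <- function(hap_idx, pop, d2, coords, K, restarts = 100L,
                   n_steps = 10000L, cooling = 0.95, nperm = 0L,
                   strict_contiguity = FALSE, seed = NULL) {
  pop <- as.character(pop)
  pops <- sort(unique(pop))
  P <- length(pops)
  if (K > P) stop("K (", K, ") exceeds the number of populations (", P, ")")
  if (K < 2L) stop("K must be >= 2")
  coords <- coords[pops, , drop = FALSE]
  if (anyDuplicated(as.data.frame(coords))) stop("population coordinates must be distinct")
  hl <- rownames(d2)
  FF <- .pop_hap_counts(as.character(hap_idx), pop, hl)[pops, , drop = FALSE]
  np <- rowSums(FF)
  S <- FF %*% d2 %*% t(FF)
  fct <- .make_fct(S, np)
  A <- delaunay_neighbors(coords)
  if (!is.null(seed)) set.seed(seed)

  xy <- as.matrix(coords[, 1:2])
  best_g <- NULL; best_f <- -Inf; history <- numeric(restarts)

  for (r in seq_len(restarts)) {
    seeds <- sample.int(P, K)
    d_to_seed <- as.matrix(stats::dist(xy))[, seeds, drop = FALSE]
    g <- max.col(-d_to_seed)        # Voronoi init around seed populations
    g[seeds] <- seq_len(K)
    if (length(unique(g)) < K) {    # ensure all groups non-empty
      for (k in setdiff(seq_len(K), unique(g))) {
        cand <- which(tabulate(g, K)[g] > 1L)
        g[sample(cand, 1L)] <- k
      }
    }
    f_cur <- fct(g)

    # pilot calibration: temperature where ~80% of adverse moves accept
    deltas <- abs(stats::rnorm(20L, 0, 0.02))
    pilot <- replicate(30L, {
      p0 <- sample.int(P, 1L)
      gs <- g; gs[p0] <- sample(setdiff(seq_len(K), g[p0]), 1L)
      if (min(tabulate(gs, K)) > 0L) abs(fct(gs) - f_cur) else NA_real_
    })
    pilot <- pilot[is.finite(pilot) & pilot > 0]
    temp <- if (length(pilot)) stats::median(pilot) / 0.2231 else 0.01

    f_best_r <- f_cur; g_best_r <- g
    for (step in seq_len(n_steps)) {
      p0 <- sample.int(P, 1L)
      sizes <- tabulate(g, K)
      if (sizes[g[p0]] <= 1L) next  # donor group would empty
      nb_groups <- unique(g[A[p0, ]])
      nb_groups <- setdiff(nb_groups, g[p0])
      target <- if (length(nb_groups) &&
                    (strict_contiguity || stats::runif(1) > 0.1)) {
        nb_groups[sample.int(length(nb_groups), 1L)]
      } else if (!strict_contiguity) {
        sample(setdiff(seq_len(K), g[p0]), 1L)
      } else next
      g2 <- g; g2[p0] <- target
      f2 <- fct(g2)
      if (f2 >= f_cur || stats::runif(1) < exp((f2 - f_cur) / temp)) {
        g <- g2; f_cur <- f2
        if (f_cur > f_best_r) { f_best_r <- f_cur; g_best_r <- g }
      }
      if (step %% 100L == 0L) temp <- temp * cooling
    }
    # greedy polish: single-population moves until no improvement
    g <- g_best_r; f_cur <- f_best_r
    repeat {
      improved <- FALSE
      for (p0 in seq_len(P)) {
        if (tabulate(g, K)[g[p0]] <= 1L) next
        for (tg in setdiff(seq_len(K), g[p0])) {
          g2 <- g; g2[p0] <- tg
          f2 <- fct(g2)
          if (f2 > f_cur + 1e-12) { g <- g2; f_cur <- f2; improved <- TRUE }
        }
      }
      if (!improved) break
    }
    f_best_r <- f_cur; g_best_r <- g
    history[r] <- f_best_r
    if (f_best_r > best_f) { best_f <- f_best_r; best_g <- g_best_r }
  }

  p <- NA_real_
  if (nperm > 0L) {
    cnt <- 0L
    for (b in seq_len(nperm))
      if (fct(sample(best_g)) >= best_f - 1e-12) cnt <- cnt + 1L
    p <- (cnt + 1) / (nperm + 1)
  }

  structure(list(K = as.integer(K), partition = stats::setNames(best_g, pops),
                 fct = best_f, p = p, history = history,
                 n_pops = P),
            class = "samova_result")
}

#' @export
print.samova_result <- function(x, ...) {
  cat("SAMOVA: K =", x$K, " F_CT =", round(x$fct, 4))
  if (!is.na(x$p)) cat("  (p =", signif(x$p, 3), ")")
  cat("\n")
  for (k in sort(unique(x$partition)))
    cat("  group", k, ":", paste(names(x$partition)[x$partition == k],
                                 collapse = ", "), "\n")
  invisible(x)
}

#' Exhaustive-search optimum of the SAMOVA objective
#'
#' Enumerates every partition of the populations into exactly K non-empty
#' groups and returns the maximal F_CT. Feasible for small population
#' counts only; used to validate the annealing search.
#'
#' @inheritParams samova
#' @return list with `fct` and `partition`.
#' @export
samova_exhaustive <- function(hap_idx, pop, d2, K) {
  pop <- as.character(pop)
  pops <- sort(unique(pop))
  P <- length(pops)
  if (P > 13L) stop("exhaustive search is limited to <= 13 populations")
  hl <- rownames(d2)
  FF <- .pop_hap_counts(as.character(hap_idx), pop, hl)[pops, , drop = FALSE]
  np <- rowSums(FF)
  S <- FF %*% d2 %*% t(FF)
  fct <- .make_fct(S, np)

  best <- list(fct = -Inf, partition = NULL)
  g <- integer(P)
  recurse <- function(i, maxg) {
    if (i > P) {
      if (maxg == K) {
        f <- fct(g)
        if (f > best$fct) best <<- list(fct = f,
                                        partition = stats::setNames(g, pops))
      }
      return(invisible())
    }
    for (k in seq_len(min(maxg + 1L, K))) {
      g[i] <<- k
      recurse(i + 1L, max(maxg, k))
    }
  }
  recurse(1L, 0L)
  best
}

#' Choose K from a set of SAMOVA results
#'
#' Returns the K maximizing F_CT among results whose permutation p-value is
#' below `alpha`; ties (within `tol`) are broken toward the smaller K.
#'
#' @param results list of `samova_result` objects (with p-values).
#' @param alpha significance threshold.
#' @param tol numeric tolerance for F_CT ties.
#' @return list with `K` (NA if none significant), `fct`, and a `table` of
#'   K / F_CT / p.
#' @export
select_k <- function(results, alpha = 0.05, tol = 1e-9) {
  tab <- data.frame(K = vapply(results, function(r) as.integer(r[["K"]]),
                               integer(1)),
                    fct = vapply(results, function(r) as.numeric(r[["fct"]]),
                                 numeric(1)),
                    p = vapply(results, function(r) as.numeric(r[["p"]]),
                               numeric(1)))
  tab <- tab[order(tab$K), ]
  sig <- tab[!is.na(tab$p) & tab$p < alpha, ]
  if (nrow(sig) == 0L)
    return(list(K = NA_integer_, fct = NA_real_, table = tab,
                reason = "no K reaches significance"))
  fmax <- max(sig$fct)
  pick <- sig[sig$fct >= fmax - tol, ]
  pick <- pick[which.min(pick$K), ]
  list(K = pick$K, fct = pick$fct, table = tab, reason = NULL)
}
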