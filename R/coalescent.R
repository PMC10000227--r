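# Single-locus Hudson-style coalescent simulator for haploid,
# maternally-inherited, non-recombining sequence (mtDNA): exponential-time
# pairwise coalescence within demes of constant (female effective) size,
# lineage movement at merge/admixture events backward in time, finite-site
# K80 mutations with optional gamma site-rate heterogeneity laid on
# branches.

#' Construct a demography (demes + backward-time events)
#'
#' @param sizes named numeric vector of haploid effective deme sizes.
#' @param events list of events from [ev_merge()] / [ev_admixture()],
#'   applied backward in time in order of their `time` (generations).
#' @return object of class `demography`.
#' @export
demography <- function(sizes, events = list()) {
  if (is.null(names(sizes)) || any(names(sizes) == ""))
    stop("deme sizes must be named")
  if (any(sizes <= 0)) stop("deme sizes must be positive")
  demes <- names(sizes)
  for (ev in events) {
    refs <- switch(ev$type,
                   merge = c(ev$source, ev$target),
                   admixture = c(ev$recipient, ev$donor_a, ev$donor_b))
    miss <- setdiff(refs, demes)
    if (length(miss)) stop("event refers to unknown deme(s): ",
                           paste(miss, collapse = ", "))
    if (ev$time < 0) stop("event times must be non-negative")
  }
  ord <- order(vapply(events, `[[`, numeric(1), "time"))
  structure(list(sizes = sizes, events = events[ord]), class = "demography")
}

#' @rdname demography
#' @param time event time in generations (backward from sampling).
#' @param source,target at `time`, all lineages of `source` move into
#'   `target`; `source` becomes inactive.
#' @export
ev_merge <- function(time, source, target)
  list(type = "merge", time = time, source = source, target = target)

#' @rdname demography
#' @param recipient,donor_a,donor_b,prop_a at `time`, each lineage of
#'   `recipient` moves to `donor_a` with probability `prop_a`, else to
#'   `donor_b`; `recipient` becomes inactive.
#' @export
ev_admixture <- function(time, recipient, donor_a, donor_b, prop_a) {
  if (prop_a <= 0 || prop_a >= 1) stop("admixture proportion must be in (0,1)")
  list(type = "admixture", time = time, recipient = recipient,
       donor_a = donor_a, donor_b = donor_b, prop_a = prop_a)
}

#' Finite-site K80 mutation model
#'
#' @param L sequence length in sites (default 669, a typical mtDNA ND5
#'   fragment).
#' @param mu per-site mutation rate per generation.
#' @param kappa transition/transversion rate ratio.
#' @param gamma_shape gamma shape for among-site rate heterogeneity
#'   (mean-1 rates; `NULL` = uniform rates; default 4).
#' @param root optional root sequence (string); random if NULL.
#' @param site_mask optional integer vector of 1-based positions whose
#'   mutation rate is forced to 0 (e.g. diagnostic sites that must stay
#'   fixed within a lineage).
#' @return object of class `mutation_model`.
#' @export
mutation_model <- function(L = 669L, mu = 4.56e-8, kappa = 10,
                           gamma_shape = 4, root = NULL, site_mask = NULL) {
  stopifnot(mu > 0, L >= 1, kappa > 0)
  if (!is.null(gamma_shape) && gamma_shape <= 0) stop("gamma_shape must be > 0")
  if (!is.null(root)) {
    root <- .aln_int(as_alignment(c(root = paste(toupper(root), collapse = ""))))[1L, ]
    if (length(root) != L) stop("root sequence length differs from L")
    if (any(root == 0L)) stop("root sequence must be unambiguous A/C/G/T")
  }
  structure(list(L = as.integer(L), mu = mu, kappa = kappa,
                 gamma_shape = gamma_shape, root = root,
                 site_mask = site_mask),
            class = "mutation_model")
}

#' Simulate a single-locus coalescent sample under a demography
#'
#' Builds the genealogy backward in time (pairwise coalescence at rate
#' \eqn{k(k-1)/2N} within each deme, lineage movement at demographic
#' events) and, when a mutation model is given, lays K80 mutations on the
#' branches with gamma-distributed site rates and evolves sequences down
#' from the root. Deterministic under a fixed seed.
#'
#' @param dem a [demography()].
#' @param sample_sizes named integer vector: sampled lineages per deme.
#' @param mut a [mutation_model()], or NULL for genealogy only.
#' @param seed optional RNG seed.
#' @return object of class `coalescent_sim`: `seqs` (integer-coded matrix,
#'   tips x sites; NULL without a mutation model), `deme` (tip deme
#'   labels), `tmrca` (generations), `total_branch_length`,
#'   `n_mutations`, `tree` (parent/time vectors).
#' @export
simulate_coalescent <- function(dem, sample_sizes, mut = NULL, seed = NULL) {
  if (!inherits(dem, "demography")) stop("dem must be a demography object")
  if (!is.null(seed)) set.seed(seed)
  demes <- names(dem$sizes)
  if (is.null(names(sample_sizes))) stop("sample_sizes must be named by deme")
  bad <- setdiff(names(sample_sizes), demes)
  if (length(bad)) stop("sample sizes given for unknown deme(s): ",
                        paste(bad, collapse = ", "))
  sample_sizes <- sample_sizes[sample_sizes > 0]
  ntot <- sum(sample_sizes)
  if (ntot < 2) stop("need at least 2 sampled lineages in total")

  nmax <- 2L * ntot - 1L
  node_time <- numeric(nmax)
  node_parent <- integer(nmax)
  lin <- stats::setNames(vector("list", length(demes)), demes)
  for (d in demes) lin[[d]] <- integer(0)
  tip_deme <- character(ntot)
  nid <- 0L
  for (d in names(sample_sizes)) {
    ids <- nid + seq_len(sample_sizes[[d]])
    lin[[d]] <- ids
    tip_deme[ids] <- d
    nid <- nid + sample_sizes[[d]]
  }
  nxt <- ntot + 1L
  active <- stats::setNames(rep(TRUE, length(demes)), demes)
  t <- 0
  events <- dem$events
  ei <- 1L

  if (length(events) == 0L && length(sample_sizes) == 1L) {
    # single panmictic deme: vectorized waiting times, O(1) pair merging
    N <- dem$sizes[[names(sample_sizes)]]
    j <- ntot:2
    times <- cumsum(stats::rexp(ntot - 1L, rate = j * (j - 1) / 2 / N))
    act <- seq_len(ntot); nact <- ntot
    for (e in seq_len(ntot - 1L)) {
      i1 <- sample.int(nact, 1L); l1 <- act[i1]
      act[i1] <- act[nact]; nact <- nact - 1L
      i2 <- sample.int(nact, 1L); l2 <- act[i2]
      nd <- ntot + e
      node_parent[l1] <- nd; node_parent[l2] <- nd
      node_time[nd] <- times[e]
      act[i2] <- nd
    }
  } else repeat {
    k <- lengths(lin)
    rates <- ifelse(active & k >= 2L, k * (k - 1) / 2 / dem$sizes, 0)
    R <- sum(rates)
    t_ev <- if (ei <= length(events)) events[[ei]]$time else Inf
    if (R == 0 && !is.finite(t_ev)) {
      occupied <- names(lin)[k > 0L]
      stop("lineages stranded past the last event in deme(s): ",
           paste(occupied, collapse = ", "), " (malformed scenario)")
    }
    dt <- if (R > 0) stats::rexp(1L, R) else Inf
    if (t + dt < t_ev) {
      t <- t + dt
      d <- sample(demes, 1L, prob = rates)
      pick <- sample(lin[[d]], 2L)
      node_time[nxt] <- t
      node_parent[pick] <- nxt
      lin[[d]] <- c(setdiff(lin[[d]], pick), nxt)
      if (nxt == nmax) break
      nxt <- nxt + 1L
    } else {
      t <- t_ev
      ev <- events[[ei]]
      ei <- ei + 1L
      if (ev$type == "merge") {
        lin[[ev$target]] <- c(lin[[ev$target]], lin[[ev$source]])
        lin[[ev$source]] <- integer(0)
        active[ev$source] <- FALSE
      } else {
        to_a <- stats::runif(length(lin[[ev$recipient]])) < ev$prop_a
        lin[[ev$donor_a]] <- c(lin[[ev$donor_a]], lin[[ev$recipient]][to_a])
        lin[[ev$donor_b]] <- c(lin[[ev$donor_b]], lin[[ev$recipient]][!to_a])
        lin[[ev$recipient]] <- integer(0)
        active[ev$recipient] <- FALSE
      }
    }
  }

  root <- nmax
  blen <- node_time[node_parent[seq_len(nmax - 1L)]] - node_time[seq_len(nmax - 1L)]
  tbl <- sum(blen)

  out <- list(seqs = NULL, deme = tip_deme, tmrca = node_time[root],
              total_branch_length = tbl, n_mutations = NA_integer_,
              tree = list(parent = node_parent, time = node_time, n_tips = ntot))

  if (!is.null(mut)) {
    L <- mut$L
    rates_s <- if (is.null(mut$gamma_shape)) rep(1, L)
               else stats::rgamma(L, shape = mut$gamma_shape, rate = mut$gamma_shape)
    if (!is.null(mut$site_mask)) rates_s[mut$site_mask] <- 0
    root_seq <- if (is.null(mut$root)) sample.int(4L, L, replace = TRUE) else mut$root
    M <- stats::rpois(1L, mut$mu * sum(rates_s) * tbl)
    mut_branch <- if (M > 0L) sample.int(nmax - 1L, M, replace = TRUE,
                                         prob = blen) else integer(0)
    mut_site <- if (M > 0L) sample.int(L, M, replace = TRUE,
                                       prob = rates_s) else integer(0)
    p_ts <- mut$kappa / (mut$kappa + 2)

    # evolve diffs-from-root down the tree (root first)
    by_branch <- split(seq_len(M), factor(mut_branch, levels = seq_len(nmax - 1L)))
    diffs <- vector("list", nmax)
    diffs[[root]] <- list(sites = integer(0), states = integer(0))
    ord <- order(node_time[seq_len(nmax)], decreasing = TRUE)
    ord <- ord[ord != root]
    for (nd in ord) {
      par <- node_parent[nd]
      d0 <- diffs[[par]]
      muts <- by_branch[[nd]]
      if (length(muts)) {
        sites <- d0$sites; states <- d0$states
        for (mm in muts[sample.int(length(muts))]) {
          s <- mut_site[mm]
          i <- match(s, sites)
          cur <- if (!is.na(i)) states[i] else root_seq[s]
          new <- if (stats::runif(1) < p_ts) c(3L, 4L, 1L, 2L)[cur]
                 else if (cur %in% c(1L, 3L)) sample(c(2L, 4L), 1L)
                 else sample(c(1L, 3L), 1L)
          if (!is.na(i)) states[i] <- new
          else { sites <- c(sites, s); states <- c(states, new) }
        }
        diffs[[nd]] <- list(sites = sites, states = states)
      } else diffs[[nd]] <- d0
    }
    seqs <- matrix(rep(root_seq, ntot), nrow = ntot, byrow = TRUE)
    for (i in seq_len(ntot)) {
      d0 <- diffs[[i]]
      if (length(d0$sites)) seqs[i, d0$sites] <- d0$states
    }
    rownames(seqs) <- paste0(tip_deme, "_", stats::ave(seq_len(ntot),
                                                       tip_deme, FUN = seq_along))
    out$seqs <- seqs
    out$n_mutations <- M
  }
  class(out) <- "coalescent_sim"
  out
}

#' @export
print.coalescent_sim <- function(x, ...) {
  cat("coalescent_sim:", length(x$deme), "tips in",
      length(unique(x$deme)), "deme(s); TMRCA =", round(x$tmrca, 1),
      "generations\n")
  if (!is.null(x$seqs))
    cat("  ", x$n_mutations, "mutations over", ncol(x$seqs), "sites\n")
  invisible(x)
}

#' Convert a simulated sample to a character alignment
#'
#' @param sim a `coalescent_sim` with sequences.
#' @return character alignment matrix.
#' @export
sim_to_alignment <- function(sim) {
  if (is.null(sim$seqs)) stop("simulation carries no sequences (mut = NULL)")
  as_alignment(stats::setNames(.int_to_seq(sim$seqs), rownames(sim$seqs)))
}

#' Mean pairwise difference count of a simulated sample
#'
#' @param sim a `coalescent_sim` with sequences.
#' @return mean number of pairwise differences.
#' @export
mean_pairwise_differences <- function(sim) .mean_pairwise_diff(sim$seqs)
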