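# Strict-clock node dating: under a constant substitution rate r
# (substitutions/site/year) the age of a split is t = d/(2r), with d the
# mean K80 distance between the two descendant groups. Confidence
# intervals come from resampling alignment columns (site bootstrap).

# Per-pair site-wise codes for fast bootstrap: for each requested pair,
# 0/1 rows over columns marking comparable sites, transitions and
# transversions.
.pair_site_codes <- function(m, pairs) {
  L <- ncol(m)
  np <- nrow(pairs)
  OK <- matrix(0L, np, L); TS <- matrix(0L, np, L); TV <- matrix(0L, np, L)
  for (p in seq_len(np)) {
    x <- m[pairs[p, 1L], ]; y <- m[pairs[p, 2L], ]
    ok <- x > 0L & y > 0L
    df <- ok & x != y
    ts <- df & abs(x - y) == 2L
    OK[p, ] <- as.integer(ok)
    TS[p, ] <- as.integer(ts)
    TV[p, ] <- as.integer(df & !ts)
  }
  list(OK = OK, TS = TS, TV = TV)
}

# mean K80 distance for every pair given per-column weights w
.k80_pairs_weighted <- function(codes, w, gamma_shape = NULL) {
  nc <- as.numeric(codes$OK %*% w)
  P <- as.numeric(codes$TS %*% w) / nc
  Q <- as.numeric(codes$TV %*% w) / nc
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- rep(NaN, length(P))
  good <- is.finite(w1) & w1 > 0 & w2 > 0
  if (is.null(gamma_shape)) {
    d[good] <- -0.5 * log(w1[good]) - 0.25 * log(w2[good])
  } else {
    a <- gamma_shape
    d[good] <- a / 2 * (w1[good]^(-1 / a) - 1) + a / 4 * (w2[good]^(-1 / a) - 1)
  }
  d
}

#' Date the split between two groups of sequences under a strict clock
#'
#' The split age is \eqn{t = \bar d / (2r)} where \eqn{\bar d} is the mean
#' pairwise K80 distance between members of the two groups and `r` the
#' substitution rate per site per year. The percentile confidence interval
#' is obtained by site bootstrap; replicates in which every between-group
#' pair is saturated are dropped.
#'
#' @param aln alignment containing both groups.
#' @param group_a,group_b vectors of sequence ids (row names) for the two
#'   sides of the split.
#' @param rate substitutions/site/year (e.g. `2.28e-8` for felid ND5).
#' @param n_boot number of site-bootstrap replicates (0 for no CI).
#' @param conf confidence level.
#' @param gamma_shape optional gamma shape for rate heterogeneity.
#' @param seed optional RNG seed.
#' @return list with `age` (years), `ci` (length-2 vector), `d_mean`,
#'   `rate`, `boot_ages`.
#' @export
clock_date_split <- function(aln, group_a, group_b, rate, n_boot = 1000L,
                             conf = 0.95, gamma_shape = NULL, seed = NULL) {
  stopifnot(rate > 0)
  aln <- as_alignment(aln)
  ia <- match(group_a, rownames(aln)); ib <- match(group_b, rownames(aln))
  if (anyNA(ia) || anyNA(ib)) stop("group ids not found in alignment")
  if (length(ia) == 0L || length(ib) == 0L) stop("empty subclade")
  m <- .aln_int(aln)
  pairs <- as.matrix(expand.grid(ia, ib))
  codes <- .pair_site_codes(m, pairs)
  L <- ncol(m)
  w0 <- rep(1, L)
  d0 <- mean(.k80_pairs_weighted(codes, w0, gamma_shape), na.rm = TRUE)
  age <- d0 / (2 * rate)
  ci <- c(NA_real_, NA_real_); boots <- numeric(0)
  if (n_boot > 0L) {
    if (!is.null(seed)) set.seed(seed)
    boots <- vapply(seq_len(n_boot), function(b) {
      w <- tabulate(sample.int(L, L, replace = TRUE), L)
      mean(.k80_pairs_weighted(codes, w, gamma_shape), na.rm = TRUE) / (2 * rate)
    }, numeric(1))
    boots <- boots[is.finite(boots)]
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha)))
  }
  list(age = age, ci = ci, d_mean = d0, rate = rate, boot_ages = boots)
}

#' Date every internal node of a rooted tree under a strict clock
#'
#' For each internal node the age is the mean between-subclade K80 distance
#' of its child clades divided by `2 * rate`; ages are then made monotone
#' (a parent is at least as old as its children) so the dated tree is
#' ultrametric with all tips at age 0.
#'
#' @param tree rooted `phylo` whose tip labels are alignment row names.
#' @param aln alignment.
#' @inheritParams clock_date_split
#' @return object of class `dated_tree`: list with `tree`, `ages` (years,
#'   named by internal node number), `ci` (matrix), `rate`, `calibration`
#'   (NULL until [calibrate_root()] is applied).
#' @export
clock_date_tree <- function(tree, aln, rate, n_boot = 0L, conf = 0.95,
                            gamma_shape = NULL, seed = NULL) {
  stopifnot(rate > 0)
  if (!ape::is.rooted(tree)) stop("tree must be rooted (see root_tree)")
  aln <- as_alignment(aln)
  m <- .aln_int(aln)
  tipidx <- match(tree$tip.label, rownames(aln))
  if (anyNA(tipidx)) stop("tree tips not found in alignment")
  ntip <- length(tree$tip.label)
  nodes <- (ntip + 1L):(ntip + tree$Nnode)

  desc <- phangorn::Descendants(tree, nodes, type = "tips")
  names(desc) <- as.character(nodes)

  # all tip pairs once; per-node cross-pair index sets
  allpairs <- t(utils::combn(ntip, 2L))
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  pairkey <- key(allpairs[, 1L], allpairs[, 2L])
  codes <- .pair_site_codes(m, cbind(tipidx[allpairs[, 1L]], tipidx[allpairs[, 2L]]))
  L <- ncol(m)

  node_pairidx <- lapply(nodes, function(nd) {
    ch <- tree$edge[tree$edge[, 1L] == nd, 2L]
    grps <- lapply(ch, function(c2)
      if (c2 <= ntip) c2 else desc[[as.character(c2)]])
    idx <- integer(0)
    ng <- length(grps)
    for (i in 1:(ng - 1L)) for (j in (i + 1L):ng) {
      eg <- expand.grid(grps[[i]], grps[[j]])
      idx <- c(idx, match(key(eg[, 1L], eg[, 2L]), pairkey))
    }
    idx
  })
  names(node_pairidx) <- as.character(nodes)

  ages_for_w <- function(w) {
    d <- .k80_pairs_weighted(codes, w, gamma_shape)
    vapply(node_pairidx, function(ix) mean(d[ix], na.rm = TRUE), numeric(1)) /
      (2 * rate)
  }
  raw <- ages_for_w(rep(1, L))

  ci <- NULL
  if (n_boot > 0L) {
    if (!is.null(seed)) set.seed(seed)
    bm <- vapply(seq_len(n_boot), function(b) {
      w <- tabulate(sample.int(L, L, replace = TRUE), L)
      ages_for_w(w)
    }, numeric(length(nodes)))
    alpha <- (1 - conf) / 2
    ci <- t(apply(matrix(bm, nrow = length(nodes)), 1L, stats::quantile,
                  probs = c(alpha, 1 - alpha), na.rm = TRUE))
    rownames(ci) <- as.character(nodes)
  }

  # enforce parent age >= child ages (post-order accumulation)
  ages <- raw
  ord <- nodes[order(ape::node.depth(tree)[nodes])]  # shallow first
  for (nd in ord) {
    ch <- tree$edge[tree$edge[, 1L] == nd, 2L]
    ch <- ch[ch > ntip]
    if (length(ch))
      ages[as.character(nd)] <- max(ages[as.character(nd)],
                                    ages[as.character(ch)])
  }

  structure(list(tree = tree, ages = ages, raw_ages = raw, ci = ci,
                 rate = rate, calibration = NULL),
            class = "dated_tree")
}

#' Rescale a dated tree so the root age matches a calibration interval
#'
#' Multiplies every node age by `midpoint / root_age` where `midpoint =
#' (t_min + t_max)/2`; relative node depths are preserved exactly and the
#' implied effective substitution rate is reported.
#'
#' @param dated a `dated_tree` (or a plain named numeric vector of ages
#'   whose first element is the root).
#' @param t_min,t_max calibration interval in years, `t_min < t_max`.
#' @return the input with ages rescaled, plus `calibration` details.
#' @export
calibrate_root <- function(dated, t_min, t_max) {
  if (t_min >= t_max) stop("t_min must be < t_max")
  midpoint <- (t_min + t_max) / 2
  if (inherits(dated, "dated_tree")) {
    ntip <- length(dated$tree$tip.label)
    root_age <- dated$ages[[as.character(ntip + 1L)]]
    if (!is.finite(root_age) || root_age <= 0) stop("root age must be > 0")
    f <- midpoint / root_age
    dated$ages <- dated$ages * f
    dated$raw_ages <- dated$raw_ages * f
    if (!is.null(dated$ci)) dated$ci <- dated$ci * f
    dated$calibration <- list(t_min = t_min, t_max = t_max, factor = f,
                              effective_rate = dated$rate / f)
    dated
  } else {
    root_age <- dated[[1L]]
    if (!is.finite(root_age) || root_age <= 0) stop("root age must be > 0")
    f <- midpoint / root_age
    out <- dated * f
    attr(out, "calibration") <- list(t_min = t_min, t_max = t_max, factor = f)
    out
  }
}

#' @export
print.dated_tree <- function(x, ...) {
  ntip <- length(x$tree$tip.label)
  cat("dated_tree:", ntip, "tips,", x$tree$Nnode, "internal nodes\n")
  cat("  root age:", format(x$ages[[as.character(ntip + 1L)]], big.mark = ","),
      "years (rate", format(x$rate, scientific = TRUE), "/site/year)\n")
  if (!is.null(x$calibration))
    cat("  calibrated to [", x$calibration$t_min, ",", x$calibration$t_max,
        "] years; effective rate", format(x$calibration$effective_rate,
                                          scientific = TRUE), "\n")
  invisible(x)
}

#' Write a dated tree as Newick with node age comments
#'
#' Node labels carry `age[_lo_hi]` annotations in years.
#'
#' @param dated a `dated_tree`.
#' @param path output path.
#' @export
write_dated_tree <- function(dated, path) {
  tr <- dated$tree
  ntip <- length(tr$tip.label)
  lab <- vapply((ntip + 1L):(ntip + tr$Nnode), function(nd) {
    a <- dated$ages[[as.character(nd)]]
    if (!is.null(dated$ci) && as.character(nd) %in% rownames(dated$ci)) {
      ci <- dated$ci[as.character(nd), ]
      sprintf("age=%.0f_CI=%.0f-%.0f", a, ci[1], ci[2])
    } else sprintf("age=%.0f", a)
  }, character(1))
  tr$node.label <- lab
  ape::write.tree(tr, file = path)
  invisible(path)
}
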