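#' Kimura two-parameter (K80) distance between two sequences
#'
#' Closed form \eqn{d = -\frac12\ln(1-2P-Q) - \frac14\ln(1-2Q)} where P and
#' Q are the proportions of sites showing a transition and a transversion,
#' computed over sites where both sequences carry an unambiguous base.
#' With `gamma_shape` set, the gamma-rate-corrected form
#' \eqn{d = \frac{a}{2}[(1-2P-Q)^{-1/a}-1] + \frac{a}{4}[(1-2Q)^{-1/a}-1]}
#' is used instead.
#'
#' Saturation (a non-positive logarithm argument) is signalled by returning
#' a non-finite distance with `saturated = TRUE`.
#'
#' @param a,b sequences (strings or character vectors of bases).
#' @param gamma_shape optional gamma shape for among-site rate variation.
#' @return list with `d`, `P`, `Q`, `p_distance`, `comparable_sites`,
#'   `saturated`.
#' @examples
#' k80_distance("ACGT", "ACGA")$d
#' @export
k80_distance <- function(a, b, gamma_shape = NULL) {
  m <- .aln_int(as_alignment(c(a = paste(toupper(a), collapse = ""),
                               b = paste(toupper(b), collapse = ""))))
  x <- m[1L, ]; y <- m[2L, ]
  ok <- x > 0L & y > 0L
  nc <- sum(ok)
  if (nc == 0L) stop("no comparable sites between the two sequences")
  diffm <- x[ok] != y[ok]
  ts <- sum(diffm & abs(x[ok] - y[ok]) == 2L)
  tv <- sum(diffm) - ts
  P <- ts / nc
  Q <- tv / nc
  k80_from_pq(P, Q, p_distance = (ts + tv) / nc, comparable = nc,
              gamma_shape = gamma_shape)
}

#' @rdname k80_distance
#' @param P,Q transition and transversion proportions.
#' @param p_distance,comparable optional passthrough diagnostics.
#' @export
k80_from_pq <- function(P, Q, p_distance = P + Q, comparable = NA_integer_,
                        gamma_shape = NULL) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  saturated <- w1 <= 0 || w2 <= 0
  d <- if (saturated) {
    NaN
  } else if (is.null(gamma_shape)) {
    -0.5 * log(w1) - 0.25 * log(w2)
  } else {
    a <- gamma_shape
    a / 2 * (w1^(-1 / a) - 1) + a / 4 * (w2^(-1 / a) - 1)
  }
  list(d = d, P = P, Q = Q, p_distance = p_distance,
       comparable_sites = comparable, saturated = saturated)
}

#' Pairwise distance matrix under a named substitution model
#'
#' `"K80"` (the default) uses this package's closed form; `"JC69"`,
#' `"TN93"` (of which HKY is a special case) and `"p"` (raw proportion)
#' delegate to [ape::dist.dna()].
#'
#' @param aln alignment.
#' @param model one of `"K80"`, `"JC69"`, `"TN93"`, `"p"`.
#' @param gamma_shape optional gamma shape (K80 and TN93).
#' @return symmetric numeric matrix with a `"model"` attribute.
#' @export
dist_model <- function(aln, model = c("K80", "JC69", "TN93", "p"),
                       gamma_shape = NULL) {
  model <- match.arg(model)
  aln <- as_alignment(aln)
  n <- nrow(aln)
  if (model == "K80") {
    m <- .aln_int(aln)
    D <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
    if (n > 1L) {
      for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
        x <- m[i, ]; y <- m[j, ]
        ok <- x > 0L & y > 0L
        nc <- sum(ok)
        if (nc == 0L) { D[i, j] <- D[j, i] <- NaN; next }
        dd <- x[ok] != y[ok]
        ts <- sum(dd & abs(x[ok] - y[ok]) == 2L)
        P <- ts / nc; Q <- (sum(dd) - ts) / nc
        D[i, j] <- D[j, i] <- k80_from_pq(P, Q, gamma_shape = gamma_shape)$d
      }
    }
  } else {
    mdl <- if (model == "p") "raw" else model
    g <- if (is.null(gamma_shape)) FALSE else gamma_shape
    D <- as.matrix(ape::dist.dna(.as_dnabin(aln), model = mdl, gamma = g,
                                 pairwise.deletion = TRUE))
  }
  attr(D, "model") <- model
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou & Nei agglomeration via [ape::nj()]; non-finite entries (e.g.
#' saturated K80 distances) abort with the offending pairs listed.
#'
#' @param D symmetric distance matrix with labels.
#' @return unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("neighbor-joining needs at least 3 taxa")
  bad <- which(!is.finite(D) & upper.tri(D), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    pairs <- apply(bad, 1L, function(ij)
      paste(rownames(D)[ij[1]], colnames(D)[ij[2]], sep = "~"))
    stop("non-finite distances for pair(s): ",
         paste(utils::head(pairs, 5L), collapse = ", "))
  }
  ape::nj(stats::as.dist(D))
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns `B` times, rebuilds the NJ tree under the
#' same distance model, and reports for each internal node of `tree` the
#' proportion of replicates containing that clade.
#'
#' @param tree reference tree (defaults to NJ on the full alignment).
#' @param aln alignment.
#' @param B number of bootstrap replicates.
#' @param model distance model passed to [dist_model()].
#' @param seed optional RNG seed.
#' @return numeric vector of support values in `[0, 1]`, one per internal
#'   node of `tree`.
#' @export
bootstrap_support <- function(aln, tree = NULL, B = 1000L, model = "K80",
                              seed = NULL) {
  aln <- as_alignment(aln)
  if (!is.null(seed)) set.seed(seed)
  build <- function(x) nj_tree(dist_model(x, model = model))
  if (is.null(tree)) tree <- build(aln)
  counts <- ape::boot.phylo(tree, aln, build, B = B, quiet = TRUE,
                            rooted = FALSE)
  counts / B
}

#' Root a tree on an outgroup or at its midpoint
#'
#' @param tree unrooted `phylo`.
#' @param outgroup optional tip label; when absent the tree is midpoint
#'   rooted (via phangorn).
#' @return rooted `phylo`.
#' @export
root_tree <- function(tree, outgroup = NULL) {
  if (!is.null(outgroup)) {
    if (!outgroup %in% tree$tip.label)
      stop("outgroup '", outgroup, "' is not a tip of the tree")
    ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  } else {
    phangorn::midpoint(tree)
  }
}
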