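# Median-joining haplotype networks (Bandelt, Forster & Roehl 1999 style):
# iteratively build an epsilon-relaxed minimum spanning network over the
# current node set, add quasi-medians of mutually connected triplets, and
# finally prune median vectors of degree <= 2.

# weighted Hamming cost between integer-coded sequences; transitions cost
# weights["ts"], transversions weights["tv"]; sites with an uncalled base
# in either sequence are skipped.
.whamming <- function(x, y, weights) {
  ok <- x > 0L & y > 0L
  df <- ok & x != y
  ts <- df & abs(x - y) == 2L
  sum(ts) * weights[["ts"]] + sum(df & !ts) * weights[["tv"]]
}

.wdist_matrix <- function(m, weights) {
  n <- nrow(m)
  D <- matrix(0, n, n)
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n)
    D[i, j] <- D[j, i] <- .whamming(m[i, ], m[j, ], weights)
  D
}

# Kruskal MST on a dense distance matrix; returns edge index matrix.
.mst_edges <- function(D) {
  n <- nrow(D)
  if (n < 2L) return(matrix(integer(0), 0L, 2L))
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  ord <- order(D[upper.tri(D)], pairs[, 1L], pairs[, 2L])
  pairs <- pairs[ord, , drop = FALSE]
  comp <- seq_len(n)
  keep <- matrix(integer(0), 0L, 2L)
  for (e in seq_len(nrow(pairs))) {
    a <- comp[pairs[e, 1L]]; b <- comp[pairs[e, 2L]]
    if (a != b) {
      comp[comp == b] <- a
      keep <- rbind(keep, pairs[e, , drop = FALSE])
      if (nrow(keep) == n - 1L) break
    }
  }
  keep
}

# bottleneck (minimax-path) distances from an MST: b[u,v] = largest edge
# weight on the unique MST path between u and v.
.bottleneck <- function(D, mst) {
  n <- nrow(D)
  B <- matrix(0, n, n)
  adj <- vector("list", n)
  for (e in seq_len(nrow(mst))) {
    i <- mst[e, 1L]; j <- mst[e, 2L]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  for (s in seq_len(n)) {
    seen <- rep(FALSE, n); seen[s] <- TRUE
    queue <- s
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      for (v in adj[[u]]) if (!seen[v]) {
        seen[v] <- TRUE
        B[s, v] <- max(B[s, u], D[u, v])
        queue <- c(queue, v)
      }
    }
  }
  B
}

#' Epsilon-relaxed minimum spanning network
#'
#' Contains every edge `(u, v)` whose cost is within `epsilon` of the
#' bottleneck (minimax MST path) cost between `u` and `v`; at `epsilon = 0`
#' this is the strict minimum spanning network, whose edge set contains
#' every minimum spanning tree.
#'
#' @param D symmetric cost matrix.
#' @param epsilon non-negative relaxation parameter.
#' @return integer matrix of edges (columns `from`, `to`).
#' @export
msn_edges <- function(D, epsilon = 0) {
  if (epsilon < 0) stop("epsilon must be >= 0")
  D <- as.matrix(D)
  mst <- .mst_edges(D)
  B <- .bottleneck(D, mst)
  idx <- which(upper.tri(D) & D <= B + epsilon + 1e-9, arr.ind = TRUE)
  colnames(idx) <- c("from", "to")
  idx
}

# quasi-median(s) of three sequences: site-wise majority state; at sites
# where all three states differ, each observed state is a valid resolution
# and the candidates multiply (capped by the caller).
.quasi_medians <- function(u, v, w, max_out = 27L) {
  base <- u
  tie_vw <- v == w & u != v & v > 0L
  base[tie_vw] <- v[tie_vw]
  called <- u > 0L & v > 0L & w > 0L
  free <- which(called & u != v & u != w & v != w)
  if (length(free) == 0L) return(matrix(base, 1L))
  if (3^length(free) > max_out) free <- free[seq_len(floor(log(max_out, 3)))]
  if (length(free) == 0L) return(matrix(base, 1L))
  combos <- expand.grid(rep(list(1:3), length(free)))
  out <- matrix(rep(base, nrow(combos)), nrow = nrow(combos), byrow = TRUE)
  for (k in seq_along(free)) {
    s <- free[k]
    states <- c(u[s], v[s], w[s])
    out[, s] <- states[combos[, k]]
  }
  out
}

#' Median-joining network of haplotypes
#'
#' Iterates: build the epsilon-relaxed minimum spanning network on weighted
#' Hamming distances (transitions cost `weights["ts"]`, transversions
#' `weights["tv"]`); for every triplet of mutually connected nodes add its
#' quasi-median sequence(s), keeping a candidate only when it connects its
#' triplet more cheaply than direct edges do (a Steiner-point gain, which
#' prunes the combinatorial blow-up at large epsilon); stop when no new
#' medians appear (or `max_iter`); finally delete median vectors of degree
#' <= 2 and rebuild. New medians per iteration are additionally capped at
#' `max_medians` to guarantee termination.
#'
#' @param hap a `haplotype_dataset`, alignment matrix, or named character
#'   vector of distinct haplotype sequences.
#' @param epsilon relaxation parameter (default 10, the setting used for
#'   weighted felid ND5 data).
#' @param weights named costs for `ts` and `tv` changes (default 1 and 3).
#' @param max_medians cap on new median vectors per iteration.
#' @param max_iter cap on median-joining iterations.
#' @return object of class `haplo_network`: list with `nodes` (data frame:
#'   id, type observed/median, frequency, category), `edges` (data frame:
#'   from, to, cost, n_sites, sites), `seqs` (integer matrix), `epsilon`,
#'   `weights`.
#' @examples
#' net <- mj_network(c(h1 = "AAT", h2 = "ATA", h3 = "TAA"), epsilon = 0)
#' net$nodes
#' @export
mj_network <- function(hap, epsilon = 10, weights = c(ts = 1, tv = 3),
                       max_medians = 1000L, max_iter = 20L) {
  if (epsilon < 0) stop("epsilon must be >= 0")
  freq <- NULL; category <- NULL
  if (inherits(hap, "haplotype_dataset")) {
    seqs <- hap$haplotypes
    freq <- hap$counts
    category <- hap$category
  } else {
    aln <- as_alignment(hap)
    seqs <- stats::setNames(.aln_strings(aln), rownames(aln))
  }
  if (length(seqs) < 2L) stop("need at least 2 haplotypes")
  # canonical input order: by label
  seqs <- seqs[order(names(seqs))]
  m <- .aln_int(as_alignment(seqs))
  n_obs <- nrow(m)
  seen <- stats::setNames(seq_len(n_obs), .int_key(m))

  for (it in seq_len(max_iter)) {
    D <- .wdist_matrix(m, weights)
    ed <- msn_edges(D, epsilon)
    adj <- matrix(FALSE, nrow(m), nrow(m))
    adj[ed] <- TRUE; adj[ed[, 2:1, drop = FALSE]] <- TRUE
    new_rows <- NULL
    budget <- max_medians
    nn <- nrow(m)
    if (nn >= 3L) {
      for (i in 1:(nn - 2L)) for (j in (i + 1L):(nn - 1L)) {
        if (!adj[i, j]) next
        for (k in (j + 1L):nn) {
          if (!(adj[i, k] && adj[j, k])) next
          med <- .quasi_medians(m[i, ], m[j, ], m[k, ])
          # cheapest direct connection of the triple: two smallest sides
          sides <- c(D[i, j], D[i, k], D[j, k])
          direct <- sum(sides) - max(sides)
          for (r in seq_len(nrow(med))) {
            kk <- .int_key(med[r, , drop = FALSE])
            if (!kk %in% names(seen) &&
                !kk %in% names(new_rows)) {
              # keep only medians that act as Steiner points for the triple
              star <- .whamming(med[r, ], m[i, ], weights) +
                .whamming(med[r, ], m[j, ], weights) +
                .whamming(med[r, ], m[k, ], weights)
              if (star < direct) {
                new_rows <- c(new_rows, stats::setNames(list(med[r, ]), kk))
                budget <- budget - 1L
              }
            }
            if (budget <= 0L) break
          }
          if (budget <= 0L) break
        }
        if (budget <= 0L) break
      }
    }
    if (length(new_rows) == 0L) break
    add <- do.call(rbind, new_rows)
    m <- rbind(m, add)
    seen <- stats::setNames(seq_len(nrow(m)), .int_key(m))
  }

  # prune median vectors of degree <= 2, iteratively
  repeat {
    D <- .wdist_matrix(m, weights)
    ed <- msn_edges(D, epsilon)
    deg <- tabulate(c(ed), nrow(m))
    drop <- which(seq_len(nrow(m)) > n_obs & deg <= 2L)
    if (length(drop) == 0L) break
    m <- m[-drop, , drop = FALSE]
  }

  n_med <- nrow(m) - n_obs
  node_ids <- c(names(seqs), if (n_med > 0L) sprintf("mv%d", seq_len(n_med)))
  rownames(m) <- node_ids
  nodes <- data.frame(
    id = node_ids,
    type = c(rep("observed", n_obs), rep("median", n_med)),
    frequency = c(if (is.null(freq)) rep(1L, n_obs) else
      as.integer(freq[names(seqs)]), rep(0L, n_med)),
    category = c(if (is.null(category)) rep(NA_character_, n_obs) else
      as.character(category[names(seqs)]), rep(NA_character_, n_med)),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    from = node_ids[ed[, 1L]], to = node_ids[ed[, 2L]],
    cost = D[ed], stringsAsFactors = FALSE
  )
  edges$n_sites <- NA_integer_; edges$sites <- NA_character_
  for (e in seq_len(nrow(edges))) {
    x <- m[ed[e, 1L], ]; y <- m[ed[e, 2L], ]
    df <- which(x > 0L & y > 0L & x != y)
    edges$n_sites[e] <- length(df)
    edges$sites[e] <- paste(df, collapse = ",")
  }
  ord <- order(edges$from, edges$to)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, seqs = m,
                 epsilon = epsilon, weights = weights),
            class = "haplo_network")
}

.int_key <- function(m) apply(m, 1L, paste, collapse = ".")

#' @export
print.haplo_network <- function(x, ...) {
  cat("haplo_network:", sum(x$nodes$type == "observed"), "observed haplotypes,",
      sum(x$nodes$type == "median"), "median vectors,",
      nrow(x$edges), "edges (epsilon =", x$epsilon, ")\n")
  invisible(x)
}

#' Assign a haplotype to a lineage using a diagnostic site panel
#'
#' @param haplotype sequence string or character vector of bases.
#' @param panel data frame with columns `pos` (1-based alignment position),
#'   `D` and `W` (expected bases per lineage); `D` and `W` must differ at
#'   every panel site.
#' @return list with `lineage` (`"D"`, `"W"` or `"conflict"`), `states`
#'   (per-site observed/expected table) and `reason` for conflicts.
#' @export
assign_lineage <- function(haplotype, panel) {
  stopifnot(all(c("pos", "D", "W") %in% names(panel)))
  if (anyDuplicated(panel$pos)) stop("panel positions must be unique")
  if (any(toupper(panel$D) == toupper(panel$W)))
    stop("panel D and W states must differ at every site")
  s <- strsplit(paste(toupper(haplotype), collapse = ""), "")[[1L]]
  if (max(panel$pos) > length(s)) stop("haplotype does not cover all panel positions")
  obs <- s[panel$pos]
  states <- data.frame(pos = panel$pos, observed = obs,
                       D = toupper(panel$D), W = toupper(panel$W))
  if (any(!obs %in% .BASES)) {
    return(list(lineage = "conflict", states = states, reason = "ambiguous"))
  }
  if (all(obs == states$D)) return(list(lineage = "D", states = states, reason = NULL))
  if (all(obs == states$W)) return(list(lineage = "W", states = states, reason = NULL))
  list(lineage = "conflict", states = states, reason = "mixed diagnostic states")
}

#' Write a haplotype network as GML
#'
#' @param net a `haplo_network`.
#' @param path output path.
#' @export
write_gml <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("graph [", con)
  writeLines("  directed 0", con)
  idx <- stats::setNames(seq_len(nrow(net$nodes)) - 1L, net$nodes$id)
  for (i in seq_len(nrow(net$nodes))) {
    nd <- net$nodes[i, ]
    writeLines(c("  node [",
                 paste0("    id ", idx[[nd$id]]),
                 paste0("    label \"", nd$id, "\""),
                 paste0("    type \"", nd$type, "\""),
                 paste0("    frequency ", nd$frequency),
                 "  ]"), con)
  }
  for (e in seq_len(nrow(net$edges))) {
    ed <- net$edges[e, ]
    writeLines(c("  edge [",
                 paste0("    source ", idx[[ed$from]]),
                 paste0("    target ", idx[[ed$to]]),
                 paste0("    weight ", format(ed$cost)),
                 paste0("    sites \"", ed$sites, "\""),
                 "  ]"), con)
  }
  writeLines("]", con)
  invisible(path)
}

#' Write network edges as TSV
#'
#' @param net a `haplo_network`.
#' @param path output path.
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
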