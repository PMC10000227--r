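#' Collapse aligned sequences into haplotypes
#'
#' Identical sequence strings are collapsed to a single haplotype (exact
#' string identity only: sequences containing `N` collapse only when the
#' whole string matches, no wildcard logic). When sample metadata is given,
#' every haplotype is assigned a carrier category in the style used for
#' wild/domestic cat surveys: `"d"` = carried only by domestic samples,
#' `"w"` = carried only by wild or admixed samples, `"dw"` = carried on both
#' sides.
#'
#' Haplotype ids are canonical: haplotypes are ordered by decreasing carrier
#' count, ties broken by sequence string, so permuting the input rows
#' changes nothing.
#'
#' @param aln alignment matrix or named character vector of sequences.
#' @param metadata optional data frame with columns `sample_id` and `class`
#'   (`wild`/`domestic`/`admixed`); extra grouping columns (e.g.
#'   `macro_region`) are tabulated per haplotype when present.
#' @return an object of class `haplotype_dataset`: a list with elements
#'   `haplotypes` (named id -> sequence), `counts`, `carriers` (list of
#'   sample ids), `category` (d/dw/w or NA without metadata), `assignment`
#'   (haplotype id per sample), `n`, `L`, `S` (segregating sites), `PI`
#'   (parsimony-informative sites), and `class_counts` / `region_counts`
#'   matrices when metadata is supplied.
#' @examples
#' aln <- as_alignment(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGA"))
#' h <- collapse_haplotypes(aln)
#' h$counts
#' @export
collapse_haplotypes <- function(aln, metadata = NULL) {
  aln <- as_alignment(aln)
  if (nrow(aln) == 0L) stop("empty alignment")
  seqs <- .aln_strings(aln)
  ids <- rownames(aln)

  first <- !duplicated(seqs)
  uniq <- seqs[first]
  cnt <- as.integer(table(factor(seqs, levels = uniq)))
  ord <- order(-cnt, uniq)
  uniq <- uniq[ord]
  cnt <- cnt[ord]
  hap_ids <- sprintf("H%02d", seq_along(uniq))
  names(uniq) <- hap_ids

  assignment <- hap_ids[match(seqs, uniq)]
  names(assignment) <- ids
  carriers <- split(ids, factor(assignment, levels = hap_ids))

  poly <- .polymorphic_sites(aln)

  out <- list(
    haplotypes = uniq,
    counts = stats::setNames(cnt, hap_ids),
    carriers = carriers,
    assignment = assignment,
    category = stats::setNames(rep(NA_character_, length(uniq)), hap_ids),
    n = nrow(aln),
    L = ncol(aln),
    S = poly$S,
    PI = poly$PI,
    seq_matrix = as_alignment(stats::setNames(uniq, hap_ids))
  )

  if (!is.null(metadata)) {
    idx <- match(ids, metadata$sample_id)
    if (anyNA(idx)) stop("metadata is missing sample(s): ",
                         paste(utils::head(ids[is.na(idx)], 3L), collapse = ", "))
    cls <- metadata$class[idx]
    tab <- table(factor(assignment, levels = hap_ids),
                 factor(cls, levels = c("wild", "domestic", "admixed")))
    out$class_counts <- unclass(tab)
    dom <- tab[, "domestic"] > 0
    wld <- tab[, "wild"] + tab[, "admixed"] > 0
    out$category <- stats::setNames(
      ifelse(dom & wld, "dw", ifelse(dom, "d", "w")), hap_ids)
    if ("macro_region" %in% names(metadata)) {
      out$region_counts <- unclass(table(factor(assignment, levels = hap_ids),
                                         metadata$macro_region[idx]))
    }
  }
  class(out) <- "haplotype_dataset"
  out
}

#' @export
print.haplotype_dataset <- function(x, ...) {
  cat("haplotype_dataset:", length(x$haplotypes), "haplotypes from", x$n,
      "sequences of", x$L, "bp\n")
  cat("  segregating sites S =", x$S, "; parsimony-informative =", x$PI, "\n")
  if (!all(is.na(x$category)))
    cat("  categories:", paste(names(table(x$category)), table(x$category),
                               sep = "=", collapse = " "), "\n")
  invisible(x)
}

# Segregating and parsimony-informative sites over unambiguous (A/C/G/T)
# states; columns where fewer than two sequences carry a called base are
# ignored.
.polymorphic_sites <- function(aln) {
  m <- .aln_int(aln)
  S <- 0L; PI <- 0L
  vary <- which(colSums(m != matrix(m[1L, ], nrow(m), ncol(m),
                                    byrow = TRUE)) > 0L)
  for (j in vary) {
    x <- m[, j]
    x <- x[x > 0L]
    if (length(x) < 2L) next
    tab <- tabulate(x, 4L)
    k <- sum(tab > 0L)
    if (k >= 2L) {
      S <- S + 1L
      if (sum(tab >= 2L) >= 2L) PI <- PI + 1L
    }
  }
  list(S = S, PI = PI)
}

#' Haplotype (gene) diversity with sampling standard deviation
#'
#' Nei's unbiased estimator \eqn{H_d = n(1 - \sum p_i^2)/(n - 1)} with its
#' sampling variance (Nei 1987, eqs. 8.4 and 8.12).
#'
#' @param counts integer vector of per-haplotype carrier counts
#'   (or a `haplotype_dataset`).
#' @return list with `Hd` and `sd`.
#' @examples
#' haplotype_diversity(c(2, 2))$Hd  # 2/3
#' @export
haplotype_diversity <- function(counts) {
  if (inherits(counts, "haplotype_dataset")) counts <- counts$counts
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("haplotype diversity undefined for fewer than 2 samples")
  p <- counts / n
  s2 <- sum(p^2)
  Hd <- n * (1 - s2) / (n - 1)
  v <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - s2^2) + s2 - s2^2)
  list(Hd = Hd, sd = sqrt(max(v, 0)))
}

#' Nucleotide diversity per site, with SD and mean pairwise differences
#'
#' \eqn{\pi} is the average over all sequence pairs of the proportion of
#' differing sites; site pairs where either base is ambiguous (`N`) or a gap
#' are skipped (pairwise deletion). `k` is the corresponding mean count of
#' pairwise differences, so `k = pi * L` exactly when no ambiguous sites are
#' present. The SD is from Nei's (1987, eq. 10.7) total variance, which
#' combines stochastic and sampling terms.
#'
#' @param aln alignment matrix or named character vector of sequences.
#' @return list with `pi`, `sd`, `k`, `n`, `L`.
#' @export
nucleotide_diversity <- function(aln) {
  aln <- as_alignment(aln)
  n <- nrow(aln)
  if (n < 2) stop("nucleotide diversity undefined for fewer than 2 sequences")
  L <- ncol(aln)

  # collapse to unique sequences and weight pairs by carrier counts
  seqs <- .aln_strings(aln)
  uniq <- unique(seqs)
  cnt <- as.integer(table(factor(seqs, levels = uniq)))
  m <- .aln_int(as_alignment(stats::setNames(uniq, paste0("u", seq_along(uniq)))))
  H <- length(uniq)

  tot_prop <- 0
  tot_diff <- 0
  if (H > 1L) {
    for (i in 1:(H - 1L)) {
      for (j in (i + 1L):H) {
        a <- m[i, ]; b <- m[j, ]
        ok <- a > 0L & b > 0L
        nc <- sum(ok)
        if (nc == 0L) next
        nd <- sum(a[ok] != b[ok])
        w <- cnt[i] * cnt[j]
        tot_prop <- tot_prop + w * nd / nc
        tot_diff <- tot_diff + w * nd
      }
    }
  }
  npairs <- n * (n - 1) / 2
  pi <- tot_prop / npairs
  k <- tot_diff / npairs
  v <- (n + 1) / (3 * (n - 1)) * pi / L +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  list(pi = pi, sd = sqrt(max(v, 0)), k = k, n = n, L = L)
}

#' Per-group diversity summary table
#'
#' Convenience wrapper producing one row per group (and overall) with sample
#' size, haplotype count, nucleotide diversity and haplotype diversity, in
#' the column layout of a standard mtDNA survey table. `pi` is per site;
#' `pi_x100` is the same value scaled by 100 for display.
#'
#' @param aln alignment.
#' @param groups factor/character vector of group labels, one per sequence
#'   (alignment row order), or NULL for a single overall row.
#' @return data frame with one row per group plus `"overall"`.
#' @export
diversity_table <- function(aln, groups = NULL) {
  aln <- as_alignment(aln)
  grp <- if (is.null(groups)) rep("overall", nrow(aln)) else as.character(groups)
  rows <- lapply(unique(c("overall", grp)), function(g) {
    sub <- if (g == "overall") aln else aln[grp == g, , drop = FALSE]
    n <- nrow(sub)
    nh <- length(unique(.aln_strings(sub)))
    if (n >= 2 && nh >= 2) {
      nd <- nucleotide_diversity(sub)
      hd <- haplotype_diversity(table(.aln_strings(sub)))
      data.frame(group = g, N = n, n_haplotypes = nh,
                 pi = nd$pi, pi_sd = nd$sd, pi_x100 = 100 * nd$pi, k = nd$k,
                 Hd = hd$Hd, Hd_sd = hd$sd)
    } else {
      data.frame(group = g, N = n, n_haplotypes = nh,
                 pi = if (n >= 2) 0 else NA_real_, pi_sd = if (n >= 2) 0 else NA_real_,
                 pi_x100 = if (n >= 2) 0 else NA_real_, k = if (n >= 2) 0 else NA_real_,
                 Hd = if (n >= 2 && nh == 1L) 0 else NA_real_,
                 Hd_sd = if (n >= 2 && nh == 1L) 0 else NA_real_)
    }
  })
  do.call(rbind, rows)
}

#' Write a haplotype table TSV
#'
#' @param hap a `haplotype_dataset`.
#' @param path output path.
#' @export
write_haplotype_table <- function(hap, path) {
  df <- data.frame(haplotype_id = names(hap$haplotypes),
                   count = as.integer(hap$counts),
                   category = hap$category,
                   sequence = unname(hap$haplotypes))
  if (!is.null(hap$class_counts))
    df <- cbind(df, as.data.frame.matrix(hap$class_counts))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
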