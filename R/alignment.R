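# Internal sequence encoding: A=1, C=2, G=3, T=4, anything else (N, -, ?) = 0.
# With this coding a substitution is a transition iff |a - b| == 2
# (A<->G and C<->T), which the distance and network code exploits.
.BASES <- c("A", "C", "G", "T")

.base_codes <- local({
  m <- integer(256)
  m[utf8ToInt("A")] <- 1L; m[utf8ToInt("a")] <- 1L
  m[utf8ToInt("C")] <- 2L; m[utf8ToInt("c")] <- 2L
  m[utf8ToInt("G")] <- 3L; m[utf8ToInt("g")] <- 3L
  m[utf8ToInt("T")] <- 4L; m[utf8ToInt("t")] <- 4L
  m
})

#' Build an alignment matrix from sequence strings
#'
#' An alignment is represented as a character matrix (rows = samples,
#' columns = sites, uppercase bases). Most functions in the package accept
#' either this matrix form or a named character vector of equal-length
#' sequence strings and convert internally.
#'
#' @param seqs named character vector of equal-length sequences, or an
#'   existing character matrix.
#' @param ids optional sample identifiers (defaults to `names(seqs)`).
#' @param window optional 1-based inclusive reference coordinates of the
#'   fragment, length-2 integer; stored as an attribute, metadata only.
#' @return character matrix with one row per sample.
#' @examples
#' aln <- as_alignment(c(s1 = "ACGT", s2 = "ACGA"))
#' dim(aln)
#' @export
as_alignment <- function(seqs, ids = NULL, window = NULL) {
  if (is.matrix(seqs)) {
    m <- toupper(seqs)
    if (!is.null(ids)) rownames(m) <- ids
  } else {
    if (is.null(ids)) ids <- names(seqs)
    seqs <- as.character(seqs)
    if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
    if (length(seqs) == 0L) stop("empty alignment")
    nc <- nchar(seqs)
    if (length(unique(nc)) != 1L) {
      bad <- ids[nc != nc[1L]][1L]
      stop("sequences have unequal lengths (first offender: '", bad, "')")
    }
    m <- matrix(toupper(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)),
                nrow = length(seqs), byrow = TRUE)
    rownames(m) <- ids
  }
  if (anyDuplicated(rownames(m))) stop("duplicated sample ids in alignment")
  if (!is.null(window)) attr(m, "window") <- as.integer(window)
  m
}

# integer-coded alignment (rows = samples)
.aln_int <- function(aln) {
  if (is.integer(aln)) return(aln)
  aln <- as_alignment(aln)
  idx <- utf8ToInt(paste(t(aln), collapse = ""))
  m <- matrix(.base_codes[idx], nrow = nrow(aln), byrow = TRUE)
  rownames(m) <- rownames(aln)
  m
}

.int_to_seq <- function(m) {
  ch <- c("N", .BASES)[m + 1L]
  apply(matrix(ch, nrow = nrow(m)), 1L, paste, collapse = "")
}

# row strings of a character alignment
.aln_strings <- function(aln) {
  if (!is.matrix(aln)) return(toupper(as.character(aln)))
  apply(aln, 1L, paste, collapse = "")
}

.as_dnabin <- function(aln) {
  aln <- as_alignment(aln)
  ape::as.DNAbin(matrix(tolower(aln), nrow = nrow(aln),
                        dimnames = list(rownames(aln), NULL)))
}
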