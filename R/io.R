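#' Read an aligned multi-FASTA file
#'
#' Sequences are uppercased and must all have the same length; ragged input
#' is rejected with the offending record named.
#'
#' @param path path to a FASTA file.
#' @return character alignment matrix (see [as_alignment()]).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("no sequences in ", path)
  lens <- lengths(dna)
  if (length(unique(lens)) != 1L) {
    bad <- names(dna)[lens != lens[1L]][1L]
    stop("sequences have unequal lengths (record '", bad, "' has ",
         lens[names(dna) == bad][1L], " bp, expected ", lens[1L], ")")
  }
  ch <- toupper(as.character(as.matrix(dna)))
  as_alignment(ch)
}

#' Write an alignment as wrapped multi-FASTA
#'
#' @param aln alignment matrix or named character vector of sequences.
#' @param path output path.
#' @param width line wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path, width = 60L) {
  aln <- as_alignment(aln)
  seqs <- .aln_strings(aln)
  ids <- rownames(aln)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", ids[i]), con)
    s <- seqs[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expects a tab-separated file with header columns `sample_id`, `class`
#' (`wild`, `domestic` or `admixed`), `macro_region`, `sub_region`, `lat`,
#' `lon`.
#'
#' @param path path to the TSV file.
#' @return data frame of sample metadata.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "class", "macro_region", "sub_region", "lat", "lon")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata is missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(md$class), c("wild", "domestic", "admixed"))
  if (length(bad)) stop("unknown sample class(es): ", paste(bad, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stop("duplicated sample_id in metadata")
  md
}

#' @rdname read_metadata
#' @param metadata data frame as returned by [read_metadata()].
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Deterministic derivation of per-stage seeds from the global seed, so that
# toggling one stage never shifts the randomness of another. Offsets are
# fixed per stage name; results stay below 2^31.
.STAGE_OFFSETS <- c(simulate = 101L, haplotypes = 211L, tree = 307L,
                    network = 401L, amova = 503L, samova = 601L,
                    neutrality = 701L, abc = 809L, pipeline = 907L)

#' Derive the RNG seed for a named pipeline stage
#'
#' @param seed global integer seed.
#' @param stage stage name, one of `names(mitophylo:::.STAGE_OFFSETS)`.
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage) {
  off <- .STAGE_OFFSETS[[stage]]
  as.integer((as.numeric(seed) * 1009 + off * 7919) %% 2147483647)
}
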