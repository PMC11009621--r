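## TE consensus library: loading, validation, homopolymer annotation.
## All coordinates are 0-based half-open internally.

#' Load a TE consensus library and single-copy normalization genes
#'
#' Reads the TE family consensus sequences and the single-copy gene set used
#' for coverage normalization, validates them, and annotates homopolymer
#' runs (the poly-A tracts at which coverage is curbed downstream).
#'
#' @param te_fasta Path to the FASTA file of TE family consensus sequences.
#' @param gene_fasta Path to the FASTA file of single-copy genes (e.g.
#'   rhino, traffic jam, rpl32 in the fly library this emulates).
#' @param ltr_lengths Optional named numeric vector giving the LTR length
#'   (bp) of LTR retrotransposon families; names must be family ids.
#' @param min_homopolymer Minimum run length (bp) annotated as a
#'   homopolymer; default 8.
#' @return An object of class `te_library` with elements `families` (named
#'   list of `te_consensus`), `genes` (named character vector) and
#'   `homopolymer_runs` (named list of 0-based half-open interval matrices).
#' @export
load_library <- function(te_fasta, gene_fasta, ltr_lengths = NULL,
                         min_homopolymer = 8) {
  tes <- read_fasta(te_fasta)
  genes <- read_fasta(gene_fasta)
  build_library(tes, genes, ltr_lengths = ltr_lengths,
                min_homopolymer = min_homopolymer)
}

#' Build a TE library from in-memory sequences
#'
#' @param tes Named character vector of TE consensus sequences.
#' @param genes Named character vector of single-copy gene sequences.
#' @inheritParams load_library
#' @return A `te_library` object; see [load_library()].
#' @export
build_library <- function(tes, genes, ltr_lengths = NULL,
                          min_homopolymer = 8) {
  validate_seqs <- function(seqs, what) {
    dup <- names(seqs)[duplicated(names(seqs))]
    if (length(dup) > 0) {
      stop("duplicate ", what, " identifier(s): ",
           paste(unique(dup), collapse = ", "))
    }
    empty <- names(seqs)[nchar(seqs) == 0]
    if (length(empty) > 0) {
      stop("empty sequence for ", what, ": ", paste(empty, collapse = ", "))
    }
    bad <- gsub("[ACGTN]", "", seqs)
    if (any(nchar(bad) > 0)) {
      offending <- unique(strsplit(paste(bad, collapse = ""), "")[[1]])
      stop("non-ACGTN character(s) in ", what, " sequences: ",
           paste(offending, collapse = ", "))
    }
  }
  tes <- toupper(tes)
  genes <- toupper(genes)
  validate_seqs(tes, "TE family")
  validate_seqs(genes, "gene")
  both <- intersect(names(tes), names(genes))
  if (length(both) > 0) {
    stop("identifier(s) used for both a TE family and a gene: ",
         paste(both, collapse = ", "))
  }
  families <- lapply(names(tes), function(id) {
    ltr <- if (!is.null(ltr_lengths) && id %in% names(ltr_lengths))
      as.integer(ltr_lengths[[id]]) else NA_integer_
    len <- nchar(tes[[id]])
    if (!is.na(ltr) && !(ltr > 0 && ltr < len / 2)) {
      stop("ltr_length for ", id, " must lie in (0, length/2)")
    }
    structure(list(family_id = id, sequence = tes[[id]], length = len,
                   ltr_length = ltr), class = "te_consensus")
  })
  names(families) <- names(tes)
  runs <- lapply(tes, find_homopolymer_runs, min_len = min_homopolymer)
  structure(list(families = families, genes = genes,
                 homopolymer_runs = runs,
                 min_homopolymer = min_homopolymer),
            class = "te_library")
}

#' @export
print.te_library <- function(x, ...) {
  cat("te_library:", length(x$families), "TE families,",
      length(x$genes), "normalization genes\n")
  invisible(x)
}

# All reference sequences the aligner sees: families first, then genes.
library_seqs <- function(library) {
  c(vapply(library$families, `[[`, "", "sequence"), library$genes)
}

#' Find maximal homopolymer runs in a sequence
#'
#' @param seq DNA sequence (single string).
#' @param min_len Minimum run length reported; must be >= 2.
#' @return Integer matrix with columns `start`, `end`: maximal runs of one
#'   repeated base, 0-based half-open, sorted and non-overlapping.
#' @export
find_homopolymer_runs <- function(seq, min_len = 8) {
  stopifnot(min_len >= 2)
  empty <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nchar(seq) == 0) return(empty)
  r <- rle(strsplit(seq, "")[[1]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$lengths >= min_len
  if (!any(keep)) return(empty)
  cbind(start = starts[keep], end = ends[keep])
}

#' Write the TE library back to FASTA files
#'
#' @param library A `te_library`.
#' @param te_fasta,gene_fasta Output paths.
#' @export
write_library <- function(library, te_fasta, gene_fasta) {
  write_fasta(vapply(library$families, `[[`, "", "sequence"), te_fasta)
  write_fasta(library$genes, gene_fasta)
  invisible(library)
}

#' Tabular manifest of a TE library
#'
#' @param library A `te_library`.
#' @return Data frame with one row per family: id, length, LTR length.
#' @export
library_manifest <- function(library) {
  data.frame(
    family_id = vapply(library$families, `[[`, "", "family_id"),
    length = vapply(library$families, `[[`, 0L, "length"),
    ltr_length = vapply(library$families, `[[`, NA_integer_, "ltr_length"),
    row.names = NULL, stringsAsFactors = FALSE)
}
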