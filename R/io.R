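## Sequence file I/O. FASTA goes through Biostrings; FASTQ uses a strict
## 4-line parser so that malformed records can be reported by record number.

#' Read a FASTA file into a named character vector
#'
#' @param path Path to a (possibly multi-line) FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA, wrapped at 60 columns
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), !anyNA(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = 60)
    writeLines(substring(s, starts, pmin(starts + 59, nchar(s))), con)
  }
  invisible(path)
}

#' Read a 4-line FASTQ file
#'
#' Errors name the first malformed record (1-based record number).
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return Data frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ: truncated record ", length(lines) %/% 4 + 1,
         " in ", path)
  }
  n <- length(lines) %/% 4
  if (n == 0) {
    return(data.frame(id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  }
  hdr <- lines[seq(1, length(lines), by = 4)]
  seq <- lines[seq(2, length(lines), by = 4)]
  plus <- lines[seq(3, length(lines), by = 4)]
  qual <- lines[seq(4, length(lines), by = 4)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                 nchar(seq) != nchar(qual))
  if (length(bad) > 0) {
    stop("malformed FASTQ record ", bad[1], " in ", path)
  }
  data.frame(id = sub("\\s.*$", "", substring(hdr, 2)),
             seq = toupper(seq), qual = qual, stringsAsFactors = FALSE)
}

#' Write reads to a 4-line FASTQ file
#'
#' @param reads Data frame with columns `id`, `seq` and optionally `qual`
#'   (defaults to constant 'I').
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qual %||% strrep("I", nchar(reads$seq))
  if (is.null(reads$qual)) qual <- strrep("I", nchar(reads$seq))
  out <- character(4 * nrow(reads))
  out[seq(1, length(out), by = 4)] <- paste0("@", reads$id)
  out[seq(2, length(out), by = 4)] <- reads$seq
  out[seq(3, length(out), by = 4)] <- "+"
  out[seq(4, length(out), by = 4)] <- qual
  writeLines(out, path)
  invisible(path)
}

# Write a data frame as a TSV with a single '#'-prefixed provenance header.
write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}
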