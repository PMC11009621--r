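## Read trimming, alignment to the consensus library (internal seed-and-
## extend aligner or ingested SAM), and pileup accumulation with separate
## tracking of unambiguous and ambiguous coverage.

#' Trim reads to a fixed length
#'
#' Reads longer than `target_len` are cut to their first `target_len`
#' bases; shorter reads are discarded (filter-or-trim semantics).
#'
#' @param reads Read data frame (`id`, `seq`, `qual`) or FASTQ path.
#' @param target_len Target read length (bp).
#' @return Trimmed read data frame.
#' @export
trim_reads <- function(reads, target_len) {
  stopifnot(target_len > 0)
  if (is.character(reads)) reads <- read_fastq(reads)
  keep <- nchar(reads$seq) >= target_len
  out <- reads[keep, , drop = FALSE]
  out$seq <- substr(out$seq, 1, target_len)
  if (!is.null(out$qual)) out$qual <- substr(out$qual, 1, target_len)
  rownames(out) <- NULL
  out
}

#' Align reads to the consensus library
#'
#' Each read is assigned its best-scoring ungapped semi-global placement
#' over all TE families, normalization genes and both strands (exact k-mer
#' seeding, match +1 / mismatch -1). Placements below `min_identity` are
#' dropped. Reads whose best score ties across two or more reference
#' sequences are emitted once per tied reference with `is_ambiguous` set;
#' their pileup weight is 1/k for k tied references.
#'
#' @param reads Read data frame (`id`, `seq`) or FASTQ path.
#' @param library A `te_library`.
#' @param min_identity Minimum identity of the best placement; default 0.75.
#' @param k Seed k-mer length; default 12.
#' @return Alignment data frame: `read_id`, `family_id`, `start` (0-based
#'   on the consensus), `strand`, `mismatches`, `aligned_len`,
#'   `is_ambiguous`, `weight`, `seq` (read oriented to consensus strand).
#'   Attribute `n_reads_in` records the input read count.
#' @export
align_reads <- function(reads, library, min_identity = 0.75, k = 12) {
  stopifnot(min_identity > 0, min_identity <= 1)
  if (is.character(reads)) reads <- read_fastq(reads)
  refs <- library_seqs(library)
  aln <- .cpp_align_reads(reads$seq, names(refs), unname(refs),
                          as.integer(k), min_identity)
  aln$read_id <- reads$id[aln$read]
  aln$read <- NULL
  tied <- table(aln$read_id)
  aln$weight <- ifelse(aln$is_ambiguous,
                       1 / as.integer(tied[aln$read_id]), 1)
  aln <- aln[, c("read_id", "family_id", "start", "strand", "mismatches",
                 "aligned_len", "is_ambiguous", "weight", "seq")]
  attr(aln, "n_reads_in") <- nrow(reads)
  aln
}

# CIGAR helpers for SAM ingest/emit
cigar_aligned_len <- function(cigar) {
  ops <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]$", "", toks))
  op <- sub("^[0-9]+", "", toks)
  sum(n[op %in% c("M", "=", "X")])
}

#' Ingest alignments from a SAM file
#'
#' Converts mapped records to the internal alignment table. Secondary
#' records whose alignment score equals the primary's mark the read
#' ambiguous (one record per tied family). Unmapped records are skipped.
#'
#' @param sam Path to a SAM file.
#' @param library A `te_library`; SAM references must be a subset of its
#'   family and gene ids.
#' @return Alignment data frame as from [align_reads()].
#' @export
ingest_sam <- function(sam, library) {
  refs <- library_seqs(library)
  lines <- readLines(sam)
  body <- lines[!startsWith(lines, "@")]
  sq <- lines[startsWith(lines, "@SQ")]
  sq_names <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  bad <- setdiff(sq_names, names(refs))
  if (length(bad) > 0) {
    stop("SAM reference(s) not in library: ", paste(bad, collapse = ", "))
  }
  rows <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t")[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0) next  # unmapped
    rname <- f[3]
    if (!rname %in% names(refs)) {
      stop("SAM reference not in library: ", rname)
    }
    tags <- f[-(1:11)]
    gettag <- function(tg) {
      hit <- tags[startsWith(tags, paste0(tg, ":"))]
      if (length(hit) == 0) NA else sub("^..:.:", "", hit[1])
    }
    alen <- cigar_aligned_len(f[6])
    nm <- suppressWarnings(as.integer(gettag("NM")))
    if (is.na(nm)) nm <- 0L
    as_ <- suppressWarnings(as.integer(gettag("AS")))
    if (is.na(as_)) as_ <- alen - 2L * nm
    rows[[length(rows) + 1]] <- data.frame(
      read_id = f[1], family_id = rname, start = as.integer(f[4]) - 1L,
      strand = if (bitwAnd(flag, 16L) > 0) "-" else "+",
      mismatches = nm, aligned_len = alen,
      secondary = bitwAnd(flag, 256L) > 0, score = as_,
      seq = if (f[10] == "*") NA_character_ else toupper(f[10]),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    aln <- data.frame(read_id = character(), family_id = character(),
                      start = integer(), strand = character(),
                      mismatches = integer(), aligned_len = integer(),
                      is_ambiguous = logical(), weight = numeric(),
                      seq = character(), stringsAsFactors = FALSE)
    attr(aln, "n_reads_in") <- 0L
    return(aln)
  }
  aln <- do.call(rbind, rows)
  # a read is ambiguous when records tied at its best score span >1 family
  keep <- logical(nrow(aln))
  amb <- logical(nrow(aln))
  for (id in unique(aln$read_id)) {
    i <- which(aln$read_id == id)
    best <- max(aln$score[i])
    ib <- i[aln$score[i] == best]
    fams <- unique(aln$family_id[ib])
    first <- ib[!duplicated(aln$family_id[ib])]
    keep[first] <- TRUE
    amb[first] <- length(fams) > 1
  }
  aln <- aln[keep, , drop = FALSE]
  aln$is_ambiguous <- amb[keep]
  tied <- table(aln$read_id)
  aln$weight <- ifelse(aln$is_ambiguous,
                       1 / as.integer(tied[aln$read_id]), 1)
  aln$secondary <- NULL
  aln$score <- NULL
  aln <- aln[, c("read_id", "family_id", "start", "strand", "mismatches",
                 "aligned_len", "is_ambiguous", "weight", "seq")]
  rownames(aln) <- NULL
  attr(aln, "n_reads_in") <- length(unique(aln$read_id))
  aln
}

#' Write an alignment table as SAM
#'
#' @param alignments Alignment data frame from [align_reads()].
#' @param library A `te_library` (for `@SQ` header lines).
#' @param path Output path.
#' @export
write_sam <- function(alignments, library, path) {
  refs <- library_seqs(library)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(refs), nchar(refs)), con)
  secondary <- duplicated(alignments$read_id)
  flag <- ifelse(alignments$strand == "-", 16L, 0L) +
    ifelse(secondary, 256L, 0L)
  score <- alignments$aligned_len - 2L * alignments$mismatches
  writeLines(paste(alignments$read_id, flag, alignments$family_id,
                   alignments$start + 1L, 60,
                   paste0(alignments$aligned_len, "M"), "*", 0, 0,
                   alignments$seq, "*",
                   paste0("NM:i:", alignments$mismatches),
                   paste0("AS:i:", score), sep = "\t"), con)
  invisible(path)
}

#' Accumulate per-family pileups from alignments
#'
#' Unambiguous alignments contribute to `cov_u` and the per-base counts;
#' ambiguous alignments contribute only to `cov_a`, at weight 1/k for k
#' tied families.
#'
#' @param alignments Alignment data frame from [align_reads()] or
#'   [ingest_sam()].
#' @param library A `te_library`.
#' @return A `pileup_matrix`: per reference sequence a list with matrix
#'   `counts` (columns cov_u, cov_a, A, C, G, T, ins, del), per-read
#'   `divergence` and `weight` vectors; plus `total_mapped_reads`.
#' @export
build_pileup <- function(alignments, library) {
  refs <- library_seqs(library)
  fams <- lapply(names(refs), function(id) {
    sub <- alignments[alignments$family_id == id & !is.na(alignments$seq), ,
                      drop = FALSE]
    len <- nchar(refs[[id]])
    m <- .cpp_pileup(len, as.integer(sub$start), sub$seq,
                     sub$is_ambiguous, sub$weight)
    counts <- cbind(m, ins = 0, del = 0)
    colnames(counts) <- c("cov_u", "cov_a", "A", "C", "G", "T",
                          "ins", "del")
    sub_all <- alignments[alignments$family_id == id, , drop = FALSE]
    list(counts = counts,
         divergence = sub_all$mismatches / sub_all$aligned_len,
         weight = sub_all$weight)
  })
  names(fams) <- names(refs)
  structure(list(families = fams,
                 total_mapped_reads = length(unique(alignments$read_id))),
            class = "pileup_matrix")
}

#' @export
print.pileup_matrix <- function(x, ...) {
  cat("pileup_matrix:", length(x$families), "reference sequences,",
      x$total_mapped_reads, "mapped reads\n")
  invisible(x)
}

#' Dump a pileup as a long table
#'
#' @param pileup A `pileup_matrix`.
#' @return Data frame (family, pos, cov_u, cov_a, A, C, G, T, ins, del)
#'   with 0-based positions.
#' @export
pileup_table <- function(pileup) {
  do.call(rbind, lapply(names(pileup$families), function(id) {
    m <- pileup$families[[id]]$counts
    data.frame(family = id, pos = seq_len(nrow(m)) - 1L, m,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}
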