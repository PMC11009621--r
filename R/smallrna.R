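## Small-RNA preprocessing (adapter removal, 18-36 nt filter), mapping to
## the consensus library, and ping-pong signature computation.

#' Remove the sequencing adapter and length-filter small-RNA reads
#'
#' For each read, everything from the first prefix-match of the adapter
#' (minimum overlap 3 nt, at most 1 mismatch per 10 bases of overlap)
#' onward is removed; reads are then filtered to 18-36 nt inclusive.
#'
#' @param reads Read data frame (`id`, `seq`, `qual`) or FASTQ path.
#' @param adapter Adapter sequence; default TGGAATTCTCGGGTGCCAAGG.
#' @param min_len,max_len Retained length range; defaults 18 and 36.
#' @return Trimmed, filtered read data frame.
#' @export
preprocess_smallrna <- function(reads, adapter = "TGGAATTCTCGGGTGCCAAGG",
                                min_len = 18, max_len = 36) {
  stopifnot(nchar(adapter) > 0)
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  ad <- strsplit(adapter, "")[[1]]
  trim_at <- function(seq) {
    chars <- strsplit(seq, "")[[1]]
    L <- length(chars)
    for (i in seq_len(L)) {
      ov <- min(length(ad), L - i + 1)
      if (ov < 3) break
      mm <- sum(chars[i:(i + ov - 1)] != ad[1:ov])
      if (mm <= ov %/% 10) return(i - 1L)
    }
    L
  }
  newlen <- vapply(reads$seq, trim_at, 0L, USE.NAMES = FALSE)
  out <- reads
  out$seq <- substr(out$seq, 1, newlen)
  if (!is.null(out$qual)) out$qual <- substr(out$qual, 1, newlen)
  keep <- nchar(out$seq) >= min_len & nchar(out$seq) <= max_len
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map small-RNA reads and count stranded 5' ends per family
#'
#' Reads are assigned to their best-matching reference and strand with the
#' internal aligner (default minimum identity 0.9); multi-mapping reads
#' count 1/k per tied family. For a sense read the 5' end is the alignment
#' start; for an antisense read it is the alignment end - 1 (both in
#' 0-based consensus coordinates).
#'
#' @param reads Preprocessed read data frame or FASTQ path.
#' @param library A `te_library` (decoy sequences may be included as extra
#'   "genes"; reads assigned to them are counted but not profiled).
#' @param min_identity Minimum alignment identity; default 0.9.
#' @param k Seed length; default 12.
#' @return Named list (per family) with numeric vectors `sense` and
#'   `antisense` of weighted 5'-end counts per consensus position, plus a
#'   `lengths` histogram of mapped read lengths.
#' @export
map_smallrna <- function(reads, library, min_identity = 0.9, k = 12) {
  aln <- align_reads(reads, library, min_identity = min_identity, k = k)
  fams <- names(library$families)
  out <- lapply(fams, function(id) {
    len <- library$families[[id]]$length
    sub <- aln[aln$family_id == id, , drop = FALSE]
    sense <- numeric(len)
    antisense <- numeric(len)
    plus <- sub$strand == "+"
    if (any(plus)) {
      t5 <- tapply(sub$weight[plus], sub$start[plus], sum)
      sense[as.integer(names(t5)) + 1] <- t5
    }
    if (any(!plus)) {
      p5 <- sub$start[!plus] + sub$aligned_len[!plus] - 1
      t5 <- tapply(sub$weight[!plus], p5, sum)
      antisense[as.integer(names(t5)) + 1] <- t5
    }
    list(sense = sense, antisense = antisense,
         lengths = table(factor(sub$aligned_len, levels = 18:36)))
  })
  names(out) <- fams
  out
}

#' Ping-pong signature from stranded 5'-end counts
#'
#' The overlap histogram is o(k) = sum over positions p of
#' sense5(p) * antisense5(p + k - 1) for k = 1..23, where k is the number
#' of nucleotides shared by the two 5' ends; the canonical ping-pong peak
#' sits at k = 10. z10 is the z-score of o(10) against the other overlap
#' sizes.
#'
#' @param counts One element of [map_smallrna()]'s result (list with
#'   `sense` and `antisense`), or a list with those two vectors.
#' @param k_max Largest overlap size considered; default 23 (the minimum
#'   piRNA length bounds the observable overlap).
#' @return List of class `pingpong_profile`: `overlap` (named numeric,
#'   k = 1..k_max), `z10`, `single_strand` flag.
#' @export
pingpong_signature <- function(counts, k_max = 23) {
  s <- counts$sense
  a <- counts$antisense
  single <- sum(s) == 0 || sum(a) == 0
  L <- length(s)
  o <- vapply(seq_len(k_max), function(k) {
    if (k > L) return(0)
    idx <- seq_len(L - k + 1)
    sum(s[idx] * a[idx + k - 1])
  }, 0)
  names(o) <- seq_len(k_max)
  bg <- o[-10]
  z10 <- if (single || sum(bg > 0) < 2 || sd(bg) == 0) NA_real_ else
    (o[10] - mean(bg)) / sd(bg)
  structure(list(overlap = o, z10 = unname(z10), single_strand = single),
            class = "pingpong_profile")
}

#' @export
print.pingpong_profile <- function(x, ...) {
  cat("ping-pong profile: argmax overlap =",
      as.integer(names(which.max(x$overlap))), "nt, z10 =",
      format(x$z10, digits = 3), "\n")
  invisible(x)
}
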