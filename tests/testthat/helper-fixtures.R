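# Shared fixtures, built in code. The synthetic library mimics the real
# consensus database in miniature: a few TE families (one carrying a
# poly-A tract) plus equal-length single-copy normalization genes, so
# read-edge effects cancel in the coverage ratio.

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_library <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(20240601)
      tes <- c(
        blood_syn = rand_dna(1500),
        opus_syn = paste0(rand_dna(1480), strrep("A", 20)),
        te412_syn = rand_dna(1800))
      genes <- c(rhi_syn = rand_dna(1500), tj_syn = rand_dna(1500),
                 rpl32_syn = rand_dna(1500))
      cache <<- build_library(tes, genes,
                              ltr_lengths = c(blood_syn = 200))
    }
    cache
  }
})

# One synthetic sample: genome with given copy numbers -> reads -> pileup
make_sample <- function(lib, copy_numbers, seed, coverage = 20,
                        read_len = 100, error_rate = 0.01,
                        lineage_snps = list(), degraded = list(),
                        backbone = 30000) {
  fams <- lapply(names(copy_numbers), function(id) {
    list(copy_number = copy_numbers[[id]],
         lineage_snps = lineage_snps[[id]],
         degraded = degraded[[id]])
  })
  names(fams) <- names(copy_numbers)
  spec <- genome_spec(backbone, fams, seed = seed)
  g <- build_genome(spec, lib)
  reads <- simulate_reads(g$genome, coverage = coverage,
                          read_len = read_len, error_rate = error_rate,
                          seed = seed + 1000)
  aln <- align_reads(reads, lib)
  list(truth = g$truth, genome = g$genome, reads = reads,
       alignments = aln, pileup = build_pileup(aln, lib))
}

# Brute-force semi-global aligner: every offset, both strands, all refs.
# Mirrors the contract of align_reads() independently of its seeding.
oracle_align <- function(reads, lib, min_identity = 0.75) {
  refs <- c(vapply(lib$families, `[[`, "", "sequence"), lib$genes)
  ref_bytes <- lapply(refs, function(s) charToRaw(s))
  rows <- list()
  for (i in seq_len(nrow(reads))) {
    fwd <- reads$seq[i]
    L <- nchar(fwd)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(fwd)))
    best_mm <- L + 1L
    best <- list()
    for (strand in c("+", "-")) {
      rb <- charToRaw(if (strand == "+") fwd else rc)
      for (r in seq_along(refs)) {
        RB <- ref_bytes[[r]]
        if (length(RB) < L) next
        for (off in 0:(length(RB) - L)) {
          mm <- sum(RB[(off + 1):(off + L)] != rb)
          if (mm < best_mm) { best_mm <- mm; best <- list() }
          if (mm == best_mm) {
            best[[length(best) + 1]] <- list(ref = names(refs)[r],
                                             strand = strand, off = off)
          }
        }
      }
    }
    if (length(best) == 0 || 1 - best_mm / L < min_identity) next
    fams <- unique(vapply(best, `[[`, "", "ref"))
    for (f in fams) {
      cand <- Filter(function(b) b$ref == f, best)
      ord <- order(vapply(cand, function(b) b$strand, ""),
                   vapply(cand, function(b) b$off, 0))
      b <- cand[[ord[1]]]
      rows[[length(rows) + 1]] <- data.frame(
        read_id = reads$id[i], family_id = f, start = b$off,
        strand = b$strand, mismatches = best_mm, aligned_len = L,
        is_ambiguous = length(fams) > 1, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Exhaustive-offset alignment oracle, vectorized over reads: computes the
# mismatch count of every (reference, strand, offset) placement for every
# read, then applies the same best-placement/tie rules as the aligner.
# All reads must share one length.
oracle_align_matrix <- function(reads, lib, min_identity = 0.75) {
  refs <- c(vapply(lib$families, `[[`, "", "sequence"), lib$genes)
  L <- unique(nchar(reads$seq))
  stopifnot(length(L) == 1)
  n <- nrow(reads)
  fwd <- matrix(unlist(lapply(reads$seq, charToRaw)), nrow = L)
  rcs <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads$seq)))
  rcm <- matrix(unlist(lapply(rcs, charToRaw)), nrow = L)
  meta <- list()
  mats <- list()
  for (r in names(refs)) {
    RB <- charToRaw(refs[[r]])
    noff <- length(RB) - L + 1
    if (noff < 1) next
    for (strand in c("+", "-")) {
      rm_ <- if (strand == "+") fwd else rcm
      mm <- matrix(0L, noff, n)
      for (o in seq_len(noff)) {
        mm[o, ] <- colSums(rm_ != RB[o:(o + L - 1)])
      }
      mats[[length(mats) + 1]] <- mm
      meta[[length(meta) + 1]] <- data.frame(
        ref = r, strand = strand, offset = seq_len(noff) - 1L,
        stringsAsFactors = FALSE)
    }
  }
  big <- do.call(rbind, mats)
  meta <- do.call(rbind, meta)
  strand_rank <- ifelse(meta$strand == "+", 0L, 1L)
  rows <- list()
  for (j in seq_len(n)) {
    bm <- min(big[, j])
    if (1 - bm / L < min_identity) next
    cand <- which(big[, j] == bm)
    fams <- unique(meta$ref[cand])
    for (f in fams) {
      cf <- cand[meta$ref[cand] == f]
      cf <- cf[order(strand_rank[cf], meta$offset[cf])][1]
      rows[[length(rows) + 1]] <- data.frame(
        read_id = reads$id[j], family_id = f, start = meta$offset[cf],
        strand = meta$strand[cf], mismatches = bm, aligned_len = L,
        is_ambiguous = length(fams) > 1, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# a pileup with flat unambiguous coverage on every reference
flat_pileup <- function(lib, te_cov, gene_cov) {
  fams <- lapply(names(lib$families), function(id) {
    len <- lib$families[[id]]$length
    counts <- cbind(cov_u = rep(te_cov[[id]], len), cov_a = 0,
                    A = 0, C = 0, G = 0, T = rep(te_cov[[id]], len),
                    ins = 0, del = 0)
    list(counts = counts, divergence = numeric(0), weight = numeric(0))
  })
  names(fams) <- names(lib$families)
  for (g in names(lib$genes)) {
    len <- nchar(lib$genes[[g]])
    counts <- cbind(cov_u = rep(gene_cov[[g]], len), cov_a = 0,
                    A = 0, C = 0, G = 0, T = rep(gene_cov[[g]], len),
                    ins = 0, del = 0)
    fams[[g]] <- list(counts = counts, divergence = numeric(0),
                      weight = numeric(0))
  }
  structure(list(families = fams, total_mapped_reads = 0),
            class = "pileup_matrix")
}

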