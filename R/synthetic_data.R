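## Synthetic data with known ground truth: genomes carrying planted TE
## copies, short-read samples, ping-pong-structured small-RNA sets, and
## divergence-ladder donor-assembly panels.

#' Specify a synthetic genome
#'
#' Describes one haploid genome: a random backbone hosting, per TE family,
#' a number of near-consensus copies (each drawing lineage SNPs
#' independently at their lineage frequency) and optionally old degraded
#' fragments at high divergence, plus exactly one copy of each
#' normalization gene.
#'
#' @param backbone_length Backbone length in bp.
#' @param families Named list (by family id). Each element is a list with
#'   `copy_number` (integer >= 0), optional `lineage_snps` (data frame with
#'   0-based `pos`, `alt` base and lineage `freq` in (0,1]), optional
#'   `copy_divergence` (per-copy random substitution rate; default 0.005,
#'   i.e. the <1% divergence expected of recently active copies) and
#'   optional `degraded` (list with `count`, `divergence`, `len_range`).
#' @param seed Integer seed; the whole genome build is deterministic in it.
#' @return A `genome_spec` object.
#' @export
genome_spec <- function(backbone_length, families, seed) {
  stopifnot(backbone_length > 0, length(seed) == 1)
  for (id in names(families)) {
    f <- families[[id]]
    stopifnot(f$copy_number >= 0)
    if (!is.null(f$lineage_snps) && nrow(f$lineage_snps) > 0) {
      stopifnot(all(f$lineage_snps$freq > 0), all(f$lineage_snps$freq <= 1))
    }
    if (!is.null(f$degraded)) {
      stopifnot(f$degraded$divergence >= 0, f$degraded$divergence < 1)
    }
  }
  structure(list(backbone_length = backbone_length, families = families,
                 seed = seed), class = "genome_spec")
}

# One TE copy: consensus + independent lineage-SNP draws + background
# substitutions (which never touch SNP positions, so the truth table agrees
# with the emitted sequence exactly).
make_te_copy <- function(consensus, snps, divergence) {
  chars <- strsplit(consensus, "")[[1]]
  carried <- logical(if (is.null(snps)) 0 else nrow(snps))
  if (length(carried) > 0) {
    carried <- runif(nrow(snps)) < snps$freq
    chars[snps$pos[carried] + 1] <- snps$alt[carried]
  }
  if (divergence > 0) {
    protect <- if (is.null(snps)) integer(0) else snps$pos + 1
    hit <- setdiff(which(runif(length(chars)) < divergence), protect)
    for (i in hit) chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1)
  }
  list(seq = paste(chars, collapse = ""), carried = carried)
}

#' Build a synthetic genome and its truth table
#'
#' @param spec A [genome_spec()].
#' @param library A `te_library` supplying consensus and gene sequences.
#' @return List with `genome` (named character vector, one contig) and
#'   `truth` (list with `copy_number`, `snp_freq` data frame of realized
#'   per-site frequencies, and `insertions` with final coordinates and
#'   identity to consensus).
#' @export
build_genome <- function(spec, library) {
  with_seed(spec$seed, {
    units <- list()
    for (id in names(spec$families)) {
      f <- spec$families[[id]]
      if (!id %in% names(library$families)) {
        stop("family not in library: ", id)
      }
      cons <- library$families[[id]]$sequence
      div <- f$copy_divergence %||% 0.005
      cn <- f$copy_number
      if (cn > 0) {
        for (i in seq_len(cn)) {
          cp <- make_te_copy(cons, f$lineage_snps, div)
          units[[length(units) + 1]] <- list(
            family = id, kind = "full", seq = cp$seq, carried = cp$carried)
        }
      }
      dg <- f$degraded
      if (!is.null(dg) && dg$count > 0) {
        for (i in seq_len(dg$count)) {
          len <- sample(dg$len_range[1]:dg$len_range[2], 1)
          st <- sample(nchar(cons) - len + 1, 1)
          frag <- mutate_seq(substr(cons, st, st + len - 1), dg$divergence)
          units[[length(units) + 1]] <- list(
            family = id, kind = "degraded", seq = frag, carried = logical(0))
        }
      }
    }
    for (g in names(library$genes)) {
      units[[length(units) + 1]] <- list(
        family = g, kind = "gene", seq = library$genes[[g]],
        carried = logical(0))
    }
    if (length(units) > spec$backbone_length + 1) {
      stop("cannot place ", length(units), " insertions without overlap; ",
           "use a larger backbone")
    }
    backbone <- random_dna(spec$backbone_length)
    offsets <- sort(sample(0:spec$backbone_length, length(units)))
    ord <- sample(length(units))  # random order along the backbone
    units <- units[ord]

    pieces <- character(2 * length(units) + 1)
    ins <- data.frame(family = character(), kind = character(),
                      start = integer(), end = integer(),
                      identity = numeric(), stringsAsFactors = FALSE)
    pos <- 0L  # running genome coordinate (0-based)
    prev <- 0L
    for (i in seq_along(units)) {
      seg <- substr(backbone, prev + 1, offsets[i])
      pieces[2 * i - 1] <- seg
      pos <- pos + nchar(seg)
      u <- units[[i]]
      pieces[2 * i] <- u$seq
      ident <- if (u$kind == "gene") 1 else {
        cons <- library$families[[u$family]]$sequence
        ref <- if (u$kind == "full") cons else NA
        if (u$kind == "full") 1 - hamming(u$seq, cons) / nchar(cons) else NA
      }
      ins <- rbind(ins, data.frame(
        family = u$family, kind = u$kind, start = pos,
        end = pos + nchar(u$seq), identity = ident,
        stringsAsFactors = FALSE))
      pos <- pos + nchar(u$seq)
      prev <- offsets[i]
    }
    pieces[2 * length(units) + 1] <- substr(backbone, prev + 1,
                                            spec$backbone_length)
    genome <- c(chr_syn = paste(pieces, collapse = ""))

    # realized per-site lineage-SNP frequencies over the planted copies
    snp_rows <- list()
    for (id in names(spec$families)) {
      f <- spec$families[[id]]
      if (is.null(f$lineage_snps) || f$copy_number == 0) next
      carried <- vapply(units[vapply(units, function(u)
        u$family == id && u$kind == "full", TRUE)],
        function(u) u$carried, logical(nrow(f$lineage_snps)))
      carried <- matrix(carried, nrow = nrow(f$lineage_snps))
      snp_rows[[id]] <- data.frame(
        family = id, pos = f$lineage_snps$pos, alt = f$lineage_snps$alt,
        lineage_freq = f$lineage_snps$freq,
        carriers = rowSums(carried), copies = f$copy_number,
        freq = rowSums(carried) / f$copy_number, stringsAsFactors = FALSE)
    }
    truth <- list(
      copy_number = vapply(names(spec$families), function(id)
        spec$families[[id]]$copy_number, 0),
      snp_freq = if (length(snp_rows) > 0) do.call(rbind, c(snp_rows,
        make.row.names = FALSE)) else NULL,
      insertions = ins)
    list(genome = genome, truth = truth)
  })
}

#' Simulate single-end short reads from a genome
#'
#' Uniform random start positions on either strand, constant read length,
#' per-base substitution errors, constant base quality.
#'
#' @param genome Named character vector of contig sequences.
#' @param coverage Target mean depth.
#' @param read_len Read length in bp.
#' @param error_rate Per-base substitution error rate.
#' @param seed Integer seed.
#' @return Data frame of reads (`id`, `seq`, `qual`) suitable for
#'   [write_fastq()].
#' @export
simulate_reads <- function(genome, coverage, read_len, error_rate, seed) {
  stopifnot(coverage > 0, all(nchar(genome) >= read_len))
  with_seed(seed, {
    glen <- sum(nchar(genome))
    n <- round(coverage * glen / read_len)
    contig <- sample(seq_along(genome), n, replace = TRUE,
                     prob = nchar(genome))
    starts <- floor(runif(n) * (nchar(genome)[contig] - read_len + 1)) + 1
    seqs <- substring(genome[contig], starts, starts + read_len - 1)
    minus <- runif(n) < 0.5
    if (any(minus)) {
      seqs[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[minus])))
    }
    if (error_rate > 0) {
      nerr <- rbinom(n, read_len, error_rate)
      for (i in which(nerr > 0)) {
        chars <- strsplit(seqs[i], "")[[1]]
        at <- sample(read_len, nerr[i])
        for (p in at) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
        seqs[i] <- paste(chars, collapse = "")
      }
    }
    out <- data.frame(id = sprintf("r%06d", seq_len(n)), seq = seqs,
                      qual = strrep("I", read_len),
                      stringsAsFactors = FALSE)
    # ground-truth sampling positions, for depth-recount oracles
    attr(out, "positions") <- data.frame(
      contig = names(genome)[contig], start = starts - 1L,
      strand = ifelse(minus, "-", "+"), stringsAsFactors = FALSE)
    out
  })
}

#' Simulate a small-RNA read set with a planted ping-pong signature
#'
#' Generates 23-29 nt piRNA-like inserts from both strands of a TE
#' consensus. A fraction of the read pairs are sense/antisense partners
#' whose 5' ends overlap by exactly 10 nt (the ping-pong configuration);
#' the remainder are independent. The sequencing adapter is appended to
#' every read.
#'
#' @param family A `te_consensus` (or single consensus string).
#' @param n_pairs Number of read pairs (total reads = 2 * n_pairs).
#' @param pingpong_fraction Fraction of pairs in ping-pong configuration.
#' @param adapter Adapter appended 3' of each insert; default is the small
#'   RNA kit adapter TGGAATTCTCGGGTGCCAAGG.
#' @param seed Integer seed.
#' @return Data frame of reads (`id`, `seq`, `qual`).
#' @export
simulate_smallrna <- function(family, n_pairs, pingpong_fraction,
                              adapter = "TGGAATTCTCGGGTGCCAAGG", seed) {
  stopifnot(pingpong_fraction >= 0, pingpong_fraction <= 1)
  cons <- if (inherits(family, "te_consensus")) family$sequence else family
  L <- nchar(cons)
  with_seed(seed, {
    n_pp <- round(pingpong_fraction * n_pairs)
    seqs <- character(0)
    for (i in seq_len(n_pp)) {
      l1 <- sample(23:29, 1)
      l2 <- sample(23:29, 1)
      # sense 5' at p, antisense 5' at p+9: 10 nt 5'-overlap
      pmin_ <- max(1, l2 - 9)
      pmax_ <- L - l1 + 1
      p <- sample(pmin_:pmax_, 1)
      q <- p + 9
      seqs <- c(seqs, substr(cons, p, p + l1 - 1),
                revcomp(substr(cons, q - l2 + 1, q)))
    }
    for (i in seq_len(n_pairs - n_pp)) {
      for (j in 1:2) {
        l <- sample(23:29, 1)
        p <- sample(L - l + 1, 1)
        s <- substr(cons, p, p + l - 1)
        if (runif(1) < 0.5) s <- revcomp(s)
        seqs <- c(seqs, s)
      }
    }
    seqs <- paste0(seqs, adapter)
    data.frame(id = sprintf("s%06d", seq_along(seqs)), seq = seqs,
               qual = strrep("I", nchar(seqs)), stringsAsFactors = FALSE)
  })
}

#' Build a divergence-ladder panel of candidate donor assemblies
#'
#' One assembly per ladder value, each carrying one insertion of every
#' library family mutated to that divergence; the 0-divergence assembly is
#' the designated donor.
#'
#' @param library A `te_library`.
#' @param divergence_ladder Numeric vector of divergences in `[0, 1)`.
#' @param seed Integer seed.
#' @param spacer Backbone length between insertions (bp).
#' @return List with `assemblies` (named list of named contig vectors) and
#'   `truth` (data frame: assembly, divergence, is_donor).
#' @export
build_species_panel <- function(library, divergence_ladder, seed,
                                spacer = 2000) {
  stopifnot(all(divergence_ladder >= 0), all(divergence_ladder < 1))
  with_seed(seed, {
    asm <- list()
    for (i in seq_along(divergence_ladder)) {
      d <- divergence_ladder[i]
      pieces <- random_dna(spacer)
      for (id in names(library$families)) {
        copy <- library$families[[id]]$sequence
        if (d > 0) copy <- mutate_seq(copy, d)
        pieces <- c(pieces, copy, random_dna(spacer))
      }
      name <- sprintf("asm_%02d", i)
      asm[[name]] <- setNames(paste(pieces, collapse = ""),
                              paste0(name, "_ctg1"))
    }
    truth <- data.frame(assembly = names(asm),
                        divergence = divergence_ladder,
                        is_donor = divergence_ladder ==
                          min(divergence_ladder),
                        stringsAsFactors = FALSE)
    list(assemblies = asm, truth = truth)
  })
}
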