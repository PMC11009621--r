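## Horizontal-transfer donor scoring: repeat-hit discovery (internal local
## aligner or ingested repeat-annotation tables), defragmentation, the
## similarity statistic s = max(score_i)/max(score_all), length-divergence
## summaries, full-length extraction, and LTR-divergence insertion dating.

hit_columns <- c("assembly_id", "contig", "start", "end", "strand",
                 "family_id", "score", "divergence", "qstart", "qend")

empty_hits <- function() {
  data.frame(assembly_id = character(), contig = character(),
             start = integer(), end = integer(), strand = character(),
             family_id = character(), score = numeric(),
             divergence = numeric(), qstart = integer(), qend = integer(),
             stringsAsFactors = FALSE)
}

#' Parse a repeat-annotation table (.out dialect)
#'
#' Reads the standard 15-column repeat annotation layout (3 header lines).
#' Coordinates are converted to 0-based half-open, percent divergence to a
#' fraction, and "C" orientation to "-"; for "C" rows the
#' position-in-repeat columns are given as (left), end, begin and are
#' swapped accordingly.
#'
#' @param path Path to the table.
#' @param assembly_id Assembly label attached to the hits; defaults to the
#'   file name.
#' @return Data frame of repeat hits.
#' @export
parse_repeat_table <- function(path, assembly_id = NULL) {
  assembly_id <- assembly_id %||% tools::file_path_sans_ext(basename(path))
  lines <- readLines(path)
  body <- lines[-seq_len(min(3, length(lines)))]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) return(empty_hits())
  rows <- lapply(seq_along(body), function(i) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(f) < 14) {
      stop("malformed repeat-table row at line ", i + 3, " of ", path)
    }
    score <- suppressWarnings(as.numeric(f[1]))
    div <- suppressWarnings(as.numeric(f[2]))
    qb <- suppressWarnings(as.integer(f[6]))
    qe <- suppressWarnings(as.integer(f[7]))
    if (anyNA(c(score, div, qb, qe))) {
      stop("malformed repeat-table row at line ", i + 3, " of ", path)
    }
    strand <- if (f[9] %in% c("C", "-")) "-" else "+"
    # position-in-repeat triplet: (begin, end, left) for +, (left, end,
    # begin) for C
    if (strand == "+") {
      rb <- as.integer(f[12]); re <- as.integer(f[13])
    } else {
      rb <- as.integer(f[14]); re <- as.integer(f[13])
    }
    data.frame(assembly_id = assembly_id, contig = f[5],
               start = qb - 1L, end = qe, strand = strand,
               family_id = f[10], score = score, divergence = div / 100,
               qstart = rb - 1L, qend = re, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write repeat hits in the .out table dialect
#'
#' @param hits Repeat-hit data frame.
#' @param path Output path.
#' @export
write_repeat_table <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "   SW   perc perc perc  queryableName      position in query    matching       repeat            position in repeat",
    "score   div. del. ins.  sequence            begin end   (left)   repeat         class/family      begin end    (left)",
    ""), con)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    # position-in-repeat triplet: (begin, end, left) for +, C rows store
    # (left, end, begin)
    trip <- if (h$strand == "+") {
      c(as.character(h$qstart + 1L), as.character(h$qend), "(0)")
    } else {
      c("(0)", as.character(h$qend), as.character(h$qstart + 1L))
    }
    writeLines(sprintf(
      "%6.0f %6.1f  0.0  0.0  %-18s %6d %6d (0) %s %-14s Unknown %6s %6s %6s %d",
      h$score, h$divergence * 100, h$contig, h$start + 1L, h$end,
      if (h$strand == "+") "+" else "C", h$family_id,
      trip[1], trip[2], trip[3], i), con)
  }
  invisible(path)
}

#' Find TE hits on an assembly with the internal local aligner
#'
#' Gapless local alignments of each family consensus against both strands
#' of every contig: exact k-mer seeds (k = 12), x-drop extension (drop
#' 20), match +1 / mismatch -1. Hits below `min_score` are dropped;
#' divergence is mismatches over alignment length.
#'
#' @param assembly Named character vector of contig sequences (or FASTA
#'   path).
#' @param library A `te_library`.
#' @param min_score Minimum alignment score; default 100.
#' @param assembly_id Assembly label; defaults to "assembly".
#' @param k Seed length; default 12.
#' @param xdrop X-drop threshold; default 20.
#' @return Data frame of repeat hits (0-based half-open contig
#'   coordinates; `qstart`/`qend` give the consensus span).
#' @export
find_hits <- function(assembly, library, min_score = 100,
                      assembly_id = "assembly", k = 12, xdrop = 20) {
  if (is.character(assembly) && length(assembly) == 1 &&
      file.exists(assembly)) {
    assembly <- read_fasta(assembly)
  }
  stopifnot(length(assembly) > 0)
  fams <- vapply(library$families, `[[`, "", "sequence")
  out <- lapply(names(assembly), function(ctg) {
    h <- .cpp_find_hits(assembly[[ctg]], names(fams), unname(fams),
                        as.integer(k), as.integer(min_score),
                        as.integer(xdrop))
    if (nrow(h) == 0) return(NULL)
    data.frame(assembly_id = assembly_id, contig = ctg,
               start = h$start, end = h$end, strand = h$strand,
               family_id = h$family_id, score = h$score,
               divergence = h$divergence, qstart = h$qstart,
               qend = h$qend, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty_hits() else out
}

#' Merge fragmented repeat hits
#'
#' Hits on the same contig, family and strand whose genomic gap is at most
#' `max_gap` are merged when their consensus spans are colinear (advance
#' with the genomic order; for "-" strand hits the spans must decrease).
#' Merged score is the sum, merged divergence the length-weighted mean.
#'
#' @param hits Repeat-hit data frame.
#' @param max_gap Maximum genomic gap bridged; default 100 bp.
#' @param colinear Require consensus-span colinearity (default TRUE); when
#'   FALSE merging is by distance only, which can fuse tandem copies.
#' @param overlap_tol Allowed consensus-span overlap between merged
#'   fragments; default 20 bp.
#' @return Merged, sorted repeat-hit data frame.
#' @export
defragment <- function(hits, max_gap = 100, colinear = TRUE,
                       overlap_tol = 20) {
  stopifnot(max_gap >= 0)
  if (nrow(hits) == 0) return(hits)
  grp <- paste(hits$assembly_id, hits$contig, hits$family_id, hits$strand,
               sep = "\r")
  out <- lapply(split(hits, grp), function(h) {
    h <- h[order(h$start), , drop = FALSE]
    merged <- h[1, , drop = FALSE]
    for (i in seq_len(nrow(h))[-1]) {
      cur <- merged[nrow(merged), ]
      nxt <- h[i, ]
      gap_ok <- nxt$start - cur$end <= max_gap
      col_ok <- if (!colinear) TRUE else if (cur$strand == "+") {
        nxt$qstart >= cur$qend - overlap_tol
      } else {
        nxt$qend <= cur$qstart + overlap_tol
      }
      if (gap_ok && col_ok && nxt$start >= cur$start) {
        cur$end <- max(cur$end, nxt$end)
        lens <- c(cur$qend - cur$qstart, nxt$qend - nxt$qstart)
        cur$divergence <- sum(c(cur$divergence, nxt$divergence) * lens) /
          sum(lens)
        cur$score <- cur$score + nxt$score
        cur$qstart <- min(cur$qstart, nxt$qstart)
        cur$qend <- max(cur$qend, nxt$qend)
        merged[nrow(merged), ] <- cur
      } else {
        merged <- rbind(merged, nxt)
      }
    }
    merged
  })
  out <- do.call(rbind, out)
  out <- out[order(out$assembly_id, out$contig, out$family_id, out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Similarity of each assembly's best hit to the consensus
#'
#' Per family, s_i = (highest hit score in assembly i) / (highest hit
#' score in any assembly); assemblies without a hit score 0. Families with
#' no hit anywhere are reported NA and flagged.
#'
#' @param hits_by_assembly Named list (by assembly id) of repeat-hit data
#'   frames, or one combined data frame with `assembly_id`.
#' @param families Optional character vector of all family ids under
#'   consideration; families without a hit in any assembly are then
#'   reported as `no_hit_families` (their s is undefined, not 0/0).
#' @return List with `table` (data frame: assembly_id, family_id, s),
#'   `best_assembly` (named character, per family argmax) and
#'   `no_hit_families`.
#' @export
similarity_scores <- function(hits_by_assembly, families = NULL) {
  if (is.data.frame(hits_by_assembly)) {
    assemblies <- unique(hits_by_assembly$assembly_id)
    hits <- hits_by_assembly
  } else {
    stopifnot(length(hits_by_assembly) >= 1)
    assemblies <- names(hits_by_assembly)
    hits <- do.call(rbind, hits_by_assembly)
  }
  fams <- unique(hits$family_id)
  no_hit <- setdiff(families %||% fams, fams)
  tab <- expand.grid(assembly_id = assemblies, family_id = fams,
                     stringsAsFactors = FALSE)
  tab$s <- mapply(function(a, f) {
    sub <- hits[hits$assembly_id == a & hits$family_id == f, ]
    if (nrow(sub) == 0) 0 else max(sub$score)
  }, tab$assembly_id, tab$family_id)
  best <- character(0)
  for (f in fams) {
    i <- tab$family_id == f
    mx <- max(tab$s[i])
    tab$s[i] <- tab$s[i] / mx
    best[f] <- tab$assembly_id[i][which.max(tab$s[i])]
  }
  if (length(no_hit) > 0) {
    tab <- rbind(tab, expand.grid(assembly_id = assemblies,
                                  family_id = no_hit, s = NA_real_,
                                  stringsAsFactors = FALSE))
  }
  list(table = tab, best_assembly = best, no_hit_families = no_hit)
}

#' Length-divergence table of repeat hits
#'
#' @param hits (Defragmented) repeat-hit data frame.
#' @return Data frame: family_id, length, divergence — one row per hit,
#'   ready for hex-bin plotting.
#' @export
length_divergence_table <- function(hits) {
  if (nrow(hits) == 0) {
    return(data.frame(family_id = character(), length = integer(),
                      divergence = numeric(), stringsAsFactors = FALSE))
  }
  data.frame(family_id = hits$family_id, length = hits$end - hits$start,
             divergence = hits$divergence, stringsAsFactors = FALSE)
}

#' Extract full-length insertions by hit length
#'
#' Sequences of defragmented hits whose genomic length falls in
#' `[lo, hi]`, reverse-complemented to consensus orientation, with ids
#' encoding assembly, contig, coordinates and strand — ready for external
#' multiple alignment.
#'
#' @param hits Repeat-hit data frame.
#' @param assembly Named character vector of contig sequences.
#' @param length_window Numeric `c(lo, hi)`.
#' @return Named character vector of sequences.
#' @export
extract_full_length <- function(hits, assembly, length_window) {
  stopifnot(length_window[1] < length_window[2])
  len <- hits$end - hits$start
  sel <- hits[len >= length_window[1] & len <= length_window[2], ,
              drop = FALSE]
  if (nrow(sel) == 0) return(setNames(character(0), character(0)))
  out <- character(nrow(sel))
  ids <- character(nrow(sel))
  for (i in seq_len(nrow(sel))) {
    h <- sel[i, ]
    ctg <- assembly[[h$contig]]
    if (is.null(ctg) || h$end > nchar(ctg) || h$start < 0) {
      stop("hit coordinates outside contig ", h$contig)
    }
    s <- substr(ctg, h$start + 1, h$end)
    if (h$strand == "-") s <- revcomp(s)
    out[i] <- s
    ids[i] <- sprintf("%s:%s:%d-%d:%s", h$assembly_id, h$contig,
                      h$start, h$end, h$strand)
  }
  setNames(out, ids)
}

#' Date an LTR insertion from the divergence of its two LTRs
#'
#' The two long terminal repeats are identical at insertion time and
#' diverge independently afterwards, so age = d / (2 * rate) where d is
#' the per-site mismatch fraction between the insertion's 5' and 3' LTR
#' copies (gapless comparison).
#'
#' @param insertion_seq Full insertion sequence (LTR ... LTR).
#' @param ltr_length LTR length in bp.
#' @param rate Substitution rate (substitutions per site per year); no
#'   default — it must be stated explicitly.
#' @return List with `d` (LTR-LTR divergence) and `age_years`.
#' @export
ltr_age <- function(insertion_seq, ltr_length, rate) {
  stopifnot(rate > 0)
  L <- nchar(insertion_seq)
  if (2 * ltr_length > L) {
    stop("insertion shorter than two LTRs; LTRs missing or unalignable")
  }
  ltr5 <- substr(insertion_seq, 1, ltr_length)
  ltr3 <- substr(insertion_seq, L - ltr_length + 1, L)
  d <- hamming(ltr5, ltr3) / ltr_length
  list(d = d, age_years = d / (2 * rate))
}
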