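## Copy-number estimation by coverage normalization, SNP calling, rpm
## abundance, invasion-status classification, timeline assembly and
## year-group comparison.

#' Default classification thresholds
#'
#' `c_min`: minimum haploid copies to count as present (0.2); `breadth`:
#' minimum covered fraction of the consensus for a recent call (0.8);
#' `divergence`: maximum mean per-read divergence for a recent call (0.05).
#'
#' @return Named list of thresholds.
#' @export
default_thresholds <- function() {
  list(c_min = 0.2, breadth = 0.8, divergence = 0.05)
}

#' Mean single-copy-gene coverage (normalization factor)
#'
#' Mean per-position unambiguous coverage pooled across all normalization
#' genes; dividing TE coverage by it yields haploid copy number.
#'
#' @param pileup A `pileup_matrix`.
#' @param library A `te_library`.
#' @return Positive scalar.
#' @export
normalization_factor <- function(pileup, library) {
  ids <- names(library$genes)
  cov <- unlist(lapply(ids, function(g)
    pileup$families[[g]]$counts[, "cov_u"]))
  if (all(cov == 0)) {
    stop("no normalization gene has coverage; copy numbers are undefined")
  }
  mean(cov)
}

# Replace coverage inside homopolymer runs by the median coverage of the
# 50 bp flanks on each side (the poly-A curbing of the coverage track).
curb_homopolymers <- function(cov, runs, flank = 50) {
  if (nrow(runs) == 0) return(cov)
  n <- length(cov)
  for (i in seq_len(nrow(runs))) {
    s <- runs[i, "start"]; e <- runs[i, "end"]  # 0-based half-open
    left <- max(1, s - flank + 1):max(1, s)
    right <- min(n, e + 1):min(n, e + flank)
    if (s == 0) left <- integer(0)
    if (e >= n) right <- integer(0)
    repl <- median(cov[unique(c(left, right))])
    cov[(s + 1):e] <- repl
  }
  cov
}

#' Estimate haploid copy number of one TE family
#'
#' Copies = mean over consensus positions of total coverage (unambiguous +
#' ambiguous), with positions inside annotated homopolymer runs replaced
#' by the median coverage of the 50 bp flanks when `curb_polyA` is set,
#' divided by the normalization factor.
#'
#' @param pileup A `pileup_matrix`.
#' @param family A `te_consensus` or family id.
#' @param factor Normalization factor from [normalization_factor()].
#' @param library A `te_library` (supplies homopolymer annotations).
#' @param curb_polyA Curb coverage at homopolymer runs; default TRUE.
#' @param sample_id Optional sample label carried in the output.
#' @param thresholds Classification thresholds; see [default_thresholds()].
#' @return One-row data frame: family_id, sample_id, copies,
#'   normalization_factor, breadth, mean_read_divergence, status.
#' @export
copy_number <- function(pileup, family, factor, library,
                        curb_polyA = TRUE, sample_id = NA_character_,
                        thresholds = default_thresholds()) {
  stopifnot(factor > 0)
  id <- if (inherits(family, "te_consensus")) family$family_id else family
  fam <- pileup$families[[id]]
  cov <- fam$counts[, "cov_u"] + fam$counts[, "cov_a"]
  breadth <- mean(cov >= 1)
  if (curb_polyA) {
    cov <- curb_homopolymers(cov, library$homopolymer_runs[[id]])
  }
  copies <- mean(cov) / factor
  mdiv <- if (length(fam$divergence) > 0) {
    sum(fam$divergence * fam$weight) / sum(fam$weight)
  } else NA_real_
  call <- data.frame(
    family_id = id, sample_id = sample_id, copies = copies,
    normalization_factor = factor, breadth = breadth,
    mean_read_divergence = mdiv, status = NA_character_,
    stringsAsFactors = FALSE)
  call$status <- classify_family(call, thresholds)
  call
}

#' Call TE-internal SNPs from a pileup
#'
#' Sites with unambiguous coverage at least `min_cov` where a
#' non-reference base has frequency at least `min_freq`; frequencies are
#' base count over total base count at the site. Ambiguous coverage is
#' excluded: base identity of ambiguous reads is unreliable.
#'
#' @param pileup A `pileup_matrix`.
#' @param family A `te_consensus` (reference bases are taken from it).
#' @param min_cov Minimum unambiguous site coverage; default 10.
#' @param min_freq Minimum alternative-allele frequency; default 0.1.
#' @return Data frame: family_id, pos (0-based), ref, alt, freq, coverage.
#' @export
call_snps <- function(pileup, family, min_cov = 10, min_freq = 0.1) {
  stopifnot(min_cov >= 1, min_freq > 0, min_freq < 0.5)
  id <- family$family_id
  m <- pileup$families[[id]]$counts
  refbase <- strsplit(family$sequence, "")[[1]]
  bases <- m[, c("A", "C", "G", "T"), drop = FALSE]
  tot <- rowSums(bases)
  rows <- list()
  for (pos in which(m[, "cov_u"] >= min_cov)) {
    for (b in DNA_BASES) {
      if (b == refbase[pos]) next
      f <- bases[pos, b] / tot[pos]
      if (f >= min_freq) {
        rows[[length(rows) + 1]] <- data.frame(
          family_id = id, pos = pos - 1L, ref = refbase[pos], alt = b,
          freq = f, coverage = tot[pos], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(family_id = character(), pos = integer(),
                      ref = character(), alt = character(),
                      freq = numeric(), coverage = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Reads-per-million abundance per family
#'
#' Reads assigned to each reference (ambiguous reads counted at weight
#' 1/k) times 1e6, divided by the total number of mapped reads.
#'
#' @param alignments Alignment data frame.
#' @return Named numeric vector (families and genes).
#' @export
rpm_abundance <- function(alignments) {
  total <- length(unique(alignments$read_id))
  if (total == 0) stop("no mapped reads; rpm undefined")
  w <- tapply(alignments$weight, alignments$family_id, sum)
  out <- as.numeric(w) * 1e6 / total
  names(out) <- names(w)
  out
}

#' Fold enrichment of copy numbers between two samples
#'
#' @param calls_a,calls_b Copy-number call tables for the two samples
#'   (same family sets; `calls_a` is the reference/earlier sample).
#' @param pseudocount Added to both numerator and denominator; default 0.1
#'   so that families absent from the earlier sample get a finite bar.
#' @return Named numeric vector of (copies_b + p) / (copies_a + p).
#' @export
fold_enrichment <- function(calls_a, calls_b, pseudocount = 0.1) {
  stopifnot(setequal(calls_a$family_id, calls_b$family_id))
  a <- setNames(calls_a$copies, calls_a$family_id)
  b <- setNames(calls_b$copies, calls_b$family_id)[names(a)]
  (b + pseudocount) / (a + pseudocount)
}

#' Classify a per-sample per-family call into invasion status
#'
#' `absent` below `c_min` copies; `recent` when copies, breadth and mean
#' read divergence all indicate intact near-consensus copies;
#' `degraded_only` otherwise (patchy or highly diverged signal, i.e.
#' remnants of an ancient invasion).
#'
#' @param call One-row copy-number call data frame.
#' @param thresholds See [default_thresholds()].
#' @return One of "absent", "degraded_only", "recent".
#' @export
classify_family <- function(call, thresholds = default_thresholds()) {
  if (call$copies < thresholds$c_min) return("absent")
  if (call$breadth >= thresholds$breadth &&
      !is.na(call$mean_read_divergence) &&
      call$mean_read_divergence <= thresholds$divergence) {
    return("recent")
  }
  "degraded_only"
}

#' Assemble per-family invasion intervals across dated samples
#'
#' For each family, the invasion interval is bracketed by `t_low`, the
#' latest collection year up to which every sample is non-recent, and
#' `t_high`, the earliest year from which every sample onward is recent.
#' Families recent everywhere get `(-Inf, earliest year)`; families absent
#' everywhere get no interval (NA row).
#'
#' @param calls Copy-number call table across samples (with `status`).
#' @param metadata Data frame with `sample_id` and `year`.
#' @return Data frame: family_id, t_low, t_high.
#' @export
build_timeline <- function(calls, metadata) {
  if (length(unique(metadata$year)) < 2) {
    stop("need samples from at least two distinct collection years")
  }
  missing <- setdiff(calls$sample_id, metadata$sample_id)
  if (length(missing) > 0) {
    stop("sample(s) without collection year: ",
         paste(missing, collapse = ", "))
  }
  calls$year <- metadata$year[match(calls$sample_id, metadata$sample_id)]
  years <- sort(unique(calls$year))
  out <- lapply(split(calls, calls$family_id), function(fc) {
    if (all(fc$status == "absent")) {
      return(data.frame(family_id = fc$family_id[1], t_low = NA_real_,
                        t_high = NA_real_, stringsAsFactors = FALSE))
    }
    all_nonrecent_upto <- vapply(years, function(y)
      all(fc$status[fc$year <= y] != "recent"), TRUE)
    all_recent_from <- vapply(years, function(y)
      all(fc$status[fc$year >= y] == "recent"), TRUE)
    t_low <- if (any(all_nonrecent_upto))
      max(years[all_nonrecent_upto]) else -Inf
    t_high <- if (any(all_recent_from))
      min(years[all_recent_from]) else Inf
    data.frame(family_id = fc$family_id[1], t_low = t_low,
               t_high = t_high, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Wilcoxon rank-sum comparison of copy numbers between two sample groups
#'
#' Two-sided; exact p-value when the combined sample size is at most 25
#' and there are no ties, normal approximation with tie correction
#' otherwise.
#'
#' @param copies_a,copies_b Copy numbers of the two groups (each >= 2).
#' @return List with `W` and `p_value`.
#' @export
compare_groups <- function(copies_a, copies_b) {
  stopifnot(length(copies_a) >= 2, length(copies_b) >= 2)
  if (all(copies_a == copies_a[1]) && all(copies_b == copies_b[1]) &&
      copies_a[1] == copies_b[1]) {
    return(list(W = length(copies_a) * length(copies_b) / 2, p_value = 1))
  }
  n <- length(copies_a) + length(copies_b)
  ties <- anyDuplicated(c(copies_a, copies_b)) > 0
  wt <- suppressWarnings(wilcox.test(copies_a, copies_b,
                                     exact = n <= 25 && !ties,
                                     correct = TRUE))
  list(W = unname(wt$statistic), p_value = wt$p.value)
}
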