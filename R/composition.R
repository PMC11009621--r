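## Cross-sample TE-SNP allele-frequency matrices, composition PCA,
## diagnostic-SNP detection and the ablation experiment.

#' Build a samples x TE-SNP allele-frequency matrix
#'
#' Columns are the union of SNP keys ("family:pos:alt", 0-based positions)
#' over all samples. An entry is the alternative-allele frequency in that
#' sample: 0 when the site was covered but the alternative absent, NA when
#' the site was uncovered (only distinguishable when pileups are given).
#'
#' @param snp_calls Named list (by sample id) of SNP call tables from
#'   [call_snps()].
#' @param metadata Data frame with `sample_id` and `population`.
#' @param pileups Optional named list of `pileup_matrix` objects used to
#'   distinguish uncovered sites (NA) from covered reference-only sites
#'   (0); without it, all absent entries are 0.
#' @param min_cov Coverage threshold defining "covered"; default 10.
#' @return An `allele_freq_matrix`: numeric matrix (samples x SNP keys)
#'   with a `population` attribute and a `filters` provenance attribute.
#' @export
build_matrix <- function(snp_calls, metadata, pileups = NULL,
                         min_cov = 10) {
  stopifnot(length(snp_calls) >= 2)
  ids <- names(snp_calls)
  if (anyDuplicated(ids) > 0) {
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  keys <- unique(unlist(lapply(snp_calls, function(s)
    if (nrow(s) > 0) paste(s$family_id, s$pos, s$alt, sep = ":"))))
  m <- matrix(0, nrow = length(ids), ncol = length(keys),
              dimnames = list(ids, keys))
  for (sid in ids) {
    s <- snp_calls[[sid]]
    if (nrow(s) > 0) {
      m[sid, paste(s$family_id, s$pos, s$alt, sep = ":")] <- s$freq
    }
    if (!is.null(pileups)) {
      parts <- strsplit(keys, ":")
      for (j in seq_along(keys)) {
        fam <- parts[[j]][1]
        pos <- as.integer(parts[[j]][2])
        covu <- pileups[[sid]]$families[[fam]]$counts[pos + 1, "cov_u"]
        if (covu < min_cov && m[sid, j] == 0) m[sid, j] <- NA
      }
    }
  }
  structure(m,
            population = setNames(
              metadata$population[match(ids, metadata$sample_id)], ids),
            filters = character(0),
            class = c("allele_freq_matrix", "matrix", "array"))
}

afm_population <- function(m) attr(m, "population")

afm_subset <- function(m, rows = NULL, cols = NULL) {
  pop <- attr(m, "population")
  filt <- attr(m, "filters")
  out <- unclass(m)
  if (!is.null(rows)) { out <- out[rows, , drop = FALSE]; pop <- pop[rows] }
  if (!is.null(cols)) out <- out[, cols, drop = FALSE]
  structure(out, population = pop, filters = filt,
            class = c("allele_freq_matrix", "matrix", "array"))
}

#' Filter an allele-frequency matrix
#'
#' Removes sites with more than two observed alleles (reference plus more
#' than one alternative) and SNPs with nonzero frequency in at most
#' `min_samples` samples.
#'
#' @param m An `allele_freq_matrix`.
#' @param min_samples SNPs found in `<= min_samples` samples are removed;
#'   default 3.
#' @return Filtered `allele_freq_matrix`.
#' @export
filter_matrix <- function(m, min_samples = 3) {
  stopifnot(min_samples >= 0)
  keys <- colnames(m)
  parts <- strsplit(keys, ":")
  site <- vapply(parts, function(p) paste(p[1], p[2], sep = ":"), "")
  observed <- colSums(!is.na(m) & m > 0) > 0
  n_alt <- tapply(observed, site, sum)
  biallelic <- keys[n_alt[site] <= 1]
  common <- keys[colSums(!is.na(m) & m > 0) > min_samples]
  keep <- intersect(biallelic, common)
  if (length(keep) == 0) {
    warning("no SNP passes the filters; returning an empty matrix")
  }
  out <- afm_subset(m, cols = keep)
  attr(out, "filters") <- unique(c(attr(m, "filters"),
    sprintf("biallelic; >%d samples", min_samples)))
  out
}

#' Principal component analysis of TE composition
#'
#' Missing entries are imputed to the column mean; columns are centered
#' (and optionally standardized) and decomposed by SVD. Component signs
#' are fixed by making each component's largest-magnitude loading
#' positive.
#'
#' @param m An `allele_freq_matrix` (>= 3 samples, >= 2 columns).
#' @param scale. Standardize columns; default FALSE (raw frequencies).
#' @return List with `coordinates` (samples x PCs), `var_explained`,
#'   `loadings` and `population`.
#' @export
composition_pca <- function(m, scale. = FALSE) {
  stopifnot(nrow(m) >= 3, ncol(m) >= 2)
  x <- unclass(m)
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- mean(x[, j], na.rm = TRUE)
  }
  sds <- apply(x, 2, sd)
  if (all(sds == 0)) stop("zero-variance matrix; PCA undefined")
  if (scale. && any(sds == 0)) x <- x[, sds > 0, drop = FALSE]
  p <- prcomp(x, center = TRUE, scale. = scale.)
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  coords <- sweep(p$x, 2, flip, `*`)
  loadings <- sweep(p$rotation, 2, flip, `*`)
  list(coordinates = coords,
       var_explained = p$sdev^2 / sum(p$sdev^2),
       loadings = loadings,
       population = afm_population(m))
}

#' Detect diagnostic SNPs for one population
#'
#' SNPs abundant in the population of interest but rare in every other
#' population: mean frequency >= `f_in` inside and <= `f_out` in each
#' other population, sorted by the inside-outside frequency gap.
#'
#' @param m An `allele_freq_matrix`.
#' @param target_pop Population label.
#' @param f_in Minimum mean frequency inside the target; default 0.3.
#' @param f_out Maximum mean frequency in every other population;
#'   default 0.1.
#' @return Character vector of SNP keys, best first.
#' @export
diagnostic_snps <- function(m, target_pop, f_in = 0.3, f_out = 0.1) {
  pop <- afm_population(m)
  if (!target_pop %in% pop) {
    stop("unknown population label: ", target_pop)
  }
  stopifnot(sum(pop == target_pop) >= 2)
  x <- unclass(m)
  inside <- colMeans(x[pop == target_pop, , drop = FALSE], na.rm = TRUE)
  others <- setdiff(unique(pop), target_pop)
  out_max <- apply(vapply(others, function(p)
    colMeans(x[pop == p, , drop = FALSE], na.rm = TRUE),
    numeric(ncol(x))), 1, max)
  hit <- which(inside >= f_in & out_max <= f_out)
  hit <- hit[order(inside[hit] - out_max[hit], decreasing = TRUE)]
  colnames(m)[hit]
}

#' PCA after removing a set of SNP columns
#'
#' @param m An `allele_freq_matrix`.
#' @param remove SNP keys to drop (must be columns of `m`).
#' @param scale. Passed to [composition_pca()].
#' @return PCA result as from [composition_pca()].
#' @export
ablate_and_pca <- function(m, remove, scale. = FALSE) {
  bad <- setdiff(remove, colnames(m))
  if (length(bad) > 0) {
    stop("not a column of the matrix: ", paste(bad, collapse = ", "))
  }
  keep <- setdiff(colnames(m), remove)
  if (length(keep) < 2) stop("removal leaves fewer than 2 SNPs")
  composition_pca(afm_subset(m, cols = keep), scale. = scale.)
}

#' Mean between-population distance on the first two PCs
#'
#' Helper used to quantify how strongly populations separate in a
#' composition PCA (e.g. before vs after ablating diagnostic SNPs).
#'
#' @param pca Result of [composition_pca()].
#' @return Mean Euclidean distance between population centroids on
#'   PC1-PC2.
#' @export
population_separation <- function(pca) {
  co <- pca$coordinates[, 1:2, drop = FALSE]
  pop <- pca$population
  cent <- do.call(rbind, lapply(split(seq_len(nrow(co)), pop),
                                function(i) colMeans(co[i, , drop = FALSE])))
  mean(dist(cent))
}
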