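## End-to-end orchestration from a config, plus figure rendering.
## Artifacts are flat TSV tables in one run directory, so stages can be
## re-run independently and runs diffed.

#' Validate a pipeline run configuration
#'
#' A config is a list (or YAML file) with `out_dir`, `seed`, `library`
#' (paths `te_fasta`/`gene_fasta`), `samples` (data frame or TSV path:
#' sample_id, year, population, fastq), optional `smallrna` (fastq,
#' adapter), optional `assemblies` (named FASTA paths), and `params`
#' overriding defaults (trim_len, min_identity, snp_min_cov, snp_min_freq,
#' min_samples, f_in, f_out, defrag_gap, min_score, curb_polyA,
#' thresholds).
#'
#' @param config List or path to a YAML file.
#' @return Validated config list with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(!is.null(config$out_dir), !is.null(config$library))
  defaults <- list(trim_len = 100, min_identity = 0.75, snp_min_cov = 10,
                   snp_min_freq = 0.1, min_samples = 3, f_in = 0.3,
                   f_out = 0.1, defrag_gap = 100, min_score = 100,
                   curb_polyA = TRUE)
  config$params <- utils::modifyList(defaults, config$params %||% list())
  p <- config$params
  stopifnot(p$trim_len > 0, p$min_identity > 0, p$min_identity <= 1,
            p$snp_min_cov >= 1, p$snp_min_freq > 0, p$snp_min_freq < 0.5,
            p$defrag_gap >= 0)
  config$seed <- config$seed %||% 1L
  if (is.character(config$samples)) config$samples <- read_tsv(config$samples)
  for (f in c(config$library$te_fasta, config$library$gene_fasta,
              config$samples$fastq)) {
    if (!is.null(f) && !file.exists(f)) stop("missing input file: ", f)
  }
  config
}

param_string <- function(params) {
  paste(names(params), unlist(params), sep = "=", collapse = " ")
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order (library, align,
#' abundance, timeline, composition, smallrna, donors) and writes one TSV
#' artifact per result into `config$out_dir`. Each table header names the
#' producing package version and parameters. All randomness derives from
#' `config$seed` expanded by fixed per-stage offsets.
#'
#' @param config See [validate_config()].
#' @param stages Subset of stages to run; default all that have inputs.
#' @return Invisibly, the artifact directory path.
#' @export
run_pipeline <- function(config,
                         stages = c("align", "abundance", "timeline",
                                    "composition", "smallrna", "donors")) {
  config <- validate_config(config)
  p <- config$params
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out, "alignments"), showWarnings = FALSE)
  hdr <- paste0("retroinvade ",
                as.character(utils::packageVersion("retroinvade")),
                " | ", param_string(p))
  log <- file.path(out, "run.log")
  logmsg <- function(...) cat(..., "\n", file = log, append = TRUE)
  cat("", file = log)

  lib <- load_library(config$library$te_fasta, config$library$gene_fasta,
                      ltr_lengths = config$library$ltr_lengths)
  write_tsv(library_manifest(lib), file.path(out, "library_manifest.tsv"),
            comment = hdr)

  aln_path <- function(sid) file.path(out, "alignments",
                                      paste0(sid, ".tsv"))

  if ("align" %in% stages) {
    for (i in seq_len(nrow(config$samples))) {
      sid <- config$samples$sample_id[i]
      reads <- trim_reads(read_fastq(config$samples$fastq[i]), p$trim_len)
      aln <- align_reads(reads, lib, min_identity = p$min_identity)
      logmsg("align:", sid, "reads_in:", attr(aln, "n_reads_in"),
             "aligned:", length(unique(aln$read_id)))
      write_tsv(aln, aln_path(sid), comment = hdr)
    }
  }

  load_alignments <- function() {
    lapply(setNames(nm = config$samples$sample_id), function(sid) {
      if (!file.exists(aln_path(sid))) {
        stop("missing artifact ", aln_path(sid),
             ": run the 'align' stage first")
      }
      read_tsv(aln_path(sid))
    })
  }

  snp_calls <- NULL
  pileups <- NULL
  if (any(c("abundance", "timeline", "composition") %in% stages)) {
    alns <- load_alignments()
    pileups <- lapply(alns, build_pileup, library = lib)
  }

  if ("abundance" %in% stages) {
    calls <- do.call(rbind, lapply(names(pileups), function(sid) {
      nf <- normalization_factor(pileups[[sid]], lib)
      do.call(rbind, lapply(lib$families, function(fam)
        copy_number(pileups[[sid]], fam, nf, lib,
                    curb_polyA = p$curb_polyA, sample_id = sid)))
    }))
    rownames(calls) <- NULL
    write_tsv(calls, file.path(out, "copy_number.tsv"), comment = hdr)
    rpm <- do.call(rbind, lapply(names(pileups), function(sid) {
      r <- rpm_abundance(read_tsv(aln_path(sid)))
      data.frame(sample_id = sid, family_id = names(r), rpm = as.numeric(r),
                 stringsAsFactors = FALSE)
    }))
    write_tsv(rpm, file.path(out, "rpm.tsv"), comment = hdr)
    logmsg("abundance:", nrow(calls), "calls")
  }

  if ("timeline" %in% stages) {
    cn_path <- file.path(out, "copy_number.tsv")
    if (!file.exists(cn_path)) {
      stop("missing artifact ", cn_path, ": run the 'abundance' stage first")
    }
    tl <- build_timeline(read_tsv(cn_path), config$samples)
    write_tsv(tl, file.path(out, "timeline.tsv"), comment = hdr)
    logmsg("timeline:", nrow(tl), "families")
  }

  if ("composition" %in% stages) {
    snp_calls <- lapply(pileups, function(pl)
      do.call(rbind, lapply(lib$families, function(fam)
        call_snps(pl, fam, min_cov = p$snp_min_cov,
                  min_freq = p$snp_min_freq))))
    m <- build_matrix(snp_calls, config$samples, pileups = pileups,
                      min_cov = p$snp_min_cov)
    m <- filter_matrix(m, min_samples = p$min_samples)
    mt <- data.frame(sample_id = rownames(m),
                     population = afm_population(m), unclass(m),
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(mt, file.path(out, "allele_freq_matrix.tsv"), comment = hdr)
    if (ncol(m) >= 2) {
      pca <- composition_pca(m)
      co <- data.frame(sample_id = rownames(pca$coordinates),
                       population = pca$population,
                       pca$coordinates[, seq_len(min(4, ncol(pca$coordinates))),
                                       drop = FALSE],
                       stringsAsFactors = FALSE)
      write_tsv(co, file.path(out, "pca_coordinates.tsv"), comment = hdr)
      ve <- data.frame(component = seq_along(pca$var_explained),
                       var_explained = pca$var_explained)
      write_tsv(ve, file.path(out, "pca_variance.tsv"), comment = hdr)
    }
    logmsg("composition:", ncol(m), "SNPs after filtering")
  }

  if ("smallrna" %in% stages && !is.null(config$smallrna)) {
    reads <- preprocess_smallrna(
      read_fastq(config$smallrna$fastq),
      adapter = config$smallrna$adapter %||% "TGGAATTCTCGGGTGCCAAGG")
    counts <- map_smallrna(reads, lib)
    prof <- lapply(counts, pingpong_signature)
    ov <- do.call(rbind, lapply(names(prof), function(id)
      data.frame(family_id = id, k = as.integer(names(prof[[id]]$overlap)),
                 overlap = as.numeric(prof[[id]]$overlap),
                 stringsAsFactors = FALSE)))
    write_tsv(ov, file.path(out, "pingpong_overlap.tsv"), comment = hdr)
    z <- data.frame(family_id = names(prof),
                    z10 = vapply(prof, `[[`, 0, "z10"),
                    stringsAsFactors = FALSE)
    write_tsv(z, file.path(out, "pingpong_summary.tsv"), comment = hdr)
    logmsg("smallrna:", nrow(reads), "reads after preprocessing")
  }

  if ("donors" %in% stages && !is.null(config$assemblies)) {
    hits <- lapply(setNames(nm = names(config$assemblies)), function(a) {
      h <- find_hits(config$assemblies[[a]], lib,
                     min_score = p$min_score, assembly_id = a)
      defragment(h, max_gap = p$defrag_gap)
    })
    sim <- similarity_scores(hits, families = names(lib$families))
    write_tsv(sim$table, file.path(out, "similarity.tsv"), comment = hdr)
    ld <- do.call(rbind, lapply(hits, length_divergence_table))
    write_tsv(ld, file.path(out, "length_divergence.tsv"), comment = hdr)
    logmsg("donors:", sum(vapply(hits, nrow, 0L)), "defragmented hits")
  }

  invisible(out)
}

#' Render summary figures from a pipeline artifact directory
#'
#' One figure per available table (copy-number status grid, PCA scatter,
#' ping-pong overlap histogram, donor similarity bars); missing tables are
#' skipped with a warning. Plot failures never corrupt tables.
#'
#' @param artifact_dir Directory written by [run_pipeline()].
#' @param format Figure file format; default "png".
#' @return Invisibly, the paths of the figures written.
#' @export
render_reports <- function(artifact_dir, format = "png") {
  figs <- file.path(artifact_dir, "figures")
  dir.create(figs, showWarnings = FALSE)
  written <- character(0)
  save_fig <- function(name, plot) {
    path <- file.path(figs, paste0(name, ".", format))
    tryCatch({
      ggplot2::ggsave(path, plot, width = 7, height = 5, dpi = 120)
      written <<- c(written, path)
    }, error = function(e) warning("figure ", name, " failed: ",
                                   conditionMessage(e)))
  }
  tab <- function(name) {
    path <- file.path(artifact_dir, name)
    if (!file.exists(path)) {
      warning("missing table ", name, "; skipping its figure")
      return(NULL)
    }
    read_tsv(path)
  }

  cn <- tab("copy_number.tsv")
  if (!is.null(cn)) {
    save_fig("status_grid",
      ggplot2::ggplot(cn, ggplot2::aes(
          x = sample_id, y = family_id, fill = status)) +
        ggplot2::geom_tile(color = "white") +
        ggplot2::geom_text(ggplot2::aes(label = round(copies, 1)),
                           size = 2.5) +
        ggplot2::scale_fill_manual(values = c(
          absent = "#d73027", degraded_only = "#fee08b",
          recent = "#1a9850")) +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90)))
  }
  co <- tab("pca_coordinates.tsv")
  if (!is.null(co) && all(c("PC1", "PC2") %in% names(co))) {
    save_fig("pca",
      ggplot2::ggplot(co, ggplot2::aes(PC1, PC2, color = population)) +
        ggplot2::geom_point(size = 2) + ggplot2::theme_minimal())
  }
  ov <- tab("pingpong_overlap.tsv")
  if (!is.null(ov)) {
    save_fig("pingpong",
      ggplot2::ggplot(ov, ggplot2::aes(k, overlap)) +
        ggplot2::geom_col() +
        ggplot2::facet_wrap(~family_id, scales = "free_y") +
        ggplot2::theme_minimal())
  }
  sim <- tab("similarity.tsv")
  if (!is.null(sim)) {
    save_fig("similarity",
      ggplot2::ggplot(sim, ggplot2::aes(assembly_id, s)) +
        ggplot2::geom_col() +
        ggplot2::facet_wrap(~family_id) +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90)))
  }
  invisible(written)
}
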