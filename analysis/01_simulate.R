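#!/usr/bin/env Rscript
# Build the synthetic study inputs: a TE consensus library with
# single-copy normalization genes, a panel of dated short-read samples
# spanning a planted invasion (absent until 1850, fixed from 1933 on),
# a small-RNA read set with a planted ping-pong signal, and a ladder of
# candidate donor assemblies. Everything downstream reads these files.

suppressPackageStartupMessages(library(retroinvade))

data_dir <- "results/data"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

## Library: three TE families (one with a poly-A tract, so coverage
## curbing is exercised) and three equal-length single-copy genes.
set.seed(20240601)
rdna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                          collapse = "")
lib <- build_library(
  c(blood_syn = rdna(1500),
    opus_syn = paste0(rdna(1480), strrep("A", 20)),
    te412_syn = rdna(1800)),
  c(rhi_syn = rdna(1500), tj_syn = rdna(1500), rpl32_syn = rdna(1500)))
write_library(lib, file.path(data_dir, "te_consensus.fa"),
              file.path(data_dir, "genes.fa"))
cat("library:", length(lib$families), "TE families,",
    length(lib$genes), "genes\n")

## Dated sample panel. blood_syn and opus_syn invade between 1850 and
## 1933; te412_syn is an old, degraded-only family throughout (the
## negative control, like Circe/Invader-4 in a real panel). The two most
## recent samples carry private blood_syn lineage SNPs (a founder-effect
## population, used again by the composition analysis).
meta <- data.frame(
  sample_id = c("s1800a", "s1800b", "s1850a", "s1850b",
                "s1933a", "s1933b", "s1967a", "s1967b"),
  year = c(1800, 1800, 1850, 1850, 1933, 1933, 1967, 1967),
  population = c(rep("historic", 6), "derived", "derived"),
  stringsAsFactors = FALSE)
priv <- data.frame(pos = c(300, 900), alt = c("A", "C"), freq = 0.7)
meta$fastq <- vapply(seq_len(nrow(meta)), function(i) {
  invaded <- meta$year[i] >= 1933
  fams <- list(
    blood_syn = list(
      copy_number = if (invaded) 10 else 0,
      lineage_snps = if (meta$population[i] == "derived") priv else NULL),
    opus_syn = list(copy_number = if (invaded) 6 else 0),
    te412_syn = list(copy_number = 0,
                     degraded = list(count = 4, divergence = 0.25,
                                     len_range = c(300, 700))))
  g <- build_genome(genome_spec(15000, fams, seed = 100 + i), lib)
  reads <- simulate_reads(g$genome, coverage = 15, read_len = 100,
                          error_rate = 0.01, seed = 200 + i)
  f <- file.path(data_dir, paste0(meta$sample_id[i], ".fastq"))
  write_fastq(reads, f)
  cat("sample", meta$sample_id[i], ":", nrow(reads), "reads\n")
  f
}, "")
write.table(meta, file.path(data_dir, "samples.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## Small RNAs: half the pairs in ping-pong configuration.
sr <- simulate_smallrna(lib$families$blood_syn, n_pairs = 1000,
                        pingpong_fraction = 0.5, seed = 300)
write_fastq(sr, file.path(data_dir, "smallrna.fastq"))
cat("small RNA:", nrow(sr), "reads\n")

## Donor-assembly ladder: the 0-divergence assembly is the true donor.
panel <- build_species_panel(lib, c(0, 0.05, 0.1, 0.2, 0.3), seed = 400)
for (a in names(panel$assemblies)) {
  write_fasta(panel$assemblies[[a]],
              file.path(data_dir, paste0(a, ".fa")))
}
write.table(panel$truth, file.path(data_dir, "assembly_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("assemblies:", length(panel$assemblies), "(donor:",
    panel$truth$assembly[panel$truth$is_donor], ")\n")
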