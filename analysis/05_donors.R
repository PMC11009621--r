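#!/usr/bin/env Rscript
# Horizontal-transfer donor analysis on the assembly ladder: find and
# defragment TE hits in every candidate assembly, rank assemblies by the
# similarity statistic s = max(score_i)/max(score_all), summarize the
# length-divergence structure, extract full-length insertions from the
# top-ranked assembly, and date a synthetic LTR insertion from its
# LTR-LTR divergence.

suppressPackageStartupMessages(library(retroinvade))

out <- "results/donors"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
lib <- load_library("results/data/te_consensus.fa",
                    "results/data/genes.fa")
truth <- read.table("results/data/assembly_truth.tsv", header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)

asm_files <- setNames(file.path("results/data",
                                paste0(truth$assembly, ".fa")),
                      truth$assembly)
assemblies <- lapply(asm_files, read_fasta)
hits <- lapply(names(assemblies), function(a)
  defragment(find_hits(assemblies[[a]], lib, assembly_id = a), 100))
names(hits) <- names(assemblies)

sim <- similarity_scores(hits, families = names(lib$families))
cat("similarity table (rows = assemblies on the divergence ladder):\n")
print(reshape(sim$table, idvar = "assembly_id", timevar = "family_id",
              direction = "wide"), digits = 2)
write.table(sim$table, file.path(out, "similarity.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("best assembly per family:",
    paste(names(sim$best_assembly), sim$best_assembly, sep = "=",
          collapse = ", "), "\n")
stopifnot(all(sim$best_assembly == truth$assembly[truth$is_donor]))

ld <- do.call(rbind, lapply(hits, length_divergence_table))
write.table(ld, file.path(out, "length_divergence.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## full-length extraction from the donor assembly
donor <- truth$assembly[truth$is_donor]
fl <- extract_full_length(hits[[donor]], assemblies[[donor]],
                          c(1400, 2000))
cat("full-length insertions extracted from", donor, ":", length(fl), "\n")
write_fasta(fl, file.path(out, "full_length_insertions.fa"))

## LTR dating: a synthetic insertion whose LTRs diverged by 1%
set.seed(900)
ltr <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
chars <- strsplit(ltr, "")[[1]]
at <- sample(400, 4)
for (i in at) chars[i] <- setdiff(c("A", "C", "G", "T"), chars[i])[1]
ins <- paste0(ltr, paste(sample(c("A", "C", "G", "T"), 3000, TRUE),
                         collapse = ""), paste(chars, collapse = ""))
age <- ltr_age(ins, ltr_length = 400, rate = 5e-9)
cat(sprintf("LTR-LTR divergence %.3f -> age %.2g years (rate 5e-9)\n",
            age$d, age$age_years))
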