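lib <- test_library()

test_that("trimming is filter-or-trim", {
  reads <- data.frame(id = c("a", "b", "c"),
                      seq = c(rand_dna(150, seed = 1), rand_dna(80),
                              rand_dna(100)),
                      qual = c(strrep("I", 150), strrep("I", 80),
                               strrep("I", 100)),
                      stringsAsFactors = FALSE)
  out <- trim_reads(reads, 100)
  expect_identical(out$id, c("a", "c"))
  expect_identical(out$seq[1], substr(reads$seq[1], 1, 100))
  expect_identical(out$seq[2], reads$seq[3])
  expect_true(all(nchar(out$qual) == 100))
})

test_that("malformed FASTQ is reported by record number", {
  f <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII",
               "r2-missing-at", "ACGT", "+", "IIII"), f)
  expect_error(read_fastq(f), "record 2")
  writeLines(c("@r1", "ACGT", "+", "III"), f)  # qual length mismatch
  expect_error(read_fastq(f), "record 1")
  writeLines(c("@r1", "ACGT", "+"), f)
  expect_error(read_fastq(f), "truncated")
})

test_that("planted reads align exactly; diverged reads are dropped", {
  cons <- lib$families$blood_syn$sequence
  planted <- substr(cons, 501, 600)
  aln <- align_reads(data.frame(id = "p", seq = planted), lib)
  expect_equal(nrow(aln), 1)
  expect_equal(aln$family_id, "blood_syn")
  expect_equal(aln$start, 500)
  expect_equal(aln$strand, "+")
  expect_equal(aln$mismatches, 0)
  expect_false(aln$is_ambiguous)

  # reverse-complement read maps to the same locus on '-'
  rcread <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(planted)))
  aln2 <- align_reads(data.frame(id = "p", seq = rcread), lib)
  expect_equal(aln2$start, 500)
  expect_equal(aln2$strand, "-")

  # 25% divergence falls below min_identity 0.8
  set.seed(4)
  chars <- strsplit(planted, "")[[1]]
  at <- sample(100, 25)
  for (i in at) chars[i] <- setdiff(c("A", "C", "G", "T"), chars[i])[1]
  div <- paste(chars, collapse = "")
  expect_equal(nrow(align_reads(data.frame(id = "d", seq = div), lib,
                                min_identity = 0.8)), 0)
})

test_that("aligner matches an exhaustive all-offsets oracle", {
  sam <- make_sample(lib, list(blood_syn = 3, opus_syn = 2), seed = 77,
                     coverage = 2, backbone = 10000)
  reads <- sam$reads[seq_len(min(250, nrow(sam$reads))), ]
  got <- align_reads(reads, lib)
  want <- oracle_align(reads, lib)
  cols <- c("read_id", "family_id", "start", "strand", "mismatches",
            "aligned_len", "is_ambiguous")
  ord <- function(d) {
    d <- d[do.call(order, d[c("read_id", "family_id")]), cols]
    rownames(d) <- NULL
    d
  }
  expect_equal(ord(as.data.frame(got)), ord(want))
})

test_that("ambiguous reads split weight across tied families", {
  # two families sharing an identical 100 bp block
  shared <- rand_dna(100, seed = 55)
  tes <- c(f1 = paste0(rand_dna(400), shared, rand_dna(400)),
           f2 = paste0(rand_dna(300), shared, rand_dna(500)))
  lib2 <- build_library(tes, c(g = rand_dna(500)))
  aln <- align_reads(data.frame(id = "s", seq = shared), lib2)
  expect_equal(nrow(aln), 2)
  expect_true(all(aln$is_ambiguous))
  expect_equal(aln$weight, c(0.5, 0.5))

  pl <- build_pileup(aln, lib2)
  expect_equal(max(pl$families$f1$counts[, "cov_a"]), 0.5)
  expect_equal(sum(pl$families$f1$counts[, "cov_u"]), 0)
})

test_that("pileup counts equal an independent recount and conserve reads", {
  sam <- make_sample(lib, list(blood_syn = 5, opus_syn = 3), seed = 91,
                     coverage = 8, backbone = 15000)
  aln <- sam$alignments
  pl <- sam$pileup

  # independent per-position recount for one family
  sub <- aln[aln$family_id == "blood_syn" & !aln$is_ambiguous, ]
  len <- lib$families$blood_syn$length
  counts <- matrix(0, len, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_len(nrow(sub))) {
    ch <- strsplit(sub$seq[i], "")[[1]]
    for (p in seq_along(ch)) {
      counts[sub$start[i] + p, ch[p]] <- counts[sub$start[i] + p, ch[p]] + 1
    }
  }
  expect_equal(unname(pl$families$blood_syn$counts[, c("A", "C", "G", "T")]),
               unname(counts))
  # covU = sum of base counts at every position
  expect_equal(pl$families$blood_syn$counts[, "cov_u"],
               rowSums(pl$families$blood_syn$counts[, c("A", "C", "G", "T")]))

  # conservation: unambiguous reads + ambiguity weights = aligned reads
  expect_equal(sum(aln$weight), length(unique(aln$read_id)))

  # permutation invariance
  perm <- aln[sample(nrow(aln)), ]
  pl2 <- build_pileup(perm, lib)
  expect_equal(pl$families$blood_syn$counts, pl2$families$blood_syn$counts)
})

test_that("SAM round trip reproduces the internal pileup", {
  sam <- make_sample(lib, list(blood_syn = 4), seed = 17, coverage = 5,
                     backbone = 10000)
  f <- tempfile(fileext = ".sam")
  write_sam(sam$alignments, lib, f)
  aln2 <- ingest_sam(f, lib)
  expect_equal(nrow(aln2), nrow(sam$alignments))
  pl1 <- sam$pileup
  pl2 <- build_pileup(aln2, lib)
  for (id in names(pl1$families)) {
    expect_equal(pl2$families[[id]]$counts, pl1$families[[id]]$counts)
  }

  # tie semantics: primary + equal-scoring secondary on another family
  f2 <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    sprintf("@SQ\tSN:%s\tLN:%d", "blood_syn", 1500),
    sprintf("@SQ\tSN:%s\tLN:%d", "opus_syn", 1500),
    paste("r1", 0, "blood_syn", 101, 60, "100M", "*", 0, 0,
          strrep("A", 100), "*", "NM:i:0", "AS:i:100", sep = "\t"),
    paste("r1", 256, "opus_syn", 201, 60, "100M", "*", 0, 0,
          strrep("A", 100), "*", "NM:i:0", "AS:i:100", sep = "\t")), f2)
  both <- ingest_sam(f2, lib)
  expect_equal(nrow(both), 2)
  expect_true(all(both$is_ambiguous))
  expect_equal(both$weight, c(0.5, 0.5))

  # unknown reference errors by name
  f3 <- tempfile(fileext = ".sam")
  writeLines(c("@SQ\tSN:unknown_fam\tLN:100"), f3)
  expect_error(ingest_sam(f3, lib), "unknown_fam")
})
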