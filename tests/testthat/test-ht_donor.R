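lib <- test_library()

test_that("repeat tables round-trip with coordinate conversion", {
  hits <- data.frame(
    assembly_id = "asm", contig = c("ctg1", "ctg1"),
    start = c(1000L, 5000L), end = c(1500L, 6200L),
    strand = c("+", "-"), family_id = c("blood_syn", "opus_syn"),
    score = c(450, 900), divergence = c(0.052, 0.104),
    qstart = c(0L, 100L), qend = c(500L, 1300L),
    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".out")
  write_repeat_table(hits, f)
  got <- parse_repeat_table(f, assembly_id = "asm")
  expect_equal(got[, names(hits)], hits, tolerance = 1e-6)

  # 1-based inclusive begin/end become 0-based half-open
  expect_equal(got$start[1], 1000)
  expect_equal(got$end[1], 1500)
  # 'C' orientation is strand '-'
  expect_equal(got$strand[2], "-")

  writeLines(c("h", "h", "", "1 2 3"), f)
  expect_error(parse_repeat_table(f), "line 4")
})

test_that("planted copies are found with the right divergence", {
  cons <- lib$families$blood_syn$sequence
  set.seed(41)
  asm <- c(ctg = paste0(rand_dna(2000), cons, rand_dna(2000)))
  hits <- find_hits(asm, lib, min_score = 100)
  hb <- hits[hits$family_id == "blood_syn", ]
  expect_equal(nrow(hb), 1)
  expect_equal(hb$divergence, 0)
  expect_equal(hb$score, 1500)
  expect_equal(hb$start, 2000)
  expect_equal(hb$end, 3500)

  # 10% diverged copy
  chars <- strsplit(cons, "")[[1]]
  at <- sample(1500, 150)
  for (i in at) chars[i] <- setdiff(c("A", "C", "G", "T"), chars[i])[1]
  asm2 <- c(ctg = paste0(rand_dna(1000), paste(chars, collapse = ""),
                         rand_dna(1000)))
  h2 <- defragment(find_hits(asm2, lib, min_score = 100), 100)
  h2 <- h2[h2$family_id == "blood_syn", ]
  expect_gte(nrow(h2), 1)
  expect_true(all(h2$divergence >= 0.08 & h2$divergence <= 0.12))

  # reverse-strand copy is found with consensus-oriented span
  asm3 <- c(ctg = paste0(rand_dna(500),
                         as.character(Biostrings::reverseComplement(
                           Biostrings::DNAString(cons))), rand_dna(500)))
  h3 <- find_hits(asm3, lib, min_score = 100)
  h3 <- h3[h3$family_id == "blood_syn", ]
  expect_equal(h3$strand, "-")
  expect_equal(h3$start, 500)
  expect_equal(h3$end, 2000)
  expect_equal(h3$qstart, 0)
  expect_equal(h3$qend, 1500)

  # no homology: no hits
  expect_equal(nrow(find_hits(c(ctg = rand_dna(5000)), lib,
                              min_score = 100)), 0)
})

test_that("defragmentation merges colinear fragments within the gap", {
  frag <- function(start, end, qs, qe, strand = "+")
    data.frame(assembly_id = "a", contig = "c", start = start, end = end,
               strand = strand, family_id = "f", score = end - start,
               divergence = 0.1, qstart = qs, qend = qe,
               stringsAsFactors = FALSE)
  two <- rbind(frag(0, 500, 0, 500), frag(580, 1000, 520, 940))
  m <- defragment(two, max_gap = 100)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 0)
  expect_equal(m$end, 1000)
  expect_equal(m$score, 920)
  expect_equal(m$qend, 940)

  # fragments 150 apart stay separate
  far <- rbind(frag(0, 500, 0, 500), frag(650, 1000, 520, 870))
  expect_equal(nrow(defragment(far, max_gap = 100)), 2)

  # non-colinear (tandem) fragments are not merged unless distance-only
  tandem <- rbind(frag(0, 500, 1000, 1500), frag(550, 1050, 0, 500))
  expect_equal(nrow(defragment(tandem, max_gap = 100)), 2)
  expect_equal(nrow(defragment(tandem, max_gap = 100, colinear = FALSE)), 1)

  # idempotent
  expect_equal(defragment(m, 100), m)
})

test_that("random fragmentation merges to an interval-union oracle", {
  set.seed(51)
  for (rep in 1:5) {
    # fragments of one planted copy: random colinear split
    cuts <- sort(sample(200:1300, sample(2:5, 1)))
    bounds <- cbind(c(0, cuts), c(cuts, 1500))
    gaps <- sample(0:80, nrow(bounds), replace = TRUE)
    frags <- do.call(rbind, lapply(seq_len(nrow(bounds)), function(i) {
      data.frame(assembly_id = "a", contig = "c",
                 start = bounds[i, 1] + 3000L, end = bounds[i, 2] + 3000L,
                 strand = "+", family_id = "f",
                 score = bounds[i, 2] - bounds[i, 1], divergence = 0,
                 qstart = bounds[i, 1], qend = bounds[i, 2],
                 stringsAsFactors = FALSE)
    }))
    m <- defragment(frags, max_gap = 100)
    # oracle: union of intervals closed under gap <= 100
    iv <- frags[order(frags$start), c("start", "end")]
    merged <- iv[1, ]
    for (i in seq_len(nrow(iv))[-1]) {
      if (iv$start[i] - merged$end[nrow(merged)] <= 100) {
        merged$end[nrow(merged)] <- max(merged$end[nrow(merged)], iv$end[i])
      } else merged <- rbind(merged, iv[i, ])
    }
    expect_equal(m[, c("start", "end")], merged, ignore_attr = TRUE)
  }
})

test_that("similarity is maximal for the donor and scale-invariant", {
  panel <- build_species_panel(lib, c(0, 0.1, 0.3), seed = 61)
  hits <- lapply(setNames(nm = names(panel$assemblies)), function(a)
    defragment(find_hits(panel$assemblies[[a]], lib, assembly_id = a), 100))
  sim <- similarity_scores(hits, families = names(lib$families))
  tab <- sim$table
  for (f in names(lib$families)) {
    s <- tab$s[tab$family_id == f]
    names(s) <- tab$assembly_id[tab$family_id == f]
    expect_equal(unname(s["asm_01"]), 1)       # donor self-maximum
    expect_true(all(diff(s[paste0("asm_0", 1:3)]) < 0))  # ladder decreases
  }
  expect_equal(unname(sim$best_assembly), rep("asm_01", 3))

  # scale invariance
  scaled <- lapply(hits, function(h) { h$score <- h$score * 7; h })
  sim2 <- similarity_scores(scaled, families = names(lib$families))
  expect_equal(sim2$table$s, sim$table$s)

  # assembly without hits scores 0; family without hits is flagged NA
  hits$empty <- hits$asm_01[0, ]
  sim3 <- similarity_scores(hits)
  expect_true(all(sim3$table$s[sim3$table$assembly_id == "empty"] == 0))
  sim4 <- similarity_scores(hits["asm_01"],
                            families = c(names(lib$families), "ghost"))
  expect_equal(sim4$no_hit_families, "ghost")
  expect_true(all(is.na(sim4$table$s[sim4$table$family_id == "ghost"])))
})

test_that("length-divergence structure separates recent from degraded", {
  spec <- genome_spec(20000, list(
    blood_syn = list(copy_number = 3),
    opus_syn = list(copy_number = 0,
      degraded = list(count = 5, divergence = 0.25,
                      len_range = c(300, 700)))), seed = 71)
  g <- build_genome(spec, lib)
  hits <- defragment(find_hits(setNames(g$genome, "ctg"), lib,
                               min_score = 30, xdrop = 60), 100)
  ld <- length_divergence_table(hits)
  recent <- ld[ld$family_id == "blood_syn", ]
  old <- ld[ld$family_id == "opus_syn", ]
  expect_true(all(recent$length > 1400 & recent$divergence < 0.02))
  expect_true(all(old$length < 900))
  expect_true(all(old$divergence > 0.15 & old$divergence < 0.35))
  expect_equal(nrow(length_divergence_table(hits[0, ])), 0)
})

test_that("full-length extraction respects the window and orientation", {
  cons <- lib$families$blood_syn$sequence
  set.seed(81)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cons)))
  asm <- c(ctg = paste0(rand_dna(1000), rc, rand_dna(800),
                        substr(cons, 1, 400), rand_dna(600)))
  hits <- defragment(find_hits(asm, lib, min_score = 100), 100)
  out <- extract_full_length(hits, asm, c(1400, 1600))
  expect_length(out, 1)
  expect_identical(unname(out), cons)     # '-' hit back in consensus frame
  expect_match(names(out), "ctg:1000-2500:-")
  expect_length(extract_full_length(hits, asm, c(4000, 6000)), 0)
  bad <- hits
  bad$end <- nchar(asm) + 10
  expect_error(extract_full_length(bad, asm, c(1, 1e6)), "outside")
})

test_that("LTR-LTR divergence dates insertions by d/(2r)", {
  set.seed(91)
  ltr <- rand_dna(400)
  body <- rand_dna(3000)
  same <- paste0(ltr, body, ltr)
  expect_equal(ltr_age(same, 400, 5e-9)$age_years, 0)

  # plant exactly 1% divergence between the two LTRs
  chars <- strsplit(ltr, "")[[1]]
  at <- sample(400, 4)
  for (i in at) chars[i] <- setdiff(c("A", "C", "G", "T"), chars[i])[1]
  aged <- paste0(ltr, body, paste(chars, collapse = ""))
  res <- ltr_age(aged, 400, 5e-9)
  expect_equal(res$d, 0.01)
  expect_equal(res$age_years, 1e6)
  expect_error(ltr_age("ACGT", 400, 5e-9), "shorter")
})
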