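lib <- test_library()

test_that("normalization factor is the pooled mean gene coverage", {
  pl <- flat_pileup(lib, list(blood_syn = 121, opus_syn = 0,
                              te412_syn = 0),
                    list(rhi_syn = 12, tj_syn = 12, rpl32_syn = 12))
  expect_equal(normalization_factor(pl, lib), 12)
  pl2 <- flat_pileup(lib, list(blood_syn = 0, opus_syn = 0, te412_syn = 0),
                     list(rhi_syn = 10, tj_syn = 12, rpl32_syn = 14))
  expect_equal(normalization_factor(pl2, lib), 12)
  pl3 <- flat_pileup(lib, list(blood_syn = 1, opus_syn = 0, te412_syn = 0),
                     list(rhi_syn = 0, tj_syn = 0, rpl32_syn = 0))
  expect_error(normalization_factor(pl3, lib), "undefined")
})

test_that("copy number reproduces the worked coverage ratio", {
  pl <- flat_pileup(lib, list(blood_syn = 121, opus_syn = 0,
                              te412_syn = 0),
                    list(rhi_syn = 12, tj_syn = 12, rpl32_syn = 12))
  nf <- normalization_factor(pl, lib)
  call <- copy_number(pl, lib$families$blood_syn, nf, lib)
  expect_equal(call$copies, 121 / 12)
  expect_equal(round(call$copies, 1), 10.1)
  zero <- copy_number(pl, lib$families$te412_syn, nf, lib)
  expect_equal(zero$copies, 0)
  expect_equal(zero$breadth, 0)
  expect_equal(zero$status, "absent")
})

test_that("poly-A curbing replaces run coverage by the flank median", {
  pl <- flat_pileup(lib, list(blood_syn = 0, opus_syn = 10,
                              te412_syn = 0),
                    list(rhi_syn = 10, tj_syn = 10, rpl32_syn = 10))
  # inflate coverage inside the poly-A tract of opus_syn ([1480,1500))
  runs <- lib$homopolymer_runs$opus_syn
  expect_equal(nrow(runs), 1)
  pl$families$opus_syn$counts[(runs[1, "start"] + 1):runs[1, "end"],
                              "cov_u"] <- 500
  curbed <- copy_number(pl, lib$families$opus_syn, 10, lib,
                        curb_polyA = TRUE)
  expect_equal(curbed$copies, 1)
  uncurbed <- copy_number(pl, lib$families$opus_syn, 10, lib,
                          curb_polyA = FALSE)
  expect_gt(uncurbed$copies, 1.5)
})

test_that("SNP calling reports the worked 15G/5A frequency", {
  pl <- flat_pileup(lib, list(blood_syn = 0, opus_syn = 0, te412_syn = 0),
                    list(rhi_syn = 1, tj_syn = 1, rpl32_syn = 1))
  len <- lib$families$blood_syn$length
  counts <- cbind(cov_u = 0, A = 0, C = 0, G = 0, T = 0)[rep(1, len), ]
  counts <- cbind(counts, cov_a = 0, ins = 0, del = 0)
  # site 100 (0-based): 15 G, 5 A on a ref-A site
  ref <- substr(lib$families$blood_syn$sequence, 101, 101)
  counts[101, "G"] <- if (ref == "G") 5 else 15
  counts[101, "A"] <- if (ref == "G") 15 else 5
  counts[101, "cov_u"] <- 20
  pl$families$blood_syn$counts <- counts
  snps <- call_snps(pl, lib$families$blood_syn, min_cov = 10,
                    min_freq = 0.1)
  major <- snps[which.max(snps$freq), ]
  expect_equal(major$freq, 0.75)
  expect_equal(major$pos, 100)
  # expected carriers: frequency x insertions
  expect_equal(0.6 * 10, 6)
  # below-coverage sites are not reported
  snps2 <- call_snps(pl, lib$families$blood_syn, min_cov = 30,
                     min_freq = 0.1)
  expect_equal(nrow(snps2), 0)
})

test_that("SNP frequencies converge to lineage truth with coverage", {
  snp <- data.frame(pos = 700, alt = "C", freq = 0.6)
  err <- vapply(c(10, 40), function(cov) {
    sam <- make_sample(lib, list(blood_syn = 10), seed = 300 + cov,
                       coverage = cov, backbone = 15000,
                       lineage_snps = list(blood_syn = snp))
    truth <- sam$truth$snp_freq$freq
    called <- call_snps(sam$pileup, lib$families$blood_syn)
    got <- called$freq[called$pos == 700 & called$alt == "C"]
    abs(got - truth)
  }, 0)
  expect_lt(err[2], 0.05)
})

test_that("rpm is conserved and definitional", {
  aln <- data.frame(
    read_id = c("a", "b", "c", "c"),
    family_id = c("blood_syn", "rhi_syn", "blood_syn", "opus_syn"),
    weight = c(1, 1, 0.5, 0.5), stringsAsFactors = FALSE)
  r <- rpm_abundance(aln)
  expect_equal(sum(r), 1e6)
  expect_equal(unname(r["blood_syn"]), 1.5e6 / 3)
  expect_error(rpm_abundance(aln[0, ]), "no mapped reads")
})

test_that("fold enrichment follows the pseudocount formula", {
  a <- data.frame(family_id = c("x", "y"), copies = c(2, 1))
  b <- data.frame(family_id = c("x", "y"), copies = c(20, 1))
  expect_equal(unname(fold_enrichment(a, b, pseudocount = 0)["x"]), 10)
  expect_equal(unname(fold_enrichment(a, b, pseudocount = 0)["y"]), 1)
  inv <- fold_enrichment(data.frame(family_id = "x", copies = 0),
                         data.frame(family_id = "x", copies = 15),
                         pseudocount = 0.1)
  expect_gt(unname(inv), 50)
})

test_that("classification is threshold-driven and monotone in divergence", {
  base <- data.frame(copies = 5, breadth = 0.95,
                     mean_read_divergence = 0.01)
  expect_equal(classify_family(transform(base, copies = 0.05)), "absent")
  expect_equal(classify_family(base), "recent")
  expect_equal(classify_family(transform(base, breadth = 0.5)),
               "degraded_only")
  # increasing divergence never moves degraded_only -> recent
  prev <- "recent"
  for (d in seq(0, 0.3, by = 0.02)) {
    st <- classify_family(transform(base, mean_read_divergence = d))
    if (prev == "degraded_only") expect_equal(st, "degraded_only")
    prev <- st
  }
})

test_that("synthetic samples classify by their planted copy structure", {
  # only moderately diverged fragments: patchy, high-divergence signal
  old <- make_sample(lib, list(blood_syn = 0), seed = 120, coverage = 20,
                     backbone = 15000,
                     degraded = list(blood_syn = list(
                       count = 10, divergence = 0.15,
                       len_range = c(500, 900))))
  nf <- normalization_factor(old$pileup, lib)
  call_old <- copy_number(old$pileup, lib$families$blood_syn, nf, lib)
  expect_equal(call_old$status, "degraded_only")
  expect_gt(call_old$mean_read_divergence, 0.05)

  # 15 full-length near-consensus copies: a recent invasion
  rec <- make_sample(lib, list(blood_syn = 15), seed = 121, coverage = 20,
                     backbone = 15000)
  nf2 <- normalization_factor(rec$pileup, lib)
  call_rec <- copy_number(rec$pileup, lib$families$blood_syn, nf2, lib)
  expect_equal(call_rec$status, "recent")
  expect_gt(call_rec$breadth, 0.95)
})

test_that("timeline brackets follow the year structure of the calls", {
  calls <- expand.grid(sample_id = sprintf("s%02d", 1:6),
                       family_id = "blood_syn",
                       stringsAsFactors = FALSE)
  meta <- data.frame(sample_id = sprintf("s%02d", 1:6),
                     year = c(1800, 1850, 1850, 1933, 1933, 1967))
  calls$status <- ifelse(meta$year[match(calls$sample_id,
                                         meta$sample_id)] >= 1933,
                         "recent", "degraded_only")
  tl <- build_timeline(calls, meta)
  expect_equal(tl$t_low, 1850)
  expect_equal(tl$t_high, 1933)

  calls$status <- "recent"
  tl2 <- build_timeline(calls, meta)
  expect_equal(tl2$t_low, -Inf)
  expect_equal(tl2$t_high, 1800)

  calls$status <- "absent"
  tl3 <- build_timeline(calls, meta)
  expect_true(is.na(tl3$t_low) && is.na(tl3$t_high))

  expect_error(build_timeline(transform(calls, sample_id = "zz"), meta),
               "zz")
})

test_that("group comparison matches the rank-sum contract", {
  res <- compare_groups(c(0, 0, 0.1), c(12, 14, 15))
  expect_lte(res$p_value, 0.1)
  expect_equal(compare_groups(c(1, 1), c(1, 1))$p_value, 1)
  # complete separation 9 vs 16 is highly significant
  res2 <- compare_groups(rnorm(9), rnorm(16) + 100)
  expect_lt(res2$p_value, 1e-4)
})
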