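test_that("variant intent follows the edit-distance rule, including partial MNV incorporation", {
  expect_equal(classify_variant_intent("AAAA", "AAGA",
                                       list(offset = 2L, ref = "A",
                                            alt = "G")), "intended")
  expect_equal(classify_variant_intent("AAAA", "AAGA",
                                       list(offset = 0L, ref = "A",
                                            alt = "C")), "unintended")
  # partial incorporation of a two-variant design: distance 2 -> 1
  expect_equal(classify_variant_intent("AAAAAA", "ACAAGA",
                                       list(offset = 1L, ref = "A",
                                            alt = "C")), "intended")
  expect_error(classify_variant_intent("AAAA", "AAGA",
                                       list(offset = 1L, ref = "C",
                                            alt = "G")), "ref allele")
})

test_that("every incorporated subset of designed variants is classified intended", {
  wt <- random_dna(60, seed = 800)
  vars <- data.frame(offset = c(10L, 25L, 40L), ref = NA, alt = NA)
  vars$ref <- substring(wt, vars$offset + 1L, vars$offset + 1L)
  vars$alt <- vapply(vars$ref, function(b) {
    setdiff(c("A", "C", "G", "T"), b)[1]
  }, character(1))
  donor <- wt
  for (i in 1:3) substr(donor, vars$offset[i] + 1L,
                        vars$offset[i] + 1L) <- vars$alt[i]
  for (mask in 0:7) {  # every subset of incorporated variants
    applied <- wt
    subset_idx <- which(bitwAnd(mask, 2^(0:2)) > 0)
    for (i in subset_idx) substr(applied, vars$offset[i] + 1L,
                                 vars$offset[i] + 1L) <- vars$alt[i]
    remaining <- setdiff(1:3, subset_idx)
    for (i in remaining) {
      expect_equal(classify_variant_intent(applied, donor,
                                           as.list(vars[i, ])), "intended",
                   label = sprintf("mask %d var %d", mask, i))
    }
  }
})

test_that("median-of-ratios normalization matches hand computation and scale invariance", {
  m <- matrix(c(10, 20, 30, 40, 50,
                20, 40, 60, 80, 100,
                40, 80, 120, 160, 200), ncol = 3)
  res <- normalize_library_size(m)
  expect_equal(unname(res$size_factors), c(0.5, 1, 2), tolerance = 1e-12)
  expect_equal(res$normalized[, 1], res$normalized[, 2])
  expect_equal(res$normalized[, 2], res$normalized[, 3])

  # two identical samples
  a <- matrix(c(5, 9, 14, 5, 9, 14), ncol = 2)
  ra <- normalize_library_size(a)
  expect_equal(ra$size_factors[1], ra$size_factors[2])

  # doubling one sample doubles its factor, normalized values agree
  b <- cbind(a[, 1], a[, 1] * 2)
  rb <- normalize_library_size(b)
  expect_equal(unname(rb$size_factors[2] / rb$size_factors[1]), 2)
  expect_equal(rb$normalized[, 1], rb$normalized[, 2])

  # zero-geometric-mean bins are excluded from the median
  z <- rbind(c(0, 100, 0), m[2:5, ])
  expect_equal(normalize_library_size(z)$size_factors,
               normalize_library_size(m[2:5, ])$size_factors)
  expect_error(normalize_library_size(cbind(c(0, 0), c(1, 2))), "all-zero")
})

test_that("size factors agree with the DESeq2 median-of-ratios oracle", {
  set.seed(810)
  m <- matrix(rnbinom(200, mu = 50, size = 5) + 1L, nrow = 40)
  ours <- normalize_library_size(m)$size_factors
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("rank-of-rank matches the double-ranking oracle, including ties", {
  # constant matrix: tie conventions
  cm <- rank_of_rank(matrix(5, 8, 3))
  expect_true(all(cm$rank == (8 + 1) / (2 * 8)))
  expect_true(all(cm$ror == (3 + 1) / (2 * 3)))

  withr::with_seed(820, {
    for (t in 1:6) {
      n <- sample(3:12, 1); m <- sample(2:12, 1)
      x <- matrix(sample(0:4, n * m, replace = TRUE), n, m)  # tie-heavy
      got <- rank_of_rank(x)
      ref <- ror_oracle(x)
      expect_equal(unname(got$rank), ref$rank)
      expect_equal(unname(got$ror), ref$ror)
    }
  })

  # a halved bin attains the minimum RoR in its row
  x <- matrix(100, 10, 5) + withr::with_seed(821,
    matrix(sample(0:1, 50, TRUE), 10, 5))
  x[4, 2] <- 50
  ror <- rank_of_rank(x)$ror
  expect_equal(which.min(ror[4, ]), 2L)

  # permuting samples permutes RoR columns identically
  perm <- c(3, 1, 4, 5, 2)
  expect_equal(rank_of_rank(x[, perm])$ror, ror[, perm],
               ignore_attr = TRUE)
})

test_that("copy-loss flags follow the RoR threshold and merge into segments", {
  expect_equal(nrow(flag_copy_loss(rank_of_rank(matrix(7, 20, 3)))$cells),
               0L)
  planted <- data.frame(bin = 91:100, sample = 7, factor = 0.05)
  counts <- simulate_coverage(200, 20, depth = 40, planted = planted,
                              seed = 31)
  cmx <- rank_of_rank(normalize_library_size(counts)$normalized)
  # planted cells sit at the bottom of the cross-sample rank distribution;
  # at 20 samples the 0.1 threshold equals rank 2 of 20, so a competitor
  # sample's naturally bottom-ranked bin can displace individual cells
  expect_true(all(cmx$ror[91:100, 7] <= 0.2))
  expect_gte(sum(cmx$ror[91:100, 7] < 0.1), 5)
  # a detected loss segment overlaps the planted run for that sample
  segs <- detect_loss_segments(cmx)
  seg7 <- segs[segs$sample == 7, ]
  expect_true(any(seg7$start_bin <= 100 & seg7$end_bin >= 91))
  # at a cohort size where rank resolution allows it, all 10 bins flag
  counts2 <- simulate_coverage(200, 400, depth = 40,
                               planted = data.frame(bin = 91:100,
                                                    sample = 7,
                                                    factor = 0.05),
                               seed = 32)
  cmx2 <- rank_of_rank(normalize_library_size(counts2)$normalized)
  hit2 <- flag_copy_loss(cmx2)$cells
  expect_true(all(91:100 %in% hit2$bin[hit2$sample == 7]))
  # threshold 0 flags nothing
  expect_equal(nrow(flag_copy_loss(cmx, threshold = 0)$cells), 0L)
})

test_that("clone outcome rules rank signatures as documented", {
  design <- list(wildtype_seq = "ACGTACGTAC", donor_seq = "ACGTACTTAC")
  intended <- data.frame(offset = 6L, ref = "G", alt = "T")
  none <- data.frame(offset = integer(), ref = character(),
                     alt = character())
  indel <- data.frame(offset = 3L, ref = "TA", alt = "T")

  expect_equal(call_clone_outcome(intended, FALSE, design)$label, "edited")
  expect_equal(call_clone_outcome(none, FALSE, design)$label, "unedited")
  expect_equal(call_clone_outcome(indel, FALSE, design)$label, "NHEJ-indel")
  expect_equal(call_clone_outcome(none, TRUE, design)$label, "DEL")
  expect_equal(call_clone_outcome(none, TRUE, design,
                                  gain_elsewhere = TRUE)$label, "TRA")
  conflict <- call_clone_outcome(intended, TRUE, design)
  expect_equal(conflict$label, "SV-unclassified")
  expect_setequal(conflict$evidence, c("intended-variant", "copy-loss"))
  expect_error(call_clone_outcome(intended, FALSE, NULL), "donor design")
})

test_that("breakpoint homology scans outward to the first mismatch", {
  shared <- random_dna(25, seed = 830)
  g <- genome_assembly(c(
    c1 = paste0(random_dna(40, seed = 831), shared),
    c2 = paste0(random_dna(60, seed = 832), shared,
                random_dna(20, seed = 833))))
  expect_equal(breakpoint_homology(
    g, list(chrom = "c1", pos = 65L, side = "left"),
    list(chrom = "c2", pos = 85L, side = "left")), 25L)
  # dissimilar flanks
  expect_equal(breakpoint_homology(
    g, list(chrom = "c1", pos = 20L, side = "left"),
    list(chrom = "c2", pos = 40L, side = "left")), 0L)
  # internal mismatch at outward position 12 stops the extension at 11
  blk <- random_dna(30, seed = 834)
  blk2 <- blk
  substr(blk2, 19, 19) <- setdiff(c("A", "C", "G", "T"),
                                  substr(blk, 19, 19))[1]
  g2 <- genome_assembly(c(c1 = paste0(random_dna(10, seed = 835), blk),
                          c2 = paste0(random_dna(10, seed = 836), blk2)))
  expect_equal(breakpoint_homology(
    g2, list(chrom = "c1", pos = 40L, side = "left"),
    list(chrom = "c2", pos = 40L, side = "left")), 11L)
  expect_error(breakpoint_homology(
    g2, list(chrom = "c1", pos = 99L, side = "left"),
    list(chrom = "c2", pos = 40L, side = "left")), "bounds")
})

test_that("background-variant filters apply in the documented order", {
  g <- matrix(NA_real_, nrow = 5, ncol = 4,
              dimnames = list(paste0("L", 1:5), paste0("c", 1:4)))
  g["L1", ] <- c(1, 1, 0, 0)    # shared across different gRNAs -> dropped
  g["L2", ] <- c(1, 0, 0, 0)    # private -> retained
  g["L3", ] <- c(NA, NA, NA, 1) # 75% missing -> dropped by locus filter
  g["L4", ] <- c(0, 1, 1, 0)    # shared within one gRNA -> retained
  g["L5", ] <- c(0, 0, 0, 1)    # private -> retained
  grnas <- c(c1 = "AAA", c2 = "CCC", c3 = "CCC", c4 = "GGG")
  res <- filter_background_variants(g, grnas)
  expect_setequal(res$kept_loci, c("L2", "L4", "L5"))
  expect_setequal(res$kept_samples, c("c1", "c2", "c3", "c4"))

  # a sample missing most loci is dropped after the locus filter
  g2 <- g
  g2["L3", ] <- c(0, 0, 0, 1)
  g2[, "c2"] <- NA
  g2["L1", "c2"] <- 1
  res2 <- filter_background_variants(g2, grnas)
  expect_false("c2" %in% res2$kept_samples)
})

test_that("bulk coverage drop and allele partitioning follow the stated arithmetic", {
  region <- list(start = 0L, end = 5000L)
  ctrl <- matrix(50, 5000, 3)
  edited <- rep(50, 5000)
  edited[2401:2600] <- 20  # 40% of control depth at the target
  est <- bulk_sv_fraction(edited, ctrl, region, pam_pos = 2500L)
  # window geometry: 5000/25 = 200 bp windows, 5000/50 = 100 bp steps
  expect_equal(nrow(est$windows), (5000 - 200) / 100 + 1)
  expect_equal(est$windows$end[1] - est$windows$start[1], 200L)
  # mean-normalization rescales both samples; the planted drop survives it
  expect_equal(est$sv_fraction,
               1 - (20 / mean(edited)) / (50 / 50), tolerance = 1e-10)
  expect_gt(est$sv_fraction, 0.55)

  flat <- bulk_sv_fraction(rep(50, 5000), ctrl, region, pam_pos = 2500L)
  expect_equal(flat$sv_fraction, 0)
  expect_true(all(abs(flat$windows$delta) < 1e-12))

  est$sv_fraction <- 0.5
  p <- partition_alleles(est, 3, 1)
  expect_equal(p$edited_fraction, 0.375)
  expect_equal(p$unedited_fraction, 0.125)
  expect_equal(p$sv_fraction + p$edited_fraction + p$unedited_fraction, 1)

  est$sv_fraction <- 0
  expect_equal(partition_alleles(est, 7, 0)$edited_fraction, 1)
  est$sv_fraction <- 1
  p1 <- partition_alleles(est, 2, 5)
  expect_equal(p1$edited_fraction, 0)
  expect_equal(p1$unedited_fraction, 0)
  expect_error(partition_alleles(est, 0, 0), "both zero")
})
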