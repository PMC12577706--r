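test_that("local SUS lengths match brute-force occurrence counting", {
  expect_equal(sus_lengths_local("ACGT"), c(1L, 1L, 1L, 1L))
  expect_equal(sus_lengths_local("ACACAC")[1], 5L)   # "ACACA" is unique
  expect_equal(sus_lengths_local("AAAA")[2], 4L)     # sentinel: suffix+1
  expect_error(sus_lengths_local(""), "non-empty")

  for (seed in 1:8) {
    n <- sample(c(20, 60, 150, 400), 1)
    s <- random_dna(n, seed = 200 + seed,
                    prob = c(0.4, 0.1, 0.1, 0.4))  # AT-rich: many repeats
    expect_equal(as.integer(sus_lengths_local(s)), sus_local_oracle(s),
                 label = paste("seed", seed))
  }
  # highly repetitive structures
  expect_equal(as.integer(sus_lengths_local(strrep("ACG", 30))),
               sus_local_oracle(strrep("ACG", 30)))
})

test_that("global SUS lengths match the occurrence-counting oracle", {
  # window duplicated verbatim on another chromosome
  win_seq <- random_dna(60, seed = 301)
  g <- genome_assembly(c(
    c1 = paste0(random_dna(100, seed = 302), win_seq,
                random_dna(100, seed = 303)),
    c2 = paste0(random_dna(50, seed = 304), win_seq,
                random_dna(50, seed = 305))))
  iv <- list(chrom = "c1", start = 100L, end = 160L)
  sus <- sus_lengths_global(iv, g)
  rest <- c(substr(g$seq["c1"], 1, 100),
            substr(g$seq["c1"], 161, nchar(g$seq["c1"])), g$seq[["c2"]])
  rest <- c(rest, revcomp(rest))
  expect_equal(as.integer(sus), sus_global_oracle(win_seq, rest))
  # every position's suffix occurs verbatim elsewhere -> all sentinels
  expect_equal(as.integer(sus), seq(61, by = -1, length.out = 60))

  # genome-unique 20-mers bound the values
  gu <- genome_assembly(c(c1 = random_dna(4000, seed = 310)))
  ivu <- list(chrom = "c1", start = 2000L, end = 2100L)
  expect_true(all(sus_lengths_global(ivu, gu) <= 20))

  # single-chromosome genome equal to the window: no external sequence
  gw <- genome_assembly(c(c1 = win_seq))
  expect_equal(sus_lengths_global(list(chrom = "c1", start = 0L, end = 60L),
                                  gw), rep(1L, 60))

  # randomized agreement including reverse-complement occurrences
  for (seed in 1:4) {
    s1 <- random_dna(500, seed = 320 + seed, prob = c(0.4, 0.1, 0.1, 0.4))
    s2 <- paste0(random_dna(200, seed = 340 + seed),
                 revcomp(substr(s1, 240, 280)),
                 random_dna(100, seed = 360 + seed))
    g2 <- genome_assembly(c(c1 = s1, c2 = s2))
    iv2 <- list(chrom = "c1", start = 200L, end = 320L)
    rest2 <- c(substr(s1, 1, 200), substr(s1, 321, 500), s2)
    rest2 <- c(rest2, revcomp(rest2))
    expect_equal(as.integer(sus_lengths_global(iv2, g2)),
                 sus_global_oracle(substr(s1, 201, 320), rest2))
  }
})

test_that("local repetitiveness index is null-calibrated and detects tandem arrays", {
  w <- random_dna(500, seed = 401)
  expect_lt(abs(index_local_repetitiveness(w, seed = 7)), 0.2)

  unit <- random_dna(50, seed = 402)
  arr <- strrep(unit, 10)
  expect_gt(index_local_repetitiveness(arr, seed = 7), 0.5)

  # monotonicity: inserting a second copy of a 100-mer never decreases it
  block <- random_dna(100, seed = 403)
  base <- paste0(random_dna(150, seed = 404), block,
                 random_dna(250, seed = 405))
  with_copy <- paste0(random_dna(150, seed = 404), block,
                      random_dna(50, seed = 406), block,
                      random_dna(100, seed = 407))
  expect_gte(index_local_repetitiveness(with_copy, seed = 9),
             index_local_repetitiveness(base, seed = 9))

  expect_error(index_local_repetitiveness("ACGTACG"), "shorter")
})

test_that("local index is invariant under reverse complement", {
  for (seed in 1:3) {
    s <- paste0(strrep(random_dna(40, seed = 410 + seed), 3),
                random_dna(200, seed = 420 + seed))
    a <- index_local_repetitiveness(s, seed = 11)
    b <- index_local_repetitiveness(revcomp(s), seed = 11)
    expect_lt(abs(a - b), 0.25)
  }
})

test_that("global repetitiveness index responds to planted distal copies", {
  backbone <- random_dna(3000, seed = 501)
  iv <- list(chrom = "c1", start = 1400L, end = 1600L)
  g0 <- genome_assembly(c(c1 = backbone, c2 = random_dna(2000, seed = 502)))
  i0 <- index_global_repetitiveness(iv, g0, seed = 13)
  expect_lt(abs(i0), 0.3)

  # full second copy of the window on another chromosome
  win_seq <- substr(backbone, 1401, 1600)
  g1 <- genome_assembly(c(c1 = backbone,
                          c2 = paste0(random_dna(900, seed = 503), win_seq,
                                      random_dna(900, seed = 504))))
  i1 <- index_global_repetitiveness(iv, g1, seed = 13)
  expect_gt(i1, i0)

  # monotone in the length of the planted shared block
  vals <- vapply(c(0L, 100L, 200L), function(L) {
    shared <- if (L > 0) substr(backbone, 1451, 1450 + L) else ""
    gg <- genome_assembly(c(c1 = backbone,
                            c2 = paste0(random_dna(800, seed = 505), shared,
                                        random_dna(800, seed = 506))))
    index_global_repetitiveness(iv, gg, seed = 13)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("tandem arm homology matches exhaustive search and excludes inverted repeats", {
  g <- genome_assembly(c(c1 = strrep("ACGTACGT", 2)))
  expect_equal(tandem_repeat_length(data.frame(chrom = "c1", pam_pos = 8L),
                                    g, 8L), 8L)
  g2 <- genome_assembly(c(c1 = "AAAATTTTGGGGCCCC"))
  expect_equal(tandem_repeat_length(data.frame(chrom = "c1", pam_pos = 8L),
                                    g2, 8L), 1L)
  # exact inverted repeat must not count as tandem homology
  g3 <- genome_assembly(c(c1 = "AAACCCGGGTTT"))
  expect_lte(tandem_repeat_length(data.frame(chrom = "c1", pam_pos = 6L),
                                  g3, 6L), 1L)

  for (seed in 1:10) {
    l <- random_dna(sample(4:18, 1), seed = 600 + seed)
    r <- random_dna(sample(4:18, 1), seed = 630 + seed)
    g4 <- genome_assembly(c(c1 = paste0(l, r)))
    site <- data.frame(chrom = "c1", pam_pos = nchar(l))
    for (k in 0:2) {
      expect_equal(
        tandem_repeat_length(site, g4, max(nchar(l), nchar(r)),
                             max_mismatch = k),
        tandem_oracle(l, r, k), label = paste(l, r, k))
    }
  }

  # monotone in arm length and mismatch allowance
  s <- random_dna(2000, seed = 650)
  gm <- genome_assembly(c(c1 = s))
  site <- data.frame(chrom = "c1", pam_pos = 1000L)
  by_arm <- vapply(c(25L, 50L, 250L, 500L), function(a) {
    tandem_repeat_length(site, gm, a)
  }, integer(1))
  expect_true(all(diff(by_arm) >= 0))
  expect_gte(tandem_repeat_length(site, gm, 250L, max_mismatch = 2),
             tandem_repeat_length(site, gm, 250L, max_mismatch = 1))
})

test_that("site profiles populate the full gradient and clip at chromosome ends", {
  sim <- small_sim()
  sites <- enumerate_pam_sites(sim$genome)

  # boundary site: all windows clipped but profile complete
  edge <- sites[sites$pam_pos < 300 & sites$chrom == "chrI", ][1, ]
  pr <- profile_site(edge, sim$genome, seed = 3)
  expect_named(pr$i_lr, as.character(REPEAT_WINDOW_SIZES))
  expect_named(pr$i_gr, as.character(REPEAT_WINDOW_SIZES))
  expect_named(pr$tandem_len, as.character(TANDEM_ARM_SIZES))
  expect_true(all(is.finite(pr$i_lr)))
  expect_true(any(pr$clipped))
  expect_true(all(diff(pr$tandem_len) >= 0))

  # batched computation equals the single-window reference implementation
  mid <- sites[sites$chrom == "chrII" & sites$pam_pos > 3900 &
                 sites$pam_pos < 4100, ][1, ]
  pr2 <- profile_site(mid, sim$genome, seed = 5)
  n <- nchar(sim$genome$seq[["chrII"]])
  for (k in seq_along(REPEAT_WINDOW_SIZES)) {
    w <- REPEAT_WINDOW_SIZES[k]
    iv <- list(chrom = "chrII",
               start = max(0L, mid$pam_pos - w %/% 2L),
               end = min(n, mid$pam_pos + (w - w %/% 2L)))
    expect_equal(pr2$i_gr[[k]],
                 index_global_repetitiveness(iv, sim$genome,
                                             seed = 5 + 1000L + k))
  }

  # a site inside the tandem array scores higher i_lr(500) than a distant one
  inside <- sites[sites$chrom == "chrI" & sites$pam_pos > 2150 &
                    sites$pam_pos < 2450, ][1, ]
  outside <- sites[sites$chrom == "chrII" & sites$pam_pos > 6000 &
                     sites$pam_pos < 6500, ][1, ]
  pin <- profile_site(inside, sim$genome, seed = 8)
  pout <- profile_site(outside, sim$genome, seed = 8)
  expect_gt(pin$i_lr[["500"]], pout$i_lr[["500"]])
})
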