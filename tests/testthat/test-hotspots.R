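mk_track <- function(pam_pos, score, chrom = "chrI",
                     strand = NULL) {
  n <- length(pam_pos)
  if (is.null(strand)) strand <- rep("+", n)
  t <- data.frame(chrom = chrom, pam_pos = as.integer(pam_pos),
                  strand = strand, score_sv = score, score_del = score,
                  score_tra = score, score_unedit = score)
  class(t) <- c("score_track", "data.frame")
  t
}

test_that("hotspot clustering follows the three-step rule on worked fixtures", {
  # 12 consecutive PAMs above threshold form one hotspot
  t12 <- mk_track(seq(1000, by = 10, length.out = 12), 0.2)
  h12 <- cluster_sv_hotspots(t12)
  expect_equal(nrow(h12), 1L)
  expect_equal(h12$n_sites, 12L)
  expect_equal(h12$start, 1000L)
  expect_equal(h12$end, 1110L)

  # 9 consecutive signals are not enough
  t9 <- mk_track(seq(1000, by = 10, length.out = 9), 0.2)
  expect_equal(nrow(cluster_sv_hotspots(t9)), 0L)

  # two 10-site runs, one below-threshold PAM between, 150-bp gap: merged
  pams <- c(seq(1000, by = 10, length.out = 10), 1120,
            seq(1240, by = 10, length.out = 10))
  scores <- c(rep(0.3, 10), 0.05, rep(0.25, 10))
  tm <- mk_track(pams, scores)
  hm <- cluster_sv_hotspots(tm)
  expect_equal(nrow(hm), 1L)
  expect_equal(hm$n_sites, 20L)
  expect_equal(c(hm$start, hm$end), c(1000L, 1330L))

  # runs broken by a below-threshold PAM and separated by >200 bp stay split
  pams2 <- c(seq(1000, by = 10, length.out = 10), 1200,
             seq(1340, by = 10, length.out = 10))
  ts <- mk_track(pams2, c(rep(0.3, 10), 0.02, rep(0.3, 10)))
  expect_equal(nrow(cluster_sv_hotspots(ts)), 2L)
  # without an intervening PAM nothing breaks the run: one hotspot
  ts2 <- mk_track(pams2[-11], rep(0.3, 20))
  expect_equal(nrow(cluster_sv_hotspots(ts2)), 1L)

  # a below-threshold PAM inside a run breaks it
  pams3 <- seq(1000, by = 10, length.out = 19)
  sc3 <- rep(0.3, 19); sc3[10] <- 0.1
  expect_equal(nrow(cluster_sv_hotspots(mk_track(pams3, sc3))), 0L)
})

test_that("hotspot clustering is idempotent and strand-agnostic", {
  withr::with_seed(61, {
    pams <- sort(sample(1000:6000, 80))
    scores <- runif(80, 0, 0.14)
    scores[20:45] <- runif(26, 0.2, 0.9)
    strands <- sample(c("+", "-"), 80, TRUE)
  })
  tr <- mk_track(pams, scores, strand = strands)
  h1 <- cluster_sv_hotspots(tr)
  # restricting to members and re-clustering returns the same spans
  members <- tr[tr$score_sv > 0.15, ]
  h2 <- cluster_sv_hotspots(members)
  expect_equal(h1[, c("chrom", "start", "end", "n_sites")],
               h2[, c("chrom", "start", "end", "n_sites")])
  # strand labels do not matter
  tr_flip <- tr
  tr_flip$strand <- ifelse(tr$strand == "+", "-", "+")
  h3 <- cluster_sv_hotspots(tr_flip)
  expect_equal(h1$start, h3$start)
  expect_equal(h1$n_sites, h3$n_sites)
})

test_that("DTER calls apply per-outcome thresholds and report fractions", {
  tr <- mk_track(seq(100, by = 50, length.out = 10),
                 c(0, 0, 0.1, 0.2, 0.3, 0.16, 0.05, 0.9, 0.12, 0.14))
  tr$score_unedit <- c(0.3, 0.2, 0.26, 0, 0, 0, 0, 0, 0, 0)
  d <- call_dters(tr)
  expect_equal(nrow(d$sites$sv), 4L)       # > 0.15
  expect_equal(nrow(d$sites$unedit), 2L)   # > 0.25
  expect_equal(unname(d$fractions["sv"]), 0.4)
  zero <- mk_track(1:5 * 100, rep(0, 5))
  dz <- call_dters(zero)
  expect_true(all(vapply(dz$sites, nrow, integer(1)) == 0L))
  # monotone: raising thresholds never grows the subsets
  d2 <- call_dters(tr, thresholds = c(sv = 0.5, del = 0.5, tra = 0.5,
                                      unedit = 0.5))
  expect_lte(nrow(d2$sites$sv), nrow(d$sites$sv))
})

test_that("loxP distances bracket sites and correlate negatively with decaying scores", {
  lox <- data.frame(chrom = "chrI", pos = c(1000L, 3500L, 4000L, 9000L))
  tr <- mk_track(c(500L, 2000L, 3700L, 6000L, 9500L), rep(0.5, 5))
  ctx <- loxp_deletion_context(tr, lox)$context
  expect_true(is.na(ctx$loxp_distance[1]))   # upstream of the first loxP
  expect_equal(ctx$loxp_distance[2], 2500)
  expect_equal(ctx$loxp_distance[3], 500)
  expect_equal(ctx$loxp_distance[4], 5000)
  expect_true(is.na(ctx$loxp_distance[5]))   # downstream of the last loxP

  # scores generated to decay with flanking distance give r < 0
  withr::with_seed(71, {
    lox2 <- data.frame(chrom = "chrI",
                       pos = sort(sample(1000:50000, 40)))
    pam <- sort(sample(1500:49000, 400))
    tr2 <- mk_track(pam, 0)
    d <- loxp_deletion_context(tr2, lox2)$context$loxp_distance
    tr2$score_del <- ifelse(is.na(d), 0.05,
                            plogis(2 - d / 400) + rnorm(400, sd = 0.05))
  })
  res <- loxp_deletion_context(tr2, lox2)
  expect_lt(res$pearson_r, -0.3)
  expect_gt(res$n, 100)
})

test_that("breakpoint bins cover a fixed +/-1050 bp geometry", {
  bp <- data.frame(chrom = "chrI", pos = 5000L)
  tr <- mk_track(c(5050L, 5051L, 5052L), c(0.5, 0.6, 0.7))
  allp <- data.frame(chrom = "chrI",
                     pam_pos = c(5050L, 5051L, 5052L, 5060L))
  b <- bin_breakpoint_scores(bp, tr, allp)
  expect_equal(nrow(b), 21L)
  expect_equal(b$offset_lo[1], -1050)
  expect_equal(b$offset_hi[21], 1050)
  filled <- which(b$n_scored > 0)
  # bins are aligned to the +/-1050 window, so +50..+52 fall in [50, 150)
  expect_equal(b$offset_lo[filled], 50)
  expect_equal(b$n_scored[filled], 3L)
  expect_equal(b$mean_score[filled], 0.6)
  # the unscored PAM at +60 contributes to the excluded fraction
  expect_equal(b$excluded_fraction[filled], 1 - 3 / 4)
  expect_true(all(is.na(b$mean_score[-filled])))

  # central enrichment when breakpoints sit in high-score regions
  withr::with_seed(81, {
    pams <- sort(sample(2000:30000, 600))
    sc <- runif(600, 0, 0.1)
    bps <- data.frame(chrom = "chrI", pos = sample(5000:25000, 10))
    for (p in bps$pos) {
      near <- abs(pams - p) < 200
      sc[near] <- sc[near] + 0.5
    }
  })
  tr2 <- mk_track(pams, sc)
  b2 <- bin_breakpoint_scores(bps, tr2, data.frame(chrom = "chrI",
                                                   pam_pos = pams))
  central <- b2$mean_score[b2$offset_lo %in% c(-150, -50, 50)]
  flank <- b2$mean_score[abs(b2$offset_lo) >= 800]
  expect_gt(min(central), max(flank, na.rm = TRUE))
})

test_that("scored tracks are sorted, bounded, and order-invariant", {
  sim <- small_sim()
  sites <- enumerate_pam_sites(sim$genome)
  sites <- assess_spacer_uniqueness(sites, sim$genome)
  sites <- sites[sites$unique &
                   sites$pam_pos > 100 &
                   sites$pam_pos < chrom_lengths(sim$genome)[sites$chrom] -
                   100, ]
  sites <- withr::with_seed(91, sites[sample(nrow(sites), 40), ])
  cfg <- feature_config(subsets = c("1", "3"), n_shuffles = 5L)
  ft <- assemble_feature_table(sites, sim$genome, config = cfg, seed = 4)
  x <- as.matrix(ft$features[, -1])
  y <- withr::with_seed(92, ft$features$i_lr_500 + rnorm(40, sd = 0.3) > 0.5)
  if (sum(y) < 3) y[order(-ft$features$i_lr_500)[1:3]] <- TRUE
  models <- list(
    sv = train_scorer(x, y, seed = 1),
    del = train_scorer(x, y, seed = 2),
    tra = train_scorer(x, y, seed = 3),
    unedit = train_scorer(x, y, seed = 4))
  trk <- score_genome(models, sites, ft)
  expect_true(all(diff(order(trk$chrom, trk$pam_pos)) > 0) ||
                !is.unsorted(trk$pam_pos[trk$chrom == trk$chrom[1]]))
  for (nm in c("score_sv", "score_del", "score_tra", "score_unedit")) {
    expect_true(all(trk[[nm]] >= 0 & trk[[nm]] <= 1))
  }
  perm <- withr::with_seed(93, sample(nrow(sites)))
  ft_perm <- list(features = ft$features[perm, ], manifest = ft$manifest)
  trk2 <- score_genome(models, sites[perm, ], ft_perm)
  expect_equal(trk, trk2)
})
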