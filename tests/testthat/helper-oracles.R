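# Independent brute-force oracles used to validate the fast implementations,
# plus small fixture builders. All fixtures are generated in code.

random_dna <- function(n, seed = NULL, prob = c(0.31, 0.19, 0.19, 0.31)) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                                  prob = prob), collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

count_occurrences <- function(pattern, text) {
  hits <- gregexpr(paste0("(?=", pattern, ")"), text, perl = TRUE)[[1]]
  if (hits[1] == -1L) 0L else length(hits)
}

# Shortest unique substring lengths by direct occurrence counting.
sus_local_oracle <- function(s) {
  n <- nchar(s)
  vapply(seq_len(n), function(i) {
    for (L in seq_len(n - i + 1L)) {
      if (count_occurrences(substr(s, i, i + L - 1L), s) == 1L) return(L)
    }
    n - i + 2L
  }, integer(1))
}

# Global variant: shortest prefix of each window suffix absent from every
# rest fragment (both strands supplied by the caller).
sus_global_oracle <- function(window, rest_fragments) {
  n <- nchar(window)
  vapply(seq_len(n), function(i) {
    for (L in seq_len(n - i + 1L)) {
      sub <- substr(window, i, i + L - 1L)
      if (!any(vapply(rest_fragments, function(r) {
        grepl(sub, r, fixed = TRUE)
      }, logical(1)))) return(L)
    }
    n - i + 2L
  }, integer(1))
}

# Exhaustive substring-pair search for the tandem arm metric.
tandem_oracle <- function(left, right, k) {
  nl <- nchar(left); nr <- nchar(right)
  la <- strsplit(left, "", fixed = TRUE)[[1]]
  ra <- strsplit(right, "", fixed = TRUE)[[1]]
  best <- 0L
  for (L in seq_len(min(nl, nr))) {
    found <- FALSE
    for (i in seq_len(nl - L + 1L)) {
      for (j in seq_len(nr - L + 1L)) {
        if (sum(la[i:(i + L - 1L)] != ra[j:(j + L - 1L)]) <= k) {
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (found) best <- L else break
  }
  best
}

# Full DP for the fitting alignment (free window flanks, full guide).
semiglobal_oracle <- function(guide, window) {
  g <- nchar(guide); w <- nchar(window)
  ga <- strsplit(guide, "", fixed = TRUE)[[1]]
  wa <- strsplit(window, "", fixed = TRUE)[[1]]
  dp <- matrix(0L, g + 1L, w + 1L)
  dp[, 1L] <- 0:g
  for (i in seq_len(g)) {
    for (j in seq_len(w)) {
      dp[i + 1L, j + 1L] <- min(dp[i, j] + (ga[i] != wa[j]),
                                dp[i, j + 1L] + 1L,
                                dp[i + 1L, j] + 1L)
    }
  }
  min(dp[g + 1L, ])
}

# Double-ranking oracle written directly from the rank formulas.
ror_oracle <- function(x) {
  n <- nrow(x); m <- ncol(x)
  R <- matrix(0, n, m)
  for (j in seq_len(m)) R[, j] <- rank(x[, j], ties.method = "average") / n
  ror <- matrix(0, n, m)
  for (i in seq_len(n)) ror[i, ] <- rank(R[i, ], ties.method = "average") / m
  list(rank = R, ror = ror)
}

# Enumerate NGG sites by regex scan, independent of the package's scanner.
pam_scan_oracle <- function(s, spacer_len = 20L) {
  n <- nchar(s)
  fwd <- integer(); rev <- integer()
  for (p in 0:(n - 1L)) {
    if (p >= spacer_len && p + 3L <= n &&
        substr(s, p + 2L, p + 3L) == "GG" &&
        !grepl("N", substr(s, p - spacer_len + 1L, p + 3L), fixed = TRUE))
      fwd <- c(fwd, p)
    if (p - 2L >= 0L && p + 1L + spacer_len <= n &&
        substr(s, p - 1L, p) == "CC" &&
        !grepl("N", substr(s, p - 1L, p + 1L + spacer_len), fixed = TRUE))
      rev <- c(rev, p)
  }
  list(fwd = fwd, rev = rev)
}

# A small two-chromosome genome with one tandem array and one dispersed
# block, used by several module tests (built once per run).
.fixture_cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    cfg <- sim_config(
      chrom_lengths = c(chrI = 8000L, chrII = 8000L),
      tandem = list(list(chrom = "chrI", pos = 2000L, unit_len = 120L,
                         copies = 5L, divergence = 0.03)),
      dispersed = list(list(block_len = 400L,
                            sites = data.frame(chrom = c("chrI", "chrII"),
                                               pos = c(5000L, 3000L)),
                            divergence = 0.02)),
      telomere_len = 300L, seed = 42L)
    .fixture_cache$sim <- simulate_genome(cfg)
  }
  .fixture_cache$sim
}
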