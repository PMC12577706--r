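# Local (I_LR) and global (I_GR) sequence-repetitiveness indices built from
# shortest-unique-substring (SUS) lengths, plus the tandem-repeat arm metric.
#
# Both indices are log2 ratios of the observed mean SUS length to its
# expectation under base-composition-preserving shuffling of the window
# (n_shuffles Monte-Carlo draws). Positive values mean the window carries
# more internal (local) or genome-wide (global) homology than its shuffled
# composition explains.

#' Default window-size gradient for repetitiveness indices (bp)
#' @export
REPEAT_WINDOW_SIZES <- c(50L, 100L, 500L, 1000L, 5000L, 10000L)

#' Default arm-size gradient for the tandem-repeat metric (bp)
#' @export
TANDEM_ARM_SIZES <- c(25L, 50L, 250L, 500L, 2500L, 5000L)

#' Per-position shortest-unique-substring lengths within a sequence
#'
#' Element `i` is the length of the shortest substring starting at position
#' `i` that occurs exactly once within `seq`. Positions whose whole suffix
#' repeats elsewhere in the sequence get the sentinel `(suffix length) + 1`
#' (the shortest absent extension), keeping values finite and monotone.
#'
#' @param seq Non-empty A/C/G/T string.
#' @return Integer vector, one value per position.
#' @export
sus_lengths_local <- function(seq) {
  stop_if_not_string(seq, "seq")
  cpp_sus_local(toupper(seq))
}

#' Shortest substring lengths unique against the rest of the genome
#'
#' For a window `[start, end)` on `chrom`, element `i` is the length of the
#' shortest substring starting at window position `i` that does not occur
#' anywhere in the genome outside the window, with both strands of the
#' remainder searched. The window interval is excised on both strands; the
#' flanks are kept as separate fragments (occurrences may not span the
#' excision). Sentinel behaviour matches [sus_lengths_local()].
#'
#' @param window_interval list(chrom=, start=, end=) in 0-based half-open
#'   coordinates.
#' @param genome A `genome_assembly`.
#' @return Integer vector of per-position lengths.
#' @export
sus_lengths_global <- function(window_interval, genome) {
  win <- genome_slice(genome, window_interval$chrom, window_interval$start,
                      window_interval$end)
  corpus <- genome_rest_corpus(genome, window_interval)
  sus_global_multi(win, corpus)[[1]]
}

# Rest-of-genome fragments (both strands) with a window excised.
genome_rest_corpus <- function(genome, window_interval) {
  frags <- character()
  for (chrom in names(genome$seq)) {
    s <- genome$seq[[chrom]]
    if (chrom == window_interval$chrom) {
      if (window_interval$start > 0)
        frags <- c(frags, substr(s, 1L, window_interval$start))
      if (window_interval$end < nchar(s))
        frags <- c(frags, substr(s, window_interval$end + 1L, nchar(s)))
    } else {
      frags <- c(frags, s)
    }
  }
  frags <- frags[nchar(frags) > 0]
  c(frags, revcomp(frags))
}

# SUS-vs-corpus for several query windows sharing one corpus.
sus_global_multi <- function(windows, corpus) {
  if (length(corpus) == 0) {
    # no external sequence: every position is vacuously unique at length 1
    return(lapply(windows, function(w) rep(1L, nchar(w))))
  }
  lapply(cpp_match_prefix(toupper(windows), toupper(corpus)),
         function(L) L + 1L)
}

#' Index of local repetitiveness (window-internal homology)
#'
#' log2 of the observed mean SUS length over the window, divided by the mean
#' of the same statistic over `n_shuffles` composition-preserving shuffles.
#'
#' @param window_seq Window sequence (>= 10 nt).
#' @param n_shuffles Number of shuffled controls (default 20).
#' @param seed RNG seed; the value is deterministic given the seed.
#' @return Numeric index; ~0 for composition-typical sequence, positive for
#'   internally repetitive windows.
#' @export
index_local_repetitiveness <- function(window_seq, n_shuffles = 20L,
                                       seed = 1L) {
  if (nchar(window_seq) < 10L) stop("window shorter than 10 nt")
  v <- with_seed(seed, cpp_sus_mean_local(toupper(window_seq), n_shuffles))
  log2(v[1] / mean(v[-1]))
}

#' Index of global repetitiveness (distal homology)
#'
#' As [index_local_repetitiveness()] but aggregating shortest substring
#' lengths unique against the rest of the genome; the shuffled controls are
#' shuffles of the window scored against the same fixed remainder.
#'
#' @inheritParams sus_lengths_global
#' @inheritParams index_local_repetitiveness
#' @return Numeric index; larger values indicate more distal homology.
#' @export
index_global_repetitiveness <- function(window_interval, genome,
                                        n_shuffles = 20L, seed = 1L) {
  win <- genome_slice(genome, window_interval$chrom, window_interval$start,
                      window_interval$end)
  if (nchar(win) < 10L) stop("window shorter than 10 nt")
  corpus <- genome_rest_corpus(genome, window_interval)
  if (length(corpus) == 0) return(0)
  v <- with_seed(seed, cpp_sus_mean_global(toupper(win), corpus, n_shuffles))
  log2(v[1] / mean(v[-1]))
}

#' Longest tandem homology between PAM-flanking arms
#'
#' Maximum length L such that some L-mer of the left arm aligns ungapped to
#' some L-mer of the right arm with at most `max_mismatch` substitutions.
#' Only same-strand matches count (inverted repeats are excluded). Arms are
#' clipped at chromosome ends.
#'
#' @param site Single-row site (chrom, pam_pos).
#' @param genome A `genome_assembly`.
#' @param arm_len Arm length in bp on each side of the PAM anchor.
#' @param max_mismatch Maximum substitutions inside the match (default 1).
#' @return Non-negative integer; 0 when either arm is empty.
#' @export
tandem_repeat_length <- function(site, genome, arm_len, max_mismatch = 1L) {
  n <- nchar(genome$seq[[site$chrom[1]]])
  p <- site$pam_pos[1]
  left <- genome_slice(genome, site$chrom[1], max(0L, p - arm_len), p)
  right <- genome_slice(genome, site$chrom[1], p, min(n, p + arm_len))
  if (nchar(left) == 0L || nchar(right) == 0L) return(0L)
  cpp_tandem_len(left, right, as.integer(max_mismatch))
}

#' Repetitiveness profile of one target site
#'
#' Computes I_LR and I_GR over the window-size gradient (windows centered at
#' the first PAM base, clipped at chromosome ends and computed on the clipped
#' window without padding) and the tandem-repeat length over the arm-size
#' gradient.
#'
#' @param site Single-row site (chrom, pam_pos, strand).
#' @param genome A `genome_assembly`.
#' @param window_sizes Window gradient (default [REPEAT_WINDOW_SIZES]).
#' @param arm_sizes Arm gradient (default [TANDEM_ARM_SIZES]).
#' @param seed RNG seed for the shuffle nulls.
#' @param n_shuffles Shuffled controls per window (default 20).
#' @return list with named numeric vectors `i_lr`, `i_gr` (one entry per
#'   window size), integer vector `tandem_len` (per arm size), and logical
#'   vector `clipped` marking windows truncated at a chromosome end.
#' @export
profile_site <- function(site, genome, window_sizes = REPEAT_WINDOW_SIZES,
                         arm_sizes = TANDEM_ARM_SIZES, seed = 1L,
                         n_shuffles = 20L) {
  chrom <- site$chrom[1]
  p <- site$pam_pos[1]
  s <- genome$seq[[chrom]]
  n <- nchar(s)
  i_lr <- i_gr <- setNames(numeric(length(window_sizes)),
                           as.character(window_sizes))
  clipped <- setNames(logical(length(window_sizes)),
                      as.character(window_sizes))
  starts <- pmax(0L, p - window_sizes %/% 2L)
  ends <- pmin(n, p + (window_sizes - window_sizes %/% 2L))
  # One rest-of-genome automaton is built with the union window excised;
  # per window size, the uncovered "ring" of the union window (padded by
  # one window length so no match can span a fragment cut) is supplied as a
  # small per-call corpus. The union of the two corpora contains exactly
  # the substrings of the genome outside that window on both strands.
  smax <- min(starts)
  emax <- max(ends)
  big <- cpp_sam_xptr(genome_rest_corpus(
    genome, list(chrom = chrom, start = smax, end = emax)))
  for (k in seq_along(window_sizes)) {
    w <- ends[k] - starts[k]
    clipped[k] <- w < window_sizes[k]
    ring <- character()
    if (starts[k] > smax)
      ring <- c(ring, substr(s, max(0L, smax - (w - 1L)) + 1L, starts[k]))
    if (ends[k] < emax)
      ring <- c(ring, substr(s, ends[k] + 1L, min(n, emax + (w - 1L))))
    ring <- c(ring, revcomp(ring))
    win <- substr(s, starts[k] + 1L, ends[k])
    i_lr[k] <- index_local_repetitiveness(win, n_shuffles = n_shuffles,
                                          seed = seed + k)
    v <- with_seed(seed + 1000L + k,
                   cpp_sus_mean_global_x(win, big, ring, n_shuffles))
    i_gr[k] <- log2(v[1] / mean(v[-1]))
  }
  tandem <- setNames(integer(length(arm_sizes)), as.character(arm_sizes))
  for (k in seq_along(arm_sizes)) {
    tandem[k] <- tandem_repeat_length(site, genome, arm_sizes[k])
  }
  list(i_lr = i_lr, i_gr = i_gr, tandem_len = tandem, clipped = clipped)
}
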