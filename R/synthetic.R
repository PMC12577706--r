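# Simulation of study-like inputs: genomes with planted repeat structure,
# outcome labels from a stated generative rule, binned coverage with planted
# copy losses, and per-clone variant observations. Every generator is a pure
# function of (config, seed).

#' Simulation configuration for a synthetic genome
#'
#' Defaults emulate a compact yeast-like genome: 38% GC background, 500-bp
#' telomeres, a 120-bp centromere at the chromosome midpoint, and planted
#' repeat elements (tandem arrays driving local repetitiveness, dispersed
#' families and subtelomeric shared blocks driving global repetitiveness).
#' Per-copy divergence keeps most 20-mers unique so planted regions remain
#' targetable, as repeat-adjacent loci are in real genomes.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param gc Background GC fraction (default 0.38).
#' @param tandem List of tandem specs: list(chrom, pos, unit_len, copies,
#'   divergence).
#' @param dispersed List of dispersed-family specs: list(block_len,
#'   sites = data.frame(chrom, pos), divergence).
#' @param subtelomeric Optional list(block_len, divergence): a shared block
#'   placed inside each chromosome's telomere-adjacent region.
#' @param telomere_len,centromere_len Annotation lengths (bp).
#' @param loxp data.frame(chrom, pos) of loxP midpoints to annotate
#'   (optional).
#' @param seed RNG seed; generation is deterministic given the config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(chrom_lengths = c(chrI = 25000L, chrII = 25000L),
                       gc = 0.38,
                       tandem = list(),
                       dispersed = list(),
                       subtelomeric = NULL,
                       telomere_len = 500L,
                       centromere_len = 120L,
                       loxp = NULL,
                       seed = 1L) {
  structure(list(chrom_lengths = chrom_lengths, gc = gc, tandem = tandem,
                 dispersed = dispersed, subtelomeric = subtelomeric,
                 telomere_len = as.integer(telomere_len),
                 centromere_len = as.integer(centromere_len),
                 loxp = loxp, seed = as.integer(seed)),
            class = "sim_config")
}

random_seq <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

diverge_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(rbinom(length(chars), 1L, rate) == 1L)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Simulate a genome with planted repeat structure
#'
#' Background sequence is i.i.d. at the configured base composition;
#' planted elements are copied exactly up to the per-copy divergence rate.
#' Telomere and centromere annotations (and loxP midpoints, if configured)
#' are emitted, and every planted interval is recorded in the truth set.
#'
#' @param config A [sim_config()].
#' @return list(genome = `genome_assembly`, truth = list(planted =
#'   data.frame(chrom, start, end, class), config = config)).
#' @export
simulate_genome <- function(config) {
  with_seed(config$seed, {
    lens <- config$chrom_lengths
    chroms <- vapply(lens, function(n) random_seq(n, config$gc), character(1))
    planted <- data.frame(chrom = character(), start = integer(),
                          end = integer(), class = character())
    put <- function(chrom, pos, block, cls) {
      n <- nchar(chroms[[chrom]])
      if (pos < 0 || pos + nchar(block) > n)
        stop("planted element out of chromosome bounds")
      substr(chroms[[chrom]], pos + 1L, pos + nchar(block)) <<- block
      planted <<- rbind(planted,
                        data.frame(chrom = chrom, start = pos,
                                   end = pos + nchar(block), class = cls))
    }
    for (sp in config$tandem) {
      unit <- random_seq(sp$unit_len, config$gc)
      div <- sp$divergence %||% 0
      block <- paste(vapply(seq_len(sp$copies), function(k) {
        diverge_seq(unit, div)
      }, character(1)), collapse = "")
      put(sp$chrom, sp$pos, block, "tandem")
    }
    for (sp in config$dispersed) {
      block <- random_seq(sp$block_len, config$gc)
      div <- sp$divergence %||% 0
      for (i in seq_len(nrow(sp$sites))) {
        put(sp$sites$chrom[i], sp$sites$pos[i], diverge_seq(block, div),
            "dispersed")
      }
    }
    if (!is.null(config$subtelomeric)) {
      block <- random_seq(config$subtelomeric$block_len, config$gc)
      div <- config$subtelomeric$divergence %||% 0
      for (chrom in names(lens)) {
        put(chrom, config$telomere_len + 100L, diverge_seq(block, div),
            "subtelomeric")
      }
    }
    # overlap check on planted intervals
    if (nrow(planted) > 1L) {
      p <- planted[order(planted$chrom, planted$start), ]
      same <- p$chrom[-1] == p$chrom[-nrow(p)]
      if (any(same & p$start[-1] < p$end[-nrow(p)]))
        stop("overlapping plant specs")
    }
    ann <- do.call(rbind, lapply(names(lens), function(chrom) {
      n <- lens[[chrom]]
      mid <- n %/% 2L
      rbind(
        data.frame(chrom = chrom, start = 0L, end = config$telomere_len,
                   name = "telomere"),
        data.frame(chrom = chrom, start = n - config$telomere_len, end = n,
                   name = "telomere"),
        data.frame(chrom = chrom, start = mid,
                   end = mid + config$centromere_len, name = "centromere"))
    }))
    if (!is.null(config$loxp)) {
      ann <- rbind(ann, data.frame(chrom = config$loxp$chrom,
                                   start = config$loxp$pos - 17L,
                                   end = config$loxp$pos + 17L,
                                   name = "loxP"))
    }
    list(genome = genome_assembly(chroms, ann),
         truth = list(planted = planted, config = config))
  })
}

#' Default parameters of the generative outcome rule
#'
#' Multinomial logits over {edited, unedited, DEL, TRA}: the edited class is
#' the reference (logit 0); the unedited logit is affine in the spacer's
#' T-homopolymer score; the DEL logit is affine in I_LR (500-bp window); the
#' TRA logit is affine in I_GR (500-bp window). The unedited sigmoid is
#' centered at a T run of 3.5 — editing failure switches on at runs of
#' four or more, mimicking RNA-polymerase-III termination of the gRNA —
#' which leaves a composition-typical site about 85% edited with ~1% per
#' SV class. The SV slopes are calibrated to the observed scale of the
#' indices in the reference study (background near 0; diverged tandem
#' arrays around 0.5 in I_LR; dispersed repeats around 1.2 in I_GR), so
#' that each class's generating covariate dominates that class and
#' recovery of the rule by the downstream models is a well-posed test.
#'
#' @export
OUTCOME_RULE_DEFAULTS <- list(unedit_intercept = -14, unedit_slope = 4.0,
                              del_intercept = -4.6, del_slope = 7.5,
                              tra_intercept = -4.6, tra_slope = 4.0)

#' Draw outcome labels from the generative rule
#'
#' @param sites Site table with a `spacer` column.
#' @param profiles data.frame with per-site `i_lr_500` and `i_gr_500`
#'   columns (e.g. the feature table).
#' @param rule_params Parameter list (see [OUTCOME_RULE_DEFAULTS]).
#' @param seed RNG seed.
#' @return list(labels = factor over {edited, unedited, DEL, TRA},
#'   probabilities = n x 4 matrix).
#' @export
simulate_outcome_labels <- function(sites, profiles,
                                    rule_params = OUTCOME_RULE_DEFAULTS,
                                    seed = 1L) {
  tscore <- vapply(sites$spacer, t_homopolymer_score, integer(1),
                   USE.NAMES = FALSE)
  logits <- cbind(
    edited = 0,
    unedited = rule_params$unedit_intercept + rule_params$unedit_slope *
      tscore,
    DEL = rule_params$del_intercept + rule_params$del_slope *
      profiles$i_lr_500,
    TRA = rule_params$tra_intercept + rule_params$tra_slope *
      profiles$i_gr_500)
  pr <- exp(logits - apply(logits, 1, max))
  pr <- pr / rowSums(pr)
  labels <- with_seed(seed, apply(pr, 1, function(p) {
    sample(colnames(pr), 1L, prob = p)
  }))
  list(labels = factor(labels, levels = colnames(pr)), probabilities = pr)
}

#' Simulate a binned read-count matrix with planted copy losses
#'
#' Negative-binomial counts (mean `depth`, dispersion `dispersion`), with
#' the mean of planted (bin, sample) cells multiplied by their loss (or
#' gain) factor.
#'
#' @param n_bins,n_samples Matrix dimensions.
#' @param depth Mean count per bin (default 40).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2;
#'   default 0.1).
#' @param planted Optional data.frame(bin, sample, factor) of planted
#'   copy-number cells (factor 0.05 = strong loss, 2 = gain).
#' @param seed RNG seed.
#' @return Integer matrix, bins x samples.
#' @export
simulate_coverage <- function(n_bins, n_samples, depth = 40,
                              dispersion = 0.1, planted = NULL, seed = 1L) {
  with_seed(seed, {
    mu <- matrix(depth, n_bins, n_samples)
    if (!is.null(planted) && nrow(planted) > 0) {
      mu[cbind(planted$bin, planted$sample)] <-
        depth * planted$factor
    }
    matrix(rnbinom(n_bins * n_samples, mu = mu, size = 1 / dispersion),
           n_bins, n_samples)
  })
}

#' Simulate per-clone variant observations and coverage signatures
#'
#' Each clone carries one donor design and a true outcome label. Edited
#' clones receive their designed variants, with incorporation of variants
#' far from the cut site decaying logistically (50% at 10 bp; the variant
#' nearest the cut is always incorporated). NHEJ clones receive a small
#' (1-3 bp) deletion at the cut site. DEL and TRA clones receive a copy-loss
#' signature over their target bins; TRA clones additionally gain a distal
#' segment. Unedited clones receive nothing.
#'
#' @param designs List of per-clone designs: list(clone_id, wildtype_seq,
#'   donor_seq, designed_variants = data.frame(offset, ref, alt),
#'   cut_offset, target_bins = integer vector).
#' @param labels Factor/character of true outcomes per clone, levels among
#'   {edited, unedited, DEL, TRA, NHEJ-indel}.
#' @param n_bins Number of coverage bins in the genome-wide matrix.
#' @param depth,dispersion Coverage model (see [simulate_coverage()]).
#' @param loss_factor Copy-loss depth multiplier (default 0.05).
#' @param decay_midpoint,decay_scale Incorporation decay: probability
#'   `plogis((decay_midpoint - distance) / decay_scale)` (defaults 10 and
#'   3 bp).
#' @param seed RNG seed.
#' @return list(variants = data.frame(clone_id, offset, ref, alt),
#'   coverage = bins x clones matrix, gain_bins = list per clone).
#' @export
simulate_clone_observations <- function(designs, labels, n_bins,
                                        depth = 40, dispersion = 0.1,
                                        loss_factor = 0.05,
                                        decay_midpoint = 10,
                                        decay_scale = 3, seed = 1L) {
  labels <- as.character(labels)
  stopifnot(length(designs) == length(labels))
  with_seed(seed, {
    vrows <- list()
    planted <- list()
    gain_bins <- vector("list", length(designs))
    for (ci in seq_along(designs)) {
      d <- designs[[ci]]
      lab <- labels[ci]
      if (lab == "edited") {
        dv <- d$designed_variants
        dist <- abs(dv$offset - d$cut_offset)
        keep <- plogis((decay_midpoint - dist) / decay_scale) >
          runif(nrow(dv))
        keep[which.min(dist)] <- TRUE
        dv <- dv[keep, , drop = FALSE]
        if (nrow(dv) > 0) {
          vrows[[length(vrows) + 1L]] <-
            cbind(clone_id = d$clone_id, dv)
        }
      } else if (lab == "NHEJ-indel") {
        del_len <- sample(1:3, 1L)
        ref <- substr(d$wildtype_seq, d$cut_offset + 1L,
                      d$cut_offset + del_len + 1L)
        vrows[[length(vrows) + 1L]] <-
          data.frame(clone_id = d$clone_id, offset = d$cut_offset,
                     ref = ref, alt = substr(ref, 1L, 1L))
      } else if (lab %in% c("DEL", "TRA")) {
        planted[[length(planted) + 1L]] <-
          data.frame(bin = d$target_bins, sample = ci,
                     factor = loss_factor)
        if (lab == "TRA") {
          # distal duplicated template segment: nonreciprocal
          # translocations gain a copy of a multi-kb template region
          glen <- sample(25:35, 1L)
          excl <- (min(d$target_bins) - glen):(max(d$target_bins) + glen)
          far <- setdiff(seq_len(n_bins - glen + 1L), excl)
          g0 <- far[sample(length(far), 1L)]
          gb <- g0:(g0 + glen - 1L)
          gain_bins[[ci]] <- gb
          planted[[length(planted) + 1L]] <-
            data.frame(bin = gb, sample = ci, factor = 2)
        }
      }
    }
    planted <- if (length(planted)) do.call(rbind, planted) else NULL
    coverage <- simulate_coverage(n_bins, length(designs), depth = depth,
                                  dispersion = dispersion,
                                  planted = planted,
                                  seed = sample.int(2^31 - 1L, 1L))
    variants <- if (length(vrows)) do.call(rbind, vrows) else
      data.frame(clone_id = character(), offset = integer(),
                 ref = character(), alt = character())
    rownames(variants) <- NULL
    list(variants = variants, coverage = coverage, gain_bins = gain_bins)
  })
}

#' Call outcomes for a simulated clone panel
#'
#' End-to-end wrapper: normalizes the clone coverage matrix, computes
#' rank-of-rank, detects loss and gain segments, and applies
#' [call_clone_outcome()] per clone using its design and observed variants.
#'
#' @param observations Result of [simulate_clone_observations()].
#' @param designs The design list the observations were generated from.
#' @param min_run Minimum flagged-bin run for loss detection at the target.
#' @param gain_window,gain_threshold Sliding-window length and mean-RoR
#'   cutoff for genome-wide gain detection (see [detect_gain_segments()]).
#' @return data.frame(clone_id, label).
#' @export
call_outcomes_panel <- function(observations, designs, min_run = 3L,
                                gain_window = 20L, gain_threshold = 0.75) {
  norm <- normalize_library_size(observations$coverage)
  cm <- rank_of_rank(norm$normalized)
  loss <- detect_loss_segments(cm, min_run = min_run)
  gain <- detect_gain_segments(cm, mean_threshold = gain_threshold,
                               window = gain_window)
  res <- lapply(seq_along(designs), function(ci) {
    d <- designs[[ci]]
    v <- observations$variants[observations$variants$clone_id == d$clone_id,
                               c("offset", "ref", "alt"), drop = FALSE]
    sl <- loss[loss$sample == ci, , drop = FALSE]
    loss_at_target <- any(sl$start_bin <= max(d$target_bins) &
                            sl$end_bin >= min(d$target_bins))
    sg <- gain[gain$sample == ci, , drop = FALSE]
    gain_elsewhere <- any(sg$end_bin < min(d$target_bins) |
                            sg$start_bin > max(d$target_bins))
    call <- call_clone_outcome(v, loss_at_target,
                               list(wildtype_seq = d$wildtype_seq,
                                    donor_seq = d$donor_seq),
                               gain_elsewhere = gain_elsewhere)
    data.frame(clone_id = d$clone_id, label = call$label)
  })
  do.call(rbind, res)
}
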