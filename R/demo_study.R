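# A self-contained reference study: a simulated two-chromosome genome with
# planted tandem, dispersed and subtelomeric repeat elements, outcome labels
# drawn from the generative rule, the four trained submodels, and the
# derived genome maps. Used by the worked examples, the acceptance checks
# and the command-line interface.

#' Configuration of the reference simulation study
#'
#' Two chromosomes carrying three tandem arrays (deletion drivers), two
#' dispersed repeat families and a subtelomeric shared block (translocation
#' drivers), all with low per-copy divergence so their spacers remain
#' mostly unique. Element positions scale with the chromosome length.
#'
#' @param seed RNG seed for the genome draw.
#' @param chrom_len Length of each of the two chromosomes (default 20 kb).
#' @return A [sim_config()].
#' @export
demo_study_config <- function(seed = 1L, chrom_len = 20000L) {
  L <- as.integer(chrom_len)
  if (L < 11000L) stop("chrom_len must be at least 11 kb for the element layout")
  at <- function(f) as.integer(round(f * L))
  sim_config(
    chrom_lengths = c(chrI = L, chrII = L),
    tandem = list(
      list(chrom = "chrI", pos = at(0.16), unit_len = 300L, copies = 5L,
           divergence = 0.03),
      list(chrom = "chrI", pos = at(0.72), unit_len = 150L, copies = 8L,
           divergence = 0.03),
      list(chrom = "chrII", pos = at(0.32), unit_len = 400L, copies = 4L,
           divergence = 0.03)),
    dispersed = list(
      list(block_len = 800L,
           sites = data.frame(chrom = c("chrI", "chrII", "chrII"),
                              pos = c(at(0.40), at(0.12), at(0.60))),
           divergence = 0.02),
      list(block_len = 600L,
           sites = data.frame(chrom = c("chrI", "chrII"),
                              pos = c(at(0.56), at(0.80))),
           divergence = 0.02)),
    subtelomeric = list(block_len = 700L, divergence = 0.02),
    telomere_len = 500L,
    centromere_len = 120L,
    seed = seed)
}

#' Run the reference study end to end
#'
#' Simulates the genome, enumerates and filters PAM sites, assembles the
#' repetitiveness/sequence feature table, draws outcome labels from the
#' generative rule, trains the four outcome submodels on a site subsample,
#' evaluates them on the held-out sites, scores every unique site, and
#' derives difficult-to-edit calls, SV hotspots and their overlap with the
#' planted repeat elements.
#'
#' @param seed Master RNG seed.
#' @param chrom_len Chromosome length passed to [demo_study_config()].
#' @param n_train Number of sites in the training subsample (default 800).
#' @param n_shuffles Shuffle count for the repetitiveness indices
#'   (default 20).
#' @param hyperparams GBDT hyperparameters for all submodels.
#' @param plan Resampling plan applied inside training.
#' @return list with elements `sim`, `sites` (scored site table),
#'   `features`, `labels`, `models`, `heldout` (per-submodel AUROC/AUPRC on
#'   held-out sites), `track`, `dters`, `hotspots`, `recovery` (fraction of
#'   planted elements overlapping a called hotspot) and `train_idx`.
#' @export
run_demo_study <- function(seed = 1L, chrom_len = 20000L, n_train = 800L,
                           n_shuffles = 20L,
                           hyperparams = list(n_trees = 150L,
                                              learning_rate = 0.1,
                                              interaction_depth = 3L),
                           plan = resampling_plan(1, "random")) {
  sim <- simulate_genome(demo_study_config(seed, chrom_len))
  genome <- sim$genome
  sites <- assess_spacer_uniqueness(enumerate_pam_sites(genome), genome)
  lens <- chrom_lengths(genome)
  keep <- sites$unique &
    sites$pam_pos >= 26L & sites$pam_pos <= lens[sites$chrom] - 27L
  sites <- sites[keep, ]
  rownames(sites) <- NULL

  cfg <- feature_config(subsets = c("1", "3"), n_shuffles = n_shuffles)
  ft <- assemble_feature_table(sites, genome, config = cfg, seed = seed)
  labels <- simulate_outcome_labels(sites, ft$features, seed = seed + 1L)

  n <- nrow(sites)
  n_train <- min(n_train, n - 200L)
  train_idx <- with_seed(seed + 2L, sample(n, n_train))
  x <- as.matrix(ft$features[, -1, drop = FALSE])
  lab <- labels$labels

  # each submodel distinguishes its undesired outcome from correct edits:
  # training and evaluation use positives plus edited sites only
  positive_sets <- list(
    unedit = lab == "unedited",
    del = lab == "DEL",
    tra = lab == "TRA",
    sv = lab %in% c("DEL", "TRA"))
  edited <- lab == "edited"
  models <- list()
  heldout <- list()
  for (nm in names(positive_sets)) {
    y <- positive_sets[[nm]]
    use_tr <- train_idx[y[train_idx] | edited[train_idx]]
    models[[nm]] <- train_scorer(x[use_tr, , drop = FALSE], y[use_tr],
                                 plan = plan, hyperparams = hyperparams,
                                 seed = seed + match(nm, names(positive_sets)))
    ho <- setdiff(which(y | edited), train_idx)
    p <- predict_raw(models[[nm]], x[ho, , drop = FALSE])
    heldout[[nm]] <- list(auroc = auroc(p, y[ho]), auprc = auprc(p, y[ho]),
                          n_pos = sum(y[ho]), idx = ho)
  }

  track <- score_genome(models, sites, ft)
  dters <- call_dters(track)
  hotspots <- cluster_sv_hotspots(track)
  planted <- sim$truth$planted
  hit <- vapply(seq_len(nrow(planted)), function(i) {
    any(hotspots$chrom == planted$chrom[i] &
          hotspots$start <= planted$end[i] &
          hotspots$end >= planted$start[i])
  }, logical(1))
  list(sim = sim, sites = sites, features = ft, labels = labels,
       models = models, heldout = heldout, track = track, dters = dters,
       hotspots = hotspots,
       recovery = mean(hit), planted_hit = hit, train_idx = train_idx)
}

#' Feature groups of the reference study for importance analysis
#'
#' Groups follow the metric families: `local_seq` (positional indicators,
#' GC, T homopolymer), `local_repeat` (the I_LR gradient together with the
#' tandem-arm lengths — two views of the same tandem-repeat structure, so
#' they are shuffled jointly), `global_repeat` (the I_GR gradient) and
#' `position` (telomere/centromere distances).
#'
#' @param feature_table A feature table from the reference study.
#' @return Named list of column-name vectors.
#' @export
demo_feature_groups <- function(feature_table) {
  cols <- colnames(feature_table$features)
  list(
    local_seq = grep("^seq_pos|^gc$|^t_homopolymer$", cols, value = TRUE),
    local_repeat = grep("^i_lr_|^tandem_len_", cols, value = TRUE),
    global_repeat = grep("^i_gr_", cols, value = TRUE),
    position = grep("^dist_", cols, value = TRUE))
}
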