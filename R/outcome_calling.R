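# Editing-outcome labeling: edit-distance intent classification, copy-loss
# detection by rank-of-rank on binned read counts, clone outcome calls,
# breakpoint homology, background-variant filtering, and bulk coverage-drop
# quantification.

#' Classify an observed variant as intended or unintended
#'
#' A variant is intended when adding it to the wild-type sequence reduces
#' the Levenshtein distance to the donor template; this also handles partial
#' incorporation of multi-nucleotide designs, where each incorporated
#' component variant individually reduces the distance.
#'
#' @param wildtype_seq Local reference sequence.
#' @param donor_seq Donor template carrying the designed variants.
#' @param observed_variant list(offset=, ref=, alt=) with a 0-based offset
#'   into `wildtype_seq`.
#' @return `"intended"` or `"unintended"`.
#' @export
classify_variant_intent <- function(wildtype_seq, donor_seq,
                                    observed_variant) {
  v <- observed_variant
  ref_at <- substr(wildtype_seq, v$offset + 1L, v$offset + nchar(v$ref))
  if (ref_at != v$ref)
    stop("variant ref allele '", v$ref, "' does not match wild-type '",
         ref_at, "' at offset ", v$offset)
  mutated <- paste0(substr(wildtype_seq, 1L, v$offset), v$alt,
                    substr(wildtype_seq, v$offset + nchar(v$ref) + 1L,
                           nchar(wildtype_seq)))
  d0 <- as.integer(adist(wildtype_seq, donor_seq))
  d1 <- as.integer(adist(mutated, donor_seq))
  if (d1 < d0) "intended" else "unintended"
}

#' Median-of-ratios library-size normalization
#'
#' Per-sample size factors are the median, over bins with a strictly
#' positive geometric mean, of the ratio of the bin's count to that
#' geometric mean; counts are divided by their sample's factor.
#'
#' @param raw_counts Non-negative integer matrix, bins x samples.
#' @return list(normalized = matrix, size_factors = numeric vector).
#' @export
normalize_library_size <- function(raw_counts) {
  raw_counts <- as.matrix(raw_counts)
  if (any(raw_counts < 0)) stop("counts must be non-negative")
  if (any(colSums(raw_counts) == 0)) stop("sample with all-zero counts")
  loggeo <- rowMeans(log(raw_counts))
  ok <- is.finite(loggeo)
  if (!any(ok)) stop("no bin has a positive geometric mean")
  sf <- apply(raw_counts, 2, function(x) {
    exp(median(log(x[ok]) - loggeo[ok]))
  })
  list(normalized = sweep(raw_counts, 2, sf, "/"), size_factors = sf)
}

#' Coverage matrix with rank and rank-of-rank layers
#'
#' Within each sample, normalized bin counts are ranked across the n bins
#' (average ranks for ties) and scaled by n; the rank-of-rank layer then
#' ranks, within each bin, those per-sample ranks across the m samples and
#' scales by m. Low RoR marks a bin under-covered in one sample relative to
#' its behaviour in all samples, which cancels shared depth biases.
#'
#' @param normalized Bins x samples matrix of normalized counts.
#' @param bins Optional data.frame (chrom, start, end) of bin coordinates.
#' @return Object of class `coverage_matrix` with layers `normalized`,
#'   `rank`, `ror` and the bin table.
#' @export
rank_of_rank <- function(normalized, bins = NULL) {
  normalized <- as.matrix(normalized)
  n <- nrow(normalized)
  m <- ncol(normalized)
  R <- apply(normalized, 2, function(x) rank(x, ties.method = "average") / n)
  R <- matrix(R, nrow = n, dimnames = dimnames(normalized))
  ror <- t(apply(R, 1, function(r) rank(r, ties.method = "average") / m))
  ror <- matrix(ror, nrow = n, dimnames = dimnames(normalized))
  structure(list(bins = bins, normalized = normalized, rank = R, ror = ror),
            class = "coverage_matrix")
}

#' Flag copy-number-loss signals from the RoR layer
#'
#' Cells with RoR below the threshold are raw loss signals; per-sample runs
#' of consecutive flagged bins are additionally merged into segments.
#'
#' @param coverage_matrix A `coverage_matrix` from [rank_of_rank()].
#' @param threshold RoR cutoff (default 0.1, strict inequality).
#' @return list(cells = data.frame(bin, sample), segments =
#'   data.frame(sample, start_bin, end_bin, n_bins)).
#' @export
flag_copy_loss <- function(coverage_matrix, threshold = 0.1) {
  idx <- which(coverage_matrix$ror < threshold, arr.ind = TRUE)
  cells <- data.frame(bin = as.integer(idx[, 1]),
                      sample = as.integer(idx[, 2]))
  cells <- cells[order(cells$sample, cells$bin), , drop = FALSE]
  rownames(cells) <- NULL
  segs <- do.call(rbind, lapply(split(cells$bin, cells$sample),
                                function(b) {
    b <- sort(b)
    grp <- cumsum(c(1L, diff(b) != 1L))
    do.call(rbind, lapply(split(b, grp), function(g) {
      data.frame(start_bin = min(g), end_bin = max(g), n_bins = length(g))
    }))
  }))
  if (is.null(segs)) {
    segs <- data.frame(sample = integer(), start_bin = integer(),
                       end_bin = integer(), n_bins = integer())
  } else {
    segs <- cbind(sample = as.integer(sub("\\..*$", "", rownames(segs))),
                  segs)
    rownames(segs) <- NULL
  }
  list(cells = cells, segments = segs[, c("sample", "start_bin", "end_bin",
                                          "n_bins")])
}

#' Detected copy-loss segments
#'
#' Raw RoR flags mark the lowest-ranked sample in roughly a tenth of the
#' bins under the null, so a single flagged bin is not evidence of loss.
#' Detection requires a run of at least `min_run` consecutive flagged bins
#' for the same sample, a deterministic stand-in for the visual confirmation
#' step used with real data.
#'
#' @inheritParams flag_copy_loss
#' @param min_run Minimum run length (bins) for a detected segment
#'   (default 3).
#' @return data.frame(sample, start_bin, end_bin, n_bins).
#' @export
detect_loss_segments <- function(coverage_matrix, threshold = 0.1,
                                 min_run = 3L) {
  segs <- flag_copy_loss(coverage_matrix, threshold)$segments
  segs[segs$n_bins >= min_run, , drop = FALSE]
}

#' Copy-gain segments (duplication evidence)
#'
#' High-RoR counterpart of the loss test, used as duplication evidence to
#' separate nonreciprocal translocations (which gain a copy of their
#' template region, typically spanning many bins) from plain deletions.
#' Because a single over-dispersed bin of a 2x segment often ranks below
#' any fixed per-cell cutoff, the evidence is aggregated: a sliding window
#' of `window` bins is flagged when its mean RoR exceeds `mean_threshold`
#' (under the null the mean of `window` near-uniform ranks concentrates at
#' 0.5, so the default keeps false windows per sample well below one even
#' for thousands of bins); overlapping flagged windows merge into
#' segments.
#'
#' @inheritParams flag_copy_loss
#' @param mean_threshold Window-mean RoR cutoff (default 0.75, strict).
#' @param window Sliding-window length in bins (default 20).
#' @return data.frame(sample, start_bin, end_bin, n_bins).
#' @export
detect_gain_segments <- function(coverage_matrix, mean_threshold = 0.75,
                                 window = 20L) {
  ror <- coverage_matrix$ror
  n <- nrow(ror)
  m <- ncol(ror)
  w <- min(window, n)
  out <- list()
  cs <- apply(ror, 2, cumsum)
  cs <- rbind(0, cs)
  for (j in seq_len(m)) {
    means <- (cs[(w + 1):(n + 1), j] - cs[1:(n - w + 1), j]) / w
    hi <- which(means > mean_threshold)
    if (length(hi) == 0L) next
    grp <- cumsum(c(1L, diff(hi) != 1L))
    for (g in split(hi, grp)) {
      out[[length(out) + 1L]] <- data.frame(
        sample = j, start_bin = min(g), end_bin = max(g) + w - 1L,
        n_bins = max(g) + w - min(g))
    }
  }
  if (length(out) == 0L)
    return(data.frame(sample = integer(), start_bin = integer(),
                      end_bin = integer(), n_bins = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call the editing outcome of one clone
#'
#' Decision rules over the three signature classes (variants within 200 bp
#' of the target, copy-loss at the target, distal duplication evidence):
#' copy loss plus an intended variant is conflicting evidence
#' (SV-unclassified); copy loss with a distal gain is a nonreciprocal
#' translocation (TRA), without one a large deletion (DEL); an intended
#' variant with clean coverage is a correct edit; an unintended indel alone
#' is an NHEJ indel; an unintended SNV alone is left SV-unclassified for
#' audit; no signatures at all is unedited.
#'
#' @param variants data.frame(offset, ref, alt) of variants within +/-200 bp
#'   of the target (possibly empty).
#' @param loss_at_target Logical: detected copy-loss segment overlapping the
#'   target bins.
#' @param donor_design list(wildtype_seq=, donor_seq=, ...).
#' @param gain_elsewhere Logical: detected copy-gain segment away from the
#'   target (default FALSE).
#' @return list(label=, evidence=) where label is one of `edited`,
#'   `unedited`, `NHEJ-indel`, `DEL`, `TRA`, `SV-unclassified`.
#' @export
call_clone_outcome <- function(variants, loss_at_target, donor_design,
                               gain_elsewhere = FALSE) {
  if (is.null(donor_design)) stop("missing donor design")
  evidence <- character()
  has_intended <- FALSE
  has_unint_indel <- FALSE
  has_unint_snv <- FALSE
  if (!is.null(variants) && nrow(variants) > 0) {
    for (i in seq_len(nrow(variants))) {
      v <- list(offset = variants$offset[i], ref = variants$ref[i],
                alt = variants$alt[i])
      cls <- classify_variant_intent(donor_design$wildtype_seq,
                                     donor_design$donor_seq, v)
      if (cls == "intended") {
        has_intended <- TRUE
      } else if (nchar(v$ref) != nchar(v$alt)) {
        has_unint_indel <- TRUE
      } else {
        has_unint_snv <- TRUE
      }
    }
  }
  if (has_intended) evidence <- c(evidence, "intended-variant")
  if (has_unint_indel || has_unint_snv)
    evidence <- c(evidence, "unintended-variant-near-target")
  if (loss_at_target) evidence <- c(evidence, "copy-loss")
  if (gain_elsewhere) evidence <- c(evidence, "distal-copy-gain")
  label <- if (loss_at_target) {
    if (has_intended) "SV-unclassified"
    else if (gain_elsewhere) "TRA"
    else "DEL"
  } else if (has_intended) {
    "edited"
  } else if (has_unint_indel) {
    "NHEJ-indel"
  } else if (has_unint_snv) {
    "SV-unclassified"
  } else {
    "unedited"
  }
  list(label = label, evidence = evidence)
}

#' Perfect-match homology length at an SV breakpoint
#'
#' Scans outward from the two breakpoints, base by base, and returns the
#' number of identical bases before the first mismatch (microhomology /
#' homology tract length shared by the joined flanks).
#'
#' @param genome A `genome_assembly`.
#' @param target_locus list(chrom=, pos=, side=) with `side` `"left"`
#'   (scan pos-1, pos-2, ...) or `"right"` (scan pos, pos+1, ...); `pos`
#'   0-based.
#' @param template_locus Same structure for the homology donor locus.
#' @return Non-negative integer homology length in bp.
#' @export
breakpoint_homology <- function(genome, target_locus, template_locus) {
  flank <- function(loc) {
    n <- nchar(genome$seq[[loc$chrom]])
    if (is.null(genome$seq[[loc$chrom]]) || loc$pos < 0 || loc$pos > n)
      stop("breakpoint out of bounds")
    side <- loc$side %||% "left"
    if (side == "left") {
      rev(strsplit(genome_slice(genome, loc$chrom, 0L, loc$pos), "",
                   fixed = TRUE)[[1]])
    } else {
      strsplit(genome_slice(genome, loc$chrom, loc$pos, n), "",
               fixed = TRUE)[[1]]
    }
  }
  a <- flank(target_locus)
  b <- flank(template_locus)
  k <- min(length(a), length(b))
  if (k == 0L) return(0L)
  neq <- which(a[seq_len(k)] != b[seq_len(k)])
  if (length(neq) == 0L) k else neq[1] - 1L
}

#' Filter background variants across a clone panel
#'
#' Applies, in order: (i) drop variant loci with missing genotypes in more
#' than half of the samples; (ii) drop samples with missing genotypes at
#' more than half of the remaining loci; (iii) drop variants present in
#' clones carrying different gRNAs (shared background variation cannot be a
#' target-site editing outcome).
#'
#' @param genotypes Loci x clones matrix: 1 = variant present, 0 = absent,
#'   NA = missing.
#' @param clone_grna Named character vector mapping clone (column) name to
#'   its gRNA sequence.
#' @return list(genotypes = filtered matrix, kept_loci =, kept_samples =).
#' @export
filter_background_variants <- function(genotypes, clone_grna) {
  g <- as.matrix(genotypes)
  keep_loci <- rowMeans(is.na(g)) <= 0.5
  g <- g[keep_loci, , drop = FALSE]
  keep_samples <- colMeans(is.na(g)) <= 0.5
  g <- g[, keep_samples, drop = FALSE]
  grnas <- clone_grna[colnames(g)]
  shared <- apply(g, 1, function(row) {
    carriers <- which(!is.na(row) & row == 1)
    length(unique(grnas[carriers])) > 1L
  })
  g <- g[!shared, , drop = FALSE]
  list(genotypes = g, kept_loci = rownames(g), kept_samples = colnames(g))
}

#' Bulk SV fraction from coverage drop at the target
#'
#' Depth vectors are normalized per sample by their mean; per sliding window
#' (window = region/25 bp, step = region/50 bp) the normalized edited depth
#' is divided by the mean of the normalized controls, and the coverage
#' reduction is `1 - normalized coverage`, clipped to [0, 1] (gains are
#' reported separately via `delta_raw`). The SV fraction of the bulk culture
#' is the coverage reduction in the window whose midpoint is nearest the
#' PAM.
#'
#' @param edited_coverage Numeric per-base depth of the edited bulk sample
#'   over the region.
#' @param control_coverages Matrix (positions x samples) or vector of
#'   per-base depths for unedited controls.
#' @param region list(start=, end=) 0-based half-open region bounds
#'   (coordinates of the depth vectors).
#' @param pam_pos PAM coordinate (0-based) inside the region.
#' @return Object of class `bulk_estimate`: window table (start, end,
#'   normalized_coverage, delta, delta_raw), `sv_fraction`, and
#'   `edited_fraction`/`unedited_fraction` (NA until
#'   [partition_alleles()]).
#' @export
bulk_sv_fraction <- function(edited_coverage, control_coverages, region,
                             pam_pos) {
  ctrl <- as.matrix(control_coverages)
  L <- region$end - region$start
  stopifnot(length(edited_coverage) == L, nrow(ctrl) == L)
  win <- max(1L, L %/% 25L)
  step <- max(1L, L %/% 50L)
  ed <- edited_coverage / mean(edited_coverage)
  cn <- sweep(ctrl, 2, colMeans(ctrl), "/")
  starts <- seq(0L, L - win, by = step)
  nc <- vapply(starts, function(s) {
    idx <- (s + 1L):(s + win)
    cmean <- mean(rowMeans(cn[idx, , drop = FALSE]))
    if (cmean == 0) stop("zero control coverage in window at offset ", s)
    mean(ed[idx]) / cmean
  }, numeric(1))
  delta_raw <- 1 - nc
  delta <- pmin(1, pmax(0, delta_raw))
  mid <- region$start + starts + win / 2
  at_pam <- which.min(abs(mid - (pam_pos + 0.5)))
  windows <- data.frame(start = region$start + starts,
                        end = region$start + starts + win,
                        normalized_coverage = nc, delta = delta,
                        delta_raw = delta_raw)
  structure(list(windows = windows, sv_fraction = delta[at_pam],
                 pam_window = at_pam, edited_fraction = NA_real_,
                 unedited_fraction = NA_real_),
            class = "bulk_estimate")
}

#' Partition the non-SV bulk fraction into edited and unedited
#'
#' The remainder `1 - sv_fraction` is split according to the ratio of reads
#' supporting the edited allele to reads supporting the wild-type allele at
#' the target variant.
#'
#' @param bulk_estimate A `bulk_estimate` from [bulk_sv_fraction()].
#' @param edited_read_count,wildtype_read_count Non-negative allele read
#'   counts (not both zero).
#' @return The updated `bulk_estimate`; fractions sum to 1.
#' @export
partition_alleles <- function(bulk_estimate, edited_read_count,
                              wildtype_read_count) {
  e <- edited_read_count
  w <- wildtype_read_count
  if (e < 0 || w < 0) stop("read counts must be non-negative")
  if (e + w == 0) stop("edited and wild-type read counts are both zero")
  rem <- 1 - bulk_estimate$sv_fraction
  bulk_estimate$edited_fraction <- rem * e / (e + w)
  bulk_estimate$unedited_fraction <- rem * w / (e + w)
  bulk_estimate
}
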