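# Genome-wide score tracks and derived maps: difficult-to-edit regions,
# SV hotspot clusters, loxP-distance context and breakpoint-bin summaries.

#' Score all sites with the four outcome submodels
#'
#' Applies the unedit/DEL/TRA/SV scorers to a feature table and min-max
#' normalizes each submodel's raw outputs over the scored site set (the
#' reference set defines the [0, 1] range).
#'
#' @param models Named list of `trained_scorer`s; names among
#'   `unedit`, `del`, `tra`, `sv`.
#' @param sites Site table (unique-spacer sites), one row per feature row.
#' @param feature_table Result of [assemble_feature_table()] for `sites`.
#' @return A `score_track` data.frame: chrom, pam_pos, strand and one
#'   `score_<model>` column per submodel, sorted by genomic coordinate.
#' @export
score_genome <- function(models, sites, feature_table) {
  x <- as.matrix(feature_table$features[, -1, drop = FALSE])
  track <- sites[, c("chrom", "pam_pos", "strand")]
  for (nm in names(models)) {
    scorer <- calibrate_scorer(models[[nm]], x)
    track[[paste0("score_", nm)]] <- predict_normalized(scorer, x)
  }
  track <- track[order(track$chrom, track$pam_pos, track$strand), ]
  rownames(track) <- NULL
  class(track) <- c("score_track", "data.frame")
  track
}

#' Default outlier thresholds for difficult-to-edit regions
#' @export
DTER_THRESHOLDS <- c(sv = 0.15, del = 0.15, tra = 0.15, unedit = 0.25)

#' Call difficult-to-edit regions from a score track
#'
#' Sites whose normalized score for an undesired outcome exceeds that
#' outcome's outlier threshold are flagged as difficult to edit for it.
#'
#' @param track A `score_track`.
#' @param thresholds Named numeric vector of per-outcome thresholds
#'   (default [DTER_THRESHOLDS]).
#' @return list(sites = named list of per-outcome site subsets, fractions =
#'   named numeric vector of subset size / track size).
#' @export
call_dters <- function(track, thresholds = DTER_THRESHOLDS) {
  subsets <- lapply(names(thresholds), function(nm) {
    col <- paste0("score_", nm)
    track[track[[col]] > thresholds[[nm]], , drop = FALSE]
  })
  names(subsets) <- names(thresholds)
  fractions <- vapply(subsets, function(s) nrow(s) / max(1L, nrow(track)),
                      numeric(1))
  list(sites = subsets, fractions = fractions)
}

#' Cluster SV-prone PAM sites into hotspots
#'
#' Three-step rule over the genome-ordered, strand-pooled PAM list:
#' (1) maximal runs of consecutive above-threshold PAMs (any below-threshold
#' PAM breaks a run); (2) runs with fewer than `min_sites` members are
#' dropped; (3) surviving runs whose edge-to-edge gap is at most
#' `merge_dist` bp are merged, pooling their member counts. The hotspot span
#' is the first-to-last member PAM position.
#'
#' @param track A `score_track`.
#' @param score_col Score column to threshold (default `"score_sv"`).
#' @param threshold Score cutoff (default 0.15, strict).
#' @param min_sites Minimum consecutive signals per run (default 10).
#' @param merge_dist Maximum gap merged in step 3 (default 200 bp).
#' @return data.frame(chrom, start, end, n_sites, max_score, mean_score).
#' @export
cluster_sv_hotspots <- function(track, score_col = "score_sv",
                                threshold = 0.15, min_sites = 10L,
                                merge_dist = 200L) {
  out <- list()
  for (chrom in unique(track$chrom)) {
    t <- track[track$chrom == chrom, , drop = FALSE]
    t <- t[order(t$pam_pos, t$strand), , drop = FALSE]
    hi <- t[[score_col]] > threshold
    if (!any(hi)) next
    run_id <- cumsum(c(TRUE, diff(as.integer(hi)) != 0))
    runs <- lapply(split(seq_len(nrow(t))[hi], run_id[hi]), function(idx) {
      data.frame(start = t$pam_pos[idx[1]],
                 end = t$pam_pos[idx[length(idx)]],
                 n_sites = length(idx),
                 max_score = max(t[[score_col]][idx]),
                 sum_score = sum(t[[score_col]][idx]))
    })
    runs <- do.call(rbind, runs)
    runs <- runs[runs$n_sites >= min_sites, , drop = FALSE]
    if (nrow(runs) == 0L) next
    runs <- runs[order(runs$start), , drop = FALSE]
    grp <- cumsum(c(1, (runs$start[-1] - runs$end[-nrow(runs)]) > merge_dist))
    merged <- do.call(rbind, lapply(split(runs, grp), function(g) {
      data.frame(chrom = chrom, start = min(g$start), end = max(g$end),
                 n_sites = sum(g$n_sites), max_score = max(g$max_score),
                 mean_score = sum(g$sum_score) / sum(g$n_sites))
    }))
    out[[chrom]] <- merged
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_sites = integer(),
                      max_score = numeric(), mean_score = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write hotspots as BED4 with a score column
#' @param hotspots Result of [cluster_sv_hotspots()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hotspots_bed <- function(hotspots, path) {
  bed <- data.frame(chrom = hotspots$chrom, start = hotspots$start,
                    end = hotspots$end + 1L,
                    name = sprintf("hotspot_%d", seq_len(nrow(hotspots))),
                    score = round(hotspots$mean_score, 4))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' loxP-distance context of scored sites
#'
#' For each site lying strictly between two loxP sites on its chromosome,
#' the flanking distance is the base-pair separation of the upstream and
#' downstream loxP positions (interval midpoints for the 34-bp loxPsym
#' site); sites outside any flanking pair get NA. The Pearson correlation
#' between flanking distance and the deletion score is computed over
#' non-missing sites.
#'
#' @param track A `score_track` with a `score_del` column.
#' @param loxp_positions data.frame(chrom, pos) of loxP midpoints.
#' @return list(context = track with `loxp_distance` column, pearson_r =,
#'   n =).
#' @export
loxp_deletion_context <- function(track, loxp_positions) {
  track$loxp_distance <- NA_real_
  for (chrom in unique(track$chrom)) {
    lp <- sort(loxp_positions$pos[loxp_positions$chrom == chrom])
    if (length(lp) < 2L) next
    sel <- which(track$chrom == chrom)
    up <- findInterval(track$pam_pos[sel], lp)
    ok <- up >= 1L & up < length(lp) & track$pam_pos[sel] > lp[pmax(1L, up)]
    track$loxp_distance[sel[ok]] <- lp[up[ok] + 1L] - lp[up[ok]]
  }
  use <- !is.na(track$loxp_distance)
  r <- if (sum(use) >= 3L && sd(track$loxp_distance[use]) > 0 &&
           sd(track$score_del[use]) > 0) {
    cor(track$loxp_distance[use], track$score_del[use])
  } else NA_real_
  list(context = track, pearson_r = r, n = sum(use))
}

#' Score summaries in distance bins around SV breakpoints
#'
#' Pools all scored PAM sites within `half_width` bp of any breakpoint into
#' fixed 100-bp bins of relative offset (site pam_pos minus breakpoint) and
#' summarizes their scores. The fraction of PAM sites excluded from scoring
#' (non-unique spacers) is reported per bin from the full PAM list.
#'
#' @param breakpoints data.frame(chrom, pos) of breakpoint coordinates.
#' @param track A `score_track` of scored (unique-spacer) sites.
#' @param all_pam_positions data.frame(chrom, pam_pos) of every PAM,
#'   including excluded ones.
#' @param half_width Window half-width (default 1050 bp).
#' @param bin Bin width (default 100 bp).
#' @param score_col Score column to summarize (default `"score_sv"`).
#' @return data.frame with one row per bin (offset_lo, offset_hi, n_scored,
#'   n_all, mean_score, median_score, excluded_fraction); bins with no
#'   scored PAM report NA summaries.
#' @export
bin_breakpoint_scores <- function(breakpoints, track, all_pam_positions,
                                  half_width = 1050L, bin = 100L,
                                  score_col = "score_sv") {
  edges <- seq(-half_width, half_width, by = bin)
  nb <- length(edges) - 1L
  acc_scored <- vector("list", nb)
  acc_all <- integer(nb)
  for (i in seq_len(nrow(breakpoints))) {
    bp <- breakpoints[i, ]
    sel <- track$chrom == bp$chrom &
      track$pam_pos >= bp$pos - half_width &
      track$pam_pos < bp$pos + half_width
    if (any(sel)) {
      off <- track$pam_pos[sel] - bp$pos
      b <- findInterval(off, edges, rightmost.closed = FALSE)
      for (k in unique(b)) {
        acc_scored[[k]] <- c(acc_scored[[k]], track[[score_col]][sel][b == k])
      }
    }
    pa <- all_pam_positions$chrom == bp$chrom &
      all_pam_positions$pam_pos >= bp$pos - half_width &
      all_pam_positions$pam_pos < bp$pos + half_width
    if (any(pa)) {
      offa <- all_pam_positions$pam_pos[pa] - bp$pos
      ba <- findInterval(offa, edges, rightmost.closed = FALSE)
      tb <- table(ba)
      acc_all[as.integer(names(tb))] <- acc_all[as.integer(names(tb))] +
        as.integer(tb)
    }
  }
  data.frame(
    offset_lo = edges[-length(edges)],
    offset_hi = edges[-1],
    n_scored = vapply(acc_scored, length, integer(1)),
    n_all = acc_all,
    mean_score = vapply(acc_scored, function(v) {
      if (length(v)) mean(v) else NA_real_
    }, numeric(1)),
    median_score = vapply(acc_scored, function(v) {
      if (length(v)) median(v) else NA_real_
    }, numeric(1)),
    excluded_fraction = ifelse(acc_all > 0,
                               1 - vapply(acc_scored, length, integer(1)) /
                                 acc_all, NA_real_))
}
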