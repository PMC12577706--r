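# Feature assembly for the outcome submodels. Feature subsets follow the
# ablation design: 1 = local sequence context, 2 = chromatin signals,
# 3 = repetitiveness and chromosomal position, T = technical covariates.

#' Default feature-assembly configuration
#'
#' @param window_sizes Repetitiveness window gradient (bp).
#' @param arm_sizes Tandem-arm gradient (bp).
#' @param subsets Feature subsets to include (any of "1","2","3","T").
#' @param chromatin_half_width Half-width (bp) of the window over which
#'   chromatin tracks are averaged (default 250).
#' @param n_shuffles Shuffle count for the repetitiveness indices.
#' @return A configuration list.
#' @export
feature_config <- function(window_sizes = REPEAT_WINDOW_SIZES,
                           arm_sizes = TANDEM_ARM_SIZES,
                           subsets = c("1", "2", "3", "T"),
                           chromatin_half_width = 250L,
                           n_shuffles = 20L) {
  list(window_sizes = as.integer(window_sizes),
       arm_sizes = as.integer(arm_sizes),
       subsets = as.character(subsets),
       chromatin_half_width = as.integer(chromatin_half_width),
       n_shuffles = as.integer(n_shuffles))
}

#' One-hot encoding of the 30-nt sequence context of a site
#'
#' Extracts the 20-nt spacer plus 5 nt on each side, oriented so the spacer
#' reads 5'-to-3' on the targeting strand (minus-strand sites are reverse
#' complemented), and one-hot encodes each of the 30 positions.
#'
#' @param site Single-row site (chrom, pam_pos, strand).
#' @param genome A `genome_assembly`.
#' @return Named numeric vector of 120 indicators (`seq_pos01_A`, ...).
#' @export
encode_sequence_context <- function(site, genome) {
  s <- context_sequence(site, genome)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  v <- numeric(120L)
  names(v) <- paste0("seq_pos", sprintf("%02d", rep(1:30, each = 4)), "_",
                     rep(bases, 30))
  idx <- (seq_len(30L) - 1L) * 4L + match(chars, bases)
  v[idx] <- 1
  v
}

# 30-nt guide-oriented context string (spacer +/- 5 nt).
context_sequence <- function(site, genome) {
  chrom <- site$chrom[1]
  p <- site$pam_pos[1]
  n <- nchar(genome$seq[[chrom]])
  if (site$strand[1] == "+") {
    if (p - 25L < 0L || p + 5L > n) stop("context window off chromosome end")
    genome_slice(genome, chrom, p - 25L, p + 5L)
  } else {
    if (p - 4L < 0L || p + 26L > n) stop("context window off chromosome end")
    revcomp(genome_slice(genome, chrom, p - 4L, p + 26L))
  }
}

# Inverse of encode_sequence_context (used in tests).
decode_sequence_context <- function(v) {
  bases <- c("A", "C", "G", "T")
  m <- matrix(v, nrow = 4L)
  paste(bases[apply(m, 2, which.max)], collapse = "")
}

#' Longest T homopolymer in a spacer
#'
#' Long T runs act as RNA-polymerase-III terminators for gRNA expression and
#' predict the absence of editing; the score is the length of the longest
#' run of consecutive T in the 20-nt spacer.
#'
#' @param spacer Spacer string.
#' @return Non-negative integer.
#' @export
t_homopolymer_score <- function(spacer) {
  runs <- gregexpr("T+", toupper(spacer))[[1]]
  if (runs[1] == -1L) return(0L)
  max(attr(runs, "match.length"))
}

#' GC fraction of a string
#' @param seq DNA string.
#' @return Fraction in [0, 1].
#' @export
gc_content <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  mean(chars %in% c("G", "C"))
}

#' Read a bedGraph track into an interval table
#' @param path bedGraph path.
#' @return data.frame (chrom, start, end, value), 0-based half-open.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             value = gr$score)
}

#' Length-weighted mean chromatin signal around a site
#'
#' Averages a sorted, non-overlapping bedGraph-style track over
#' `[pam_pos - half_width, pam_pos + half_width)`. Portions of the window
#' without track data contribute the track's global (length-weighted) mean,
#' so sites in data gaps are imputed rather than dropped.
#'
#' @param track data.frame (chrom, start, end, value), as from
#'   [read_bedgraph()].
#' @param site Single-row site.
#' @param half_width Window half-width in bp (default 250).
#' @return Numeric signal value.
#' @export
chromatin_signal <- function(track, site, half_width = 250L) {
  if (any(track$end <= track$start)) stop("malformed track")
  gmean <- sum((track$end - track$start) * track$value) /
    sum(track$end - track$start)
  lo <- site$pam_pos[1] - half_width
  hi <- site$pam_pos[1] + half_width
  t <- track[track$chrom == site$chrom[1] & track$end > lo &
               track$start < hi, , drop = FALSE]
  if (nrow(t) == 0L) return(gmean)
  cov_len <- pmin(t$end, hi) - pmax(t$start, lo)
  covered <- sum(cov_len)
  (sum(cov_len * t$value) + (hi - lo - covered) * gmean) / (hi - lo)
}

#' Distances to the nearest telomere and to the centromere
#'
#' Distance from `pam_pos` to the nearest edge of the nearest annotated
#' telomere interval and of the centromere interval on the site's
#' chromosome; 0 when the site lies inside the interval.
#'
#' @param site Single-row site.
#' @param annotations Annotation data.frame (chrom, start, end, name) with
#'   `telomere` and `centromere` classes.
#' @return list(dist_telomere=, dist_centromere=).
#' @export
chromosomal_position_features <- function(site, annotations) {
  p <- site$pam_pos[1]
  dist_to <- function(cls) {
    a <- annotations[annotations$chrom == site$chrom[1] &
                       annotations$name == cls, , drop = FALSE]
    if (nrow(a) == 0L) stop("missing ", cls, " annotation for chromosome ",
                            site$chrom[1])
    min(pmax(0L, pmax(a$start - p, p - (a$end - 1L))))
  }
  list(dist_telomere = dist_to("telomere"),
       dist_centromere = dist_to("centromere"))
}

#' Assemble the model feature table
#'
#' Builds one row per site: positional sequence indicators, GC content and
#' T-homopolymer score (subset 1); chromatin track signals (subset 2);
#' repetitiveness gradient and chromosomal-position distances (subset 3);
#' one-hot technical covariates with a declared reference level (subset T).
#' The returned manifest records each column's subset so ablations only
#' change the column set, never the row keys. Assembly is a pure function of
#' its inputs, the configuration, and the seed.
#'
#' @param sites Site table (one row per site).
#' @param genome A `genome_assembly`.
#' @param tracks Named list of chromatin track data.frames.
#' @param covariates Optional data.frame of per-site categorical covariates
#'   (e.g. variant type, editing system), one row per site.
#' @param config Configuration from [feature_config()].
#' @param seed RNG seed for the repetitiveness shuffles.
#' @return list(features = data.frame keyed by `site_id`, manifest =
#'   data.frame(column, subset)).
#' @export
assemble_feature_table <- function(sites, genome, tracks = list(),
                                   covariates = NULL,
                                   config = feature_config(), seed = 1L) {
  ids <- site_ids(sites)
  if (anyDuplicated(ids)) stop("site id collisions")
  n <- nrow(sites)
  feats <- data.frame(site_id = ids)
  manifest <- data.frame(column = character(), subset = character())
  add <- function(df, block, subset) {
    manifest <<- rbind(manifest,
                       data.frame(column = colnames(block), subset = subset))
    cbind(df, block)
  }

  if ("1" %in% config$subsets) {
    ctx <- t(vapply(seq_len(n), function(i) {
      encode_sequence_context(sites[i, ], genome)
    }, numeric(120L)))
    loc <- data.frame(
      gc = vapply(sites$spacer, gc_content, numeric(1), USE.NAMES = FALSE),
      t_homopolymer = vapply(sites$spacer, t_homopolymer_score, integer(1),
                             USE.NAMES = FALSE))
    feats <- add(feats, as.data.frame(ctx), "1")
    feats <- add(feats, loc, "1")
  }
  if ("2" %in% config$subsets && length(tracks) > 0) {
    chr <- vapply(names(tracks), function(tn) {
      vapply(seq_len(n), function(i) {
        chromatin_signal(tracks[[tn]], sites[i, ],
                         half_width = config$chromatin_half_width)
      }, numeric(1))
    }, numeric(n))
    chr <- matrix(chr, nrow = n,
                  dimnames = list(NULL, paste0("chromatin_", names(tracks))))
    feats <- add(feats, as.data.frame(chr), "2")
  }
  if ("3" %in% config$subsets) {
    prof <- lapply(seq_len(n), function(i) {
      profile_site(sites[i, ], genome, window_sizes = config$window_sizes,
                   arm_sizes = config$arm_sizes,
                   seed = seed + 7L * sites$pam_pos[i],
                   n_shuffles = config$n_shuffles)
    })
    rep_block <- do.call(rbind, lapply(prof, function(p) {
      c(setNames(p$i_lr, paste0("i_lr_", names(p$i_lr))),
        setNames(p$i_gr, paste0("i_gr_", names(p$i_gr))),
        setNames(as.numeric(p$tandem_len),
                 paste0("tandem_len_", names(p$tandem_len))))
    }))
    pos <- do.call(rbind, lapply(seq_len(n), function(i) {
      as.data.frame(chromosomal_position_features(sites[i, ], genome$ann))
    }))
    feats <- add(feats, as.data.frame(rep_block), "3")
    feats <- add(feats, pos, "3")
  }
  if ("T" %in% config$subsets && !is.null(covariates)) {
    if (nrow(covariates) != n) stop("covariates must have one row per site")
    for (cv in names(covariates)) {
      levs <- levels(factor(covariates[[cv]]))
      if (length(levs) < 1L) stop("missing covariate levels for ", cv)
      # reference level = first; indicators for the rest
      for (lv in levs[-1]) {
        block <- data.frame(x = as.numeric(covariates[[cv]] == lv))
        colnames(block) <- paste0("cov_", cv, "_", lv)
        feats <- add(feats, block, "T")
      }
    }
  }
  if (anyNA(feats)) stop("internal error: missing values after assembly")
  rownames(feats) <- NULL
  list(features = feats, manifest = manifest)
}

#' Stable site identifiers
#' @param sites Site table.
#' @return Character vector `chrom:pam_pos:strand`.
#' @export
site_ids <- function(sites) {
  paste(sites$chrom, sites$pam_pos, sites$strand, sep = ":")
}

#' Write a feature table with its JSON manifest sidecar
#' @param ft Result of [assemble_feature_table()].
#' @param path TSV output path; the manifest goes to `<path>.manifest.json`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  write.table(ft$features, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(ft$manifest, paste0(path, ".manifest.json"),
                       dataframe = "rows")
  invisible(path)
}
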