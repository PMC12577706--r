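# Genome loading, Cas9 target-site enumeration, spacer uniqueness and
# off-target scanning. Coordinates are 0-based half-open throughout; BED
# conventions apply on disk.

#' Construct a genome assembly object
#'
#' A genome assembly holds named chromosome sequences (A/C/G/T/N, case
#' normalized to upper case) plus optional named interval annotations
#' (telomere, centromere, loxP, gene, ...) in 0-based half-open coordinates.
#'
#' @param chromosomes Named character vector of chromosome sequences.
#' @param annotations Optional data.frame with columns `chrom`, `start`,
#'   `end`, `name` (0-based half-open).
#' @return An object of class `genome_assembly`.
#' @export
genome_assembly <- function(chromosomes, annotations = NULL) {
  if (length(chromosomes) == 0L) stop("empty genome")
  if (is.null(names(chromosomes)) || anyNA(names(chromosomes)) ||
      any(names(chromosomes) == ""))
    stop("chromosomes must be named")
  chromosomes <- toupper(chromosomes)
  bad <- grepl("[^ACGTN]", chromosomes)
  if (any(bad))
    stop("non-IUPAC character in chromosome(s): ",
         paste(names(chromosomes)[bad], collapse = ", "))
  if (is.null(annotations)) {
    annotations <- data.frame(chrom = character(), start = integer(),
                              end = integer(), name = character())
  } else {
    stopifnot(all(c("chrom", "start", "end", "name") %in% names(annotations)))
    lens <- nchar(chromosomes)
    if (!all(annotations$chrom %in% names(chromosomes)))
      stop("annotation on unknown chromosome")
    if (any(annotations$start < 0) ||
        any(annotations$end > lens[annotations$chrom]) ||
        any(annotations$end <= annotations$start))
      stop("annotation interval out of chromosome bounds")
  }
  structure(list(seq = chromosomes, ann = annotations),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("genome_assembly:", length(x$seq), "chromosome(s),",
      sum(nchar(x$seq)), "bp;", nrow(x$ann), "annotation interval(s)\n")
  invisible(x)
}

#' Chromosome lengths of an assembly
#' @param genome A `genome_assembly`.
#' @return Named integer vector of lengths.
#' @export
chrom_lengths <- function(genome) nchar(genome$seq)

#' Load a genome from FASTA plus BED annotations
#'
#' @param fasta_path Path to a (multi-record) FASTA file.
#' @param annotation_paths Optional character vector of BED4 paths; the BED
#'   name column assigns each interval to an annotation class.
#' @return A `genome_assembly`.
#' @export
load_genome <- function(fasta_path, annotation_paths = NULL) {
  if (!file.exists(fasta_path)) stop("FASTA not found: ", fasta_path)
  ss <- Biostrings::readDNAStringSet(fasta_path)
  chroms <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  ann <- NULL
  if (!is.null(annotation_paths)) {
    parts <- lapply(annotation_paths, function(p) {
      if (!file.exists(p)) stop("BED not found: ", p)
      gr <- rtracklayer::import(p, format = "BED")
      nm <- gr$name
      if (is.null(nm)) nm <- rep(NA_character_, length(gr))
      data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1L,
                 end = GenomicRanges::end(gr),
                 name = nm)
    })
    ann <- do.call(rbind, parts)
  }
  genome_assembly(chroms, ann)
}

#' Write annotations of an assembly as BED4
#' @param genome A `genome_assembly`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations_bed <- function(genome, path) {
  a <- genome$ann
  write.table(a[, c("chrom", "start", "end", "name")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Enumerate candidate Cas9 target sites
#'
#' Scans both strands for NGG protospacer-adjacent motifs ("N" = any of
#' A/C/G/T; positions 2-3 are literal GG). `pam_pos` is the 0-based
#' coordinate of the first PAM base on the forward strand. Sites whose
#' 20-nt spacer or 3-nt PAM would extend past a sequence end, or whose
#' spacer+PAM window contains an ambiguous base, are excluded.
#'
#' @param genome A `genome_assembly`.
#' @param pam_motif PAM motif; only `"NGG"` is supported.
#' @param spacer_len Spacer length in nt (default 20).
#' @return A data.frame with columns `chrom`, `pam_pos`, `strand`, `spacer`,
#'   `pam`, `unique` (NA until [assess_spacer_uniqueness()] is run), sorted
#'   by (chrom, pam_pos, strand).
#' @export
enumerate_pam_sites <- function(genome, pam_motif = "NGG", spacer_len = 20L) {
  if (!identical(toupper(pam_motif), "NGG"))
    stop("only the NGG PAM motif is supported")
  if (length(genome$seq) == 0L) stop("empty genome")
  spacer_len <- as.integer(spacer_len)
  res <- lapply(names(genome$seq), function(chrom) {
    s <- genome$seq[[chrom]]
    n <- nchar(s)
    out <- list()
    # forward: GG at 0-based (p+1, p+2)
    gg <- unlist(gregexpr("(?=GG)", s, perl = TRUE))
    gg <- gg[gg > 0]
    p <- gg - 2L  # 0-based pam_pos
    p <- p[p >= spacer_len & (p + 3L) <= n]
    if (length(p)) {
      spacer <- substring(s, p - spacer_len + 1L, p)
      pam <- substring(s, p + 1L, p + 3L)
      keep <- !grepl("N", spacer, fixed = TRUE) & !grepl("N", pam, fixed = TRUE)
      out$fwd <- data.frame(chrom = chrom, pam_pos = p[keep], strand = "+",
                            spacer = spacer[keep], pam = pam[keep])
    }
    # reverse: forward-strand CC at 0-based (p-2, p-1)
    cc <- unlist(gregexpr("(?=CC)", s, perl = TRUE))
    cc <- cc[cc > 0]
    p <- cc + 1L  # 0-based pam_pos (first PAM base on - strand)
    p <- p[(p - 2L) >= 0L & (p + 1L + spacer_len) <= n]
    if (length(p)) {
      spacer_fw <- substring(s, p + 2L, p + 1L + spacer_len)
      pam_fw <- substring(s, p - 1L, p + 1L)
      keep <- !grepl("N", spacer_fw, fixed = TRUE) &
        !grepl("N", pam_fw, fixed = TRUE)
      out$rev <- data.frame(chrom = chrom, pam_pos = p[keep], strand = "-",
                            spacer = revcomp(spacer_fw[keep]),
                            pam = revcomp(pam_fw[keep]))
    }
    do.call(rbind, out)
  })
  sites <- do.call(rbind, res)
  if (is.null(sites) || nrow(sites) == 0L) {
    sites <- data.frame(chrom = character(), pam_pos = integer(),
                        strand = character(), spacer = character(),
                        pam = character())
  }
  sites <- sites[order(sites$chrom, sites$pam_pos, sites$strand), ]
  rownames(sites) <- NULL
  sites$unique <- rep(NA, nrow(sites))
  attr(sites, "spacer_len") <- spacer_len
  sites
}

#' Flag spacers with perfect off-target matches
#'
#' A spacer is non-unique when the identical 20-mer occurs, immediately
#' adjacent to an NGG PAM, at more than one genomic location (both strands
#' counted). A second occurrence lacking its own NGG does not disqualify a
#' spacer, since Cas9 binding requires the PAM.
#'
#' @param sites Sites from [enumerate_pam_sites()] on the same genome (any
#'   subset).
#' @param genome The `genome_assembly` the sites came from.
#' @return `sites` with the `unique` flag filled in.
#' @export
assess_spacer_uniqueness <- function(sites, genome) {
  spacer_len <- attr(sites, "spacer_len") %||% 20L
  all_sites <- enumerate_pam_sites(genome, spacer_len = spacer_len)
  counts <- table(all_sites$spacer)
  sites$unique <- as.vector(counts[sites$spacer] == 1L)
  sites
}

#' Minimum semiglobal edit distance of a guide within a window
#'
#' Fitting alignment of the 23-nt guide (20-nt spacer + NGG) inside the
#' longer genomic window: the window's flanks are free, the guide must be
#' fully consumed, and substitutions/internal gaps cost 1. Both the forward
#' window and its reverse complement are scanned; the minimum-distance
#' orientation is reported, with ties broken by lowest window start and then
#' the + orientation.
#'
#' @param guide_23nt 23-nt guide string (spacer + PAM).
#' @param window_seq Genomic window, length >= 23.
#' @return A list with `edit_distance`, `mismatches` (substitutions along an
#'   optimal path), `start`/`end` (0-based half-open, window coordinates) and
#'   `strand` (`"+"`/`"-"` orientation of the hit).
#' @export
semiglobal_distance <- function(guide_23nt, window_seq) {
  guide_23nt <- toupper(guide_23nt)
  window_seq <- toupper(window_seq)
  if (nchar(guide_23nt) != 23L) stop("guide must be 23 nt")
  if (nchar(window_seq) < nchar(guide_23nt))
    stop("window shorter than guide")
  n <- nchar(window_seq)
  fw <- cpp_semiglobal(guide_23nt, window_seq)
  rv <- cpp_semiglobal(guide_23nt, revcomp(window_seq))
  rv_start <- n - rv$end
  rv_end <- n - rv$start
  pick_fw <- fw$distance < rv$distance ||
    (fw$distance == rv$distance &&
       (fw$start < rv_start || (fw$start == rv_start)))
  if (pick_fw) {
    list(edit_distance = fw$distance, mismatches = fw$mismatches,
         start = fw$start, end = fw$end, strand = "+")
  } else {
    list(edit_distance = rv$distance, mismatches = rv$mismatches,
         start = rv_start, end = rv_end, strand = "-")
  }
}

#' Scan a genome for close-mismatch off-target loci
#'
#' Finds every NGG-adjacent 20-mer within `max_mismatches` substitutions of
#' the site's spacer (no indels), excluding the on-target locus itself.
#'
#' @param site A single-row site (as from [enumerate_pam_sites()]).
#' @param genome The `genome_assembly` to scan.
#' @param max_mismatches Maximum substitution count (default 3).
#' @param all_sites Optional precomputed full enumeration of `genome`
#'   (speeds up repeated scans).
#' @return data.frame of hits: `chrom`, `pam_pos`, `start` (0-based start of
#'   the protospacer), `strand`, `mismatches`, `edit_distance`.
#' @export
scan_offtargets <- function(site, genome, max_mismatches = 3L,
                            all_sites = NULL) {
  if (is.null(all_sites)) all_sites <- enumerate_pam_sites(genome)
  mm <- cpp_hamming(site$spacer[1], all_sites$spacer)
  keep <- mm <= max_mismatches &
    !(all_sites$chrom == site$chrom[1] &
        all_sites$pam_pos == site$pam_pos[1] &
        all_sites$strand == site$strand[1])
  hits <- all_sites[keep, c("chrom", "pam_pos", "strand")]
  hits$start <- ifelse(hits$strand == "+", hits$pam_pos - 20L,
                       hits$pam_pos + 1L)
  hits$mismatches <- mm[keep]
  hits$edit_distance <- hits$mismatches
  rownames(hits) <- NULL
  hits[, c("chrom", "pam_pos", "start", "strand", "mismatches",
           "edit_distance")]
}

#' Fetch the sequence of a 0-based half-open interval
#' @param genome A `genome_assembly`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open bounds.
#' @return Sequence string.
#' @export
genome_slice <- function(genome, chrom, start, end) {
  n <- nchar(genome$seq[[chrom]])
  if (is.null(genome$seq[[chrom]])) stop("unknown chromosome: ", chrom)
  if (start < 0 || end > n || end < start) stop("interval out of bounds")
  substr(genome$seq[[chrom]], start + 1L, end)
}
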