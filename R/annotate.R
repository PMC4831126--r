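# Region annotation: ZFP57 motif counting and enrichment, AMR-dataset
# overlap scoring, CpG-island detection and transcript-relative mapping.

#' Count motif occurrences in sequences
#'
#' Counts exact forward occurrences of `motif` and, when `both_strands`,
#' forward occurrences of its reverse complement (skipped when the motif is
#' its own reverse complement).  `N` bases never match.
#'
#' @param sequence character vector of sequences.
#' @param motif the motif (default the ZFP57 binding hexamer TGCCGC).
#' @param both_strands count the reverse complement too (default TRUE).
#' @return integer vector of counts, one per sequence.
#' @export
count_motif <- function(sequence, motif = "TGCCGC", both_strands = TRUE) {
  if (length(motif) != 1 || !nzchar(motif)) stop("motif must be non-empty")
  motif <- toupper(motif)
  pats <- motif
  rc <- reverse_complement(motif)
  if (both_strands && rc != motif) pats <- c(pats, rc)
  counts <- integer(length(sequence))
  for (p in pats) {
    counts <- counts + vapply(sequence, function(s) {
      if (!nzchar(s)) return(0L)
      h <- unlist(gregexpr(p, toupper(s), fixed = TRUE))
      sum(h > 0)
    }, integer(1), USE.NAMES = FALSE)
  }
  counts
}

#' Extract region sequences from a genome
#'
#' @param genome named character vector of contig sequences.
#' @param regions region data.frame (0-based half-open).
#' @return character vector of region sequences.
#' @export
region_sequences <- function(genome, regions) {
  check_regions(regions)
  if (nrow(regions) == 0) return(character())
  chrom <- as.character(regions$chrom)
  if (!all(chrom %in% names(genome))) {
    stop("region chrom not present in genome")
  }
  if (any(regions$end > nchar(genome[chrom]))) {
    stop("region extends beyond contig end")
  }
  substr(unname(genome[chrom]), regions$start + 1L, regions$end)
}

#' Motif-count histogram over a region set
#'
#' @param regions region data.frame.
#' @param genome named character vector of contig sequences.
#' @inheritParams count_motif
#' @return data.frame with `motif_count` (0..max) and `n_regions`; the
#'   counts sum to the number of regions.
#' @export
motif_distribution <- function(regions, genome, motif = "TGCCGC",
                               both_strands = TRUE) {
  counts <- count_motif(region_sequences(genome, regions), motif,
                        both_strands)
  mx <- if (length(counts)) max(counts) else 0L
  data.frame(motif_count = 0:mx,
             n_regions = tabulate(counts + 1L, nbins = mx + 1L))
}

#' Percentage of counts at or above a threshold
#'
#' `100 * |{c >= k}| / n`, the summary used to compare motif content
#' between region sets (e.g. "two or more motif copies").  The full
#' precision value is returned; display rounding to whole percent is left
#' to the caller.
#'
#' @param counts non-empty integer vector (e.g. motif counts per region).
#' @param k inclusive threshold (default 2).
#' @return percentage as a single number.
#' @export
fraction_at_least <- function(counts, k = 2) {
  if (length(counts) == 0) stop("counts must be non-empty")
  100 * sum(counts >= k) / length(counts)
}

#' Percentage of AMR scores strictly above a threshold
#'
#' @param scores integer vector of per-region dataset counts.
#' @param threshold strict lower bound (default 5, i.e. "more than 5
#'   datasets").
#' @return percentage as a single number.
#' @export
amr_fraction <- function(scores, threshold = 5) {
  if (length(scores) == 0) stop("scores must be non-empty")
  100 * sum(scores > threshold) / length(scores)
}

#' Score regions against allele-specific-methylation datasets
#'
#' Each dataset contributes 1 to a region's score when any of its intervals
#' overlaps the region by at least one base (dataset-level indicator, not
#' interval-level counting).
#'
#' @param regions region data.frame.
#' @param amr_datasets list of interval data.frames, one per dataset.
#' @param threshold strict threshold for the summary fraction (default 5).
#' @return list with `scores` (data.frame `region_id`, `n_datasets`),
#'   `fraction_above` (percentage of regions with score strictly above
#'   `threshold`) and `threshold`.
#' @export
amr_overlap <- function(regions, amr_datasets, threshold = 5) {
  check_regions(regions)
  if (!"region_id" %in% names(regions)) {
    regions$region_id <- region_ids(regions)
  }
  n <- nrow(regions)
  score <- integer(n)
  if (n > 0 && length(amr_datasets)) {
    gr <- regions_to_granges(regions)
    for (ds in amr_datasets) {
      check_regions(ds)
      if (nrow(ds) == 0) next
      score <- score +
        as.integer(IRanges::countOverlaps(gr, regions_to_granges(ds)) > 0)
    }
  }
  list(scores = data.frame(region_id = regions$region_id,
                           n_datasets = score, stringsAsFactors = FALSE),
       fraction_above = if (n > 0) amr_fraction(score, threshold) else
         NA_real_,
       threshold = threshold)
}

#' Detect CpG islands
#'
#' Gardiner-Garden style criteria: 200 bp windows (step 1) with GC content
#' at least `gc_min` and observed/expected CpG ratio at least `oe_min`
#' (`O/E = n_CG * L / (n_C * n_G)`) are merged into maximal islands of at
#' least `min_len` bases.
#'
#' @param genome named character vector of contig sequences.
#' @param min_len minimum island length (default 200).
#' @param gc_min minimum GC fraction (default 0.50).
#' @param oe_min minimum observed/expected CpG ratio (default 0.60).
#' @param window window size (default 200).
#' @return data.frame of island intervals (0-based half-open).
#' @export
detect_cpg_islands <- function(genome, min_len = 200, gc_min = 0.50,
                               oe_min = 0.60, window = 200) {
  out <- list()
  for (ctg in names(genome)) {
    b <- strsplit(genome[[ctg]], "")[[1]]
    L <- length(b)
    if (L < window) next
    cC <- c(0, cumsum(b == "C"))
    cG <- c(0, cumsum(b == "G"))
    cCG <- c(0, cumsum(b == "C" & c(b[-1] == "G", FALSE)))
    i <- seq_len(L - window + 1)           # window = [i, i + window - 1]
    nC <- cC[i + window] - cC[i]
    nG <- cG[i + window] - cG[i]
    nCG <- cCG[i + window - 1] - cCG[i]    # CG pairs fully inside
    gc <- (nC + nG) / window
    oe <- ifelse(nC * nG > 0, nCG * window / (nC * nG), 0)
    pass <- gc >= gc_min & oe >= oe_min
    if (!any(pass)) next
    spans <- IRanges::reduce(IRanges::IRanges(start = which(pass),
                                              width = window))
    spans <- spans[IRanges::width(spans) >= min_len]
    if (!length(spans)) next
    out[[ctg]] <- data.frame(chrom = ctg,
                             start = IRanges::start(spans) - 1L,
                             end = IRanges::end(spans),
                             stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  res <- sort_regions(do.call(rbind, out))
  rownames(res) <- NULL
  res
}

#' Map regions to transcript context
#'
#' For each region centre (`floor((start + end) / 2)`): the minimum
#' distance over same-contig transcripts to the transcript 5' end (the
#' `start` of a plus-strand transcript, `end - 1` of a minus-strand one),
#' whether the centre lies within any transcript, and whether it is
#' TSS-proximal (distance <= 1000, inclusive).
#'
#' @param regions region data.frame.
#' @param transcripts data.frame with `chrom`, `start`, `end`, `strand`.
#' @return data.frame with `region_id`, `center`, `distance_to_5prime`,
#'   `within_transcript`, `tss_proximal`.  Regions on contigs without any
#'   transcript get `NA` distance (with a warning); an empty transcript set
#'   is an error.
#' @export
map_to_transcripts <- function(regions, transcripts) {
  check_regions(regions)
  stopifnot(is.data.frame(transcripts))
  if (nrow(transcripts) == 0) {
    stop("transcript set is empty: distances are undefined")
  }
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(transcripts)),
            all(transcripts$strand %in% c("+", "-")))
  if (!"region_id" %in% names(regions)) {
    regions$region_id <- region_ids(regions)
  }
  tss <- ifelse(transcripts$strand == "+", transcripts$start,
                transcripts$end - 1L)
  center <- as.integer(floor((regions$start + regions$end) / 2))
  n <- nrow(regions)
  dist <- rep(NA_real_, n)
  within <- logical(n)
  for (i in seq_len(n)) {
    same <- transcripts$chrom == regions$chrom[i]
    if (!any(same)) next
    dist[i] <- min(abs(center[i] - tss[same]))
    within[i] <- any(center[i] >= transcripts$start[same] &
                       center[i] < transcripts$end[same])
  }
  if (anyNA(dist)) {
    warning("some regions lie on contigs without transcripts; distance NA")
  }
  data.frame(region_id = regions$region_id, center = center,
             distance_to_5prime = dist, within_transcript = within,
             tss_proximal = !is.na(dist) & dist <= 1000,
             stringsAsFactors = FALSE)
}
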