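# Region definition pipeline: read filtering, per-sample region calling,
# cross-sample merging, per-region counting and the RPM floor.
# Coordinates are 0-based half-open throughout (BED convention on disk).

#' Filter aligned reads on mapping quality and remove duplicates
#'
#' Drops reads with mapping quality below `min_mapq`, then keeps exactly one
#' read per sample sharing (chrom, 5' position, strand) -- the standard
#' single-end duplicate definition (the 5' position of a minus-strand read
#' is its `end`).  Output order is stable (first occurrence wins).
#'
#' @param reads data.frame with columns `chrom`, `start`, `end`, `mapq`,
#'   `strand`, `sample`.
#' @param min_mapq minimum mapping quality retained (default 37).
#' @return the filtered data.frame.
#' @export
filter_reads <- function(reads, min_mapq = 37) {
  stopifnot(is.data.frame(reads))
  if (nrow(reads) == 0) return(reads)
  stopifnot(all(c("chrom", "start", "end", "mapq", "strand", "sample") %in%
                  names(reads)))
  keep <- reads[reads$mapq >= min_mapq, , drop = FALSE]
  if (nrow(keep) == 0) return(keep)
  five_prime <- ifelse(keep$strand == "+", keep$start, keep$end)
  key <- paste(keep$sample, keep$chrom, five_prime, keep$strand, sep = "\r")
  out <- keep[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Extend each read to the full capture fragment from its 5' end along its
# strand, clipped to the contig.
extend_fragments <- function(reads, fragment_extension = 250,
                             contig_lengths = NULL) {
  fstart <- ifelse(reads$strand == "+", reads$start,
                   reads$end - fragment_extension)
  fend <- fstart + fragment_extension
  fstart <- pmax(fstart, 0)
  if (!is.null(contig_lengths)) {
    lim <- contig_lengths[as.character(reads$chrom)]
    fend <- pmin(fend, lim)
  }
  data.frame(chrom = reads$chrom, start = fstart, end = fend,
             sample = if ("sample" %in% names(reads)) reads$sample else NA,
             stringsAsFactors = FALSE)
}

#' Call methylated regions from one sample's filtered reads
#'
#' A simplified capture-peak caller.  Each read is extended to
#' `fragment_extension` bases from its 5' end along its strand; the genome
#' is tiled into `window`-sized windows; a window is significant when the
#' Poisson upper tail `P(X >= obs)` under `lambda = max(genome-wide rate,
#' local 10 kb rate)` falls below `p_threshold`.  Runs of adjacent
#' significant windows are joined into maximal intervals.
#'
#' @param reads filtered reads of one sample (data.frame as in
#'   [filter_reads()]).
#' @param contig_lengths named vector of contig lengths in bases.
#' @param p_threshold Poisson significance threshold (default 1e-8).
#' @param fragment_extension capture fragment size (default 250).
#' @param window tiling window size (default 250).
#' @param local_span span of the local background window (default 10 kb).
#' @return data.frame of regions (`chrom`, `start`, `end`), 0-based
#'   half-open, sorted; non-overlapping by construction.
#' @export
call_regions <- function(reads, contig_lengths, p_threshold = 1e-8,
                         fragment_extension = 250, window = 250,
                         local_span = 1e4) {
  stopifnot(is.data.frame(reads), nrow(reads) >= 1,
            !is.null(names(contig_lengths)), all(contig_lengths > 0))
  genome_size <- sum(contig_lengths)
  if (genome_size <= 0) stop("genome size must be positive")
  frags <- extend_fragments(reads, fragment_extension, contig_lengths)
  eff_len <- fragment_extension + window - 1
  lambda_bg <- nrow(frags) * eff_len / genome_size

  out <- list()
  for (ctg in names(contig_lengths)) {
    len <- contig_lengths[[ctg]]
    f <- frags[frags$chrom == ctg, , drop = FALSE]
    ws <- seq(0, len - 1, by = window)
    we <- pmin(ws + window, len)
    if (nrow(f) == 0) next
    fr <- IRanges::IRanges(start = f$start + 1L, end = f$end)
    cnt <- IRanges::countOverlaps(IRanges::IRanges(ws + 1L, we), fr)
    mid <- (ws + we) / 2
    ls <- pmax(0, mid - local_span / 2)
    le <- pmin(len, mid + local_span / 2)
    lc <- IRanges::countOverlaps(IRanges::IRanges(ls + 1L, le), fr)
    lambda_loc <- lc * eff_len / (le - ls + fragment_extension - 1)
    lambda <- pmax(lambda_bg, lambda_loc)
    p <- ppois(cnt - 1, lambda, lower.tail = FALSE)
    sig <- cnt > 0 & p < p_threshold
    if (!any(sig)) next
    r <- rle(sig)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1
    hit <- which(r$values)
    out[[ctg]] <- data.frame(chrom = ctg, start = ws[starts_i[hit]],
                             end = we[ends_i[hit]],
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

# Minimal union-find for merging components.
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Merge region sets across samples by reciprocal overlap
#'
#' Two regions merge when their overlap exceeds 50% of the SHORTER region's
#' length (strict inequality); merged regions take the union span.  Merging
#' is repeated to a fixpoint, so the operation is idempotent and invariant
#' to input order.
#'
#' @param region_sets a list of region data.frames (one per sample), or a
#'   single data.frame.  When a list is given, regions within each
#'   per-sample set must not overlap one another; a single data.frame
#'   (e.g. a previously merged universe, which may legitimately retain
#'   pairs below the merge threshold) is accepted as-is.
#' @param min_overlap_frac merge threshold as a fraction of the shorter
#'   region (default 0.5, exceeded strictly).
#' @return sorted data.frame of merged regions with a `region_id` column.
#' @export
merge_region_sets <- function(region_sets, min_overlap_frac = 0.5) {
  check_sets <- !is.data.frame(region_sets)
  if (is.data.frame(region_sets)) region_sets <- list(region_sets)
  for (rs in region_sets) {
    check_regions(rs)
    if (check_sets && nrow(rs) > 1) {
      o <- order(as.character(rs$chrom), rs$start)
      same <- rs$chrom[o][-1] == rs$chrom[o][-nrow(rs)]
      if (any(same & rs$start[o][-1] < rs$end[o][-nrow(rs)])) {
        stop("regions within one input set must be non-overlapping")
      }
    }
  }
  cur <- do.call(rbind, lapply(region_sets, function(x) {
    x[, c("chrom", "start", "end"), drop = FALSE]
  }))
  if (is.null(cur) || nrow(cur) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), region_id = character(),
                      stringsAsFactors = FALSE))
  }
  cur <- unique(sort_regions(cur))
  repeat {
    gr <- regions_to_granges(cur)
    hits <- IRanges::findOverlaps(gr, drop.self = TRUE,
                                  drop.redundant = TRUE)
    if (!length(hits)) break
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ov <- pmin(cur$end[q], cur$end[s]) - pmax(cur$start[q], cur$start[s])
    shorter <- pmin(cur$end[q] - cur$start[q], cur$end[s] - cur$start[s])
    edge <- ov > min_overlap_frac * shorter
    if (!any(edge)) break
    parent <- seq_len(nrow(cur))
    for (k in which(edge)) {
      ra <- uf_find(parent, q[k])
      rb <- uf_find(parent, s[k])
      if (ra != rb) parent[rb] <- ra
    }
    root <- vapply(seq_len(nrow(cur)), function(i) uf_find(parent, i),
                   integer(1))
    comp <- split(seq_len(nrow(cur)), root)
    cur <- do.call(rbind, lapply(comp, function(ix) {
      # members of a component overlap pairwise-transitively, hence share
      # a contig; the merged region is the union span
      data.frame(chrom = cur$chrom[ix[1]],
                 start = min(cur$start[ix]),
                 end = max(cur$end[ix]),
                 stringsAsFactors = FALSE)
    }))
    cur <- unique(sort_regions(cur))
  }
  cur <- unique(sort_regions(cur))
  rownames(cur) <- NULL
  cur$region_id <- region_ids(cur)
  cur
}

#' Count fragment overlaps per merged region
#'
#' A read counts toward a region when its extended fragment overlaps the
#' region by at least one base; a fragment spanning two regions counts in
#' both.  Library size is the total number of filtered reads per sample
#' regardless of region membership.
#'
#' @param regions merged region data.frame (with or without `region_id`).
#' @param reads filtered reads for all samples.
#' @param samples ordered sample ids; defaults to order of appearance in
#'   `reads`.  An error is raised if `reads` contains samples not listed.
#' @param fragment_extension capture fragment size (default 250).
#' @param contig_lengths optional named contig lengths for fragment
#'   clipping.
#' @return object of class `region_count_matrix`: list with `regions`,
#'   `samples`, `counts` (region x sample integer matrix) and
#'   `library_sizes`.
#' @export
count_matrix <- function(regions, reads, samples = NULL,
                         fragment_extension = 250, contig_lengths = NULL) {
  check_regions(regions)
  stopifnot(is.data.frame(reads), nrow(reads) >= 1)
  if (is.null(samples)) samples <- unique(reads$sample)
  if (!all(reads$sample %in% samples)) {
    stop("reads contain sample ids not listed in `samples`")
  }
  if (!"region_id" %in% names(regions)) regions$region_id <- region_ids(regions)
  frags <- extend_fragments(reads, fragment_extension, contig_lengths)
  gr_regions <- regions_to_granges(regions)
  counts <- matrix(0L, nrow(regions), length(samples),
                   dimnames = list(regions$region_id, samples))
  lib <- setNames(integer(length(samples)), samples)
  for (s in samples) {
    f <- frags[frags$sample == s, , drop = FALSE]
    lib[s] <- nrow(f)
    if (nrow(f) == 0) next
    gr_f <- regions_to_granges(f)
    counts[, s] <- IRanges::countOverlaps(gr_regions, gr_f)
  }
  if (any(lib == 0)) {
    stop("every sample must contribute at least one filtered read")
  }
  structure(list(regions = regions, samples = samples, counts = counts,
                 library_sizes = lib),
            class = "region_count_matrix")
}

#' @export
print.region_count_matrix <- function(x, ...) {
  cat(sprintf("Region count matrix: %d regions x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  library sizes: %s\n",
              paste(sprintf("%s=%d", names(x$library_sizes),
                            x$library_sizes), collapse = " ")))
  invisible(x)
}

#' Reads-per-million matrix
#'
#' @param mat a `region_count_matrix`.
#' @return numeric matrix of counts scaled to reads per million library
#'   reads.
#' @export
rpm <- function(mat) {
  stopifnot(inherits(mat, "region_count_matrix"))
  sweep(mat$counts, 2, mat$library_sizes / 1e6, `/`)
}

#' Apply the reads-per-million floor
#'
#' Retains a region iff its RPM reaches `min_rpm` (inclusive) in at least
#' one sample; regions below the floor in every sample are removed.
#'
#' @param mat a `region_count_matrix`.
#' @param min_rpm the floor (default 20).
#' @return the filtered `region_count_matrix`.
#' @export
rpm_filter <- function(mat, min_rpm = 20) {
  stopifnot(inherits(mat, "region_count_matrix"),
            all(mat$library_sizes > 0))
  keep <- rowSums(rpm(mat) >= min_rpm) >= 1
  out <- mat
  out$regions <- mat$regions[keep, , drop = FALSE]
  rownames(out$regions) <- NULL
  out$counts <- mat$counts[keep, , drop = FALSE]
  out
}
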