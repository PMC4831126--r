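# End-to-end driver: filtered reads -> per-sample region calls -> merged
# universe -> counts -> RPM floor -> per-case exact tests -> shared
# regions.

#' Run the full capture analysis on aligned reads
#'
#' @param reads aligned reads for all samples (BED6+1 data.frame).
#' @param contig_lengths named vector of contig lengths.
#' @param cohort data.frame with `sample_id` and `group`; cases are the
#'   `"patient"` rows, the control group the `"control"` rows.
#' @param min_mapq mapping-quality floor (default 37).
#' @param p_threshold region-calling significance threshold (default
#'   1e-8).
#' @param fragment_extension capture fragment size (default 250).
#' @param window calling window size (default 250).
#' @param min_rpm reads-per-million floor (default 20).
#' @param alpha BH-adjusted significance level, inclusive (default 0.05).
#' @param dispersion optional fixed NB dispersion.
#' @return object of class `mbd_analysis`: list with `counts`
#'   (`region_count_matrix` after the RPM floor), `diff` (`mbd_diff`),
#'   `calls` (per-case aberrant lists), `shared` (`shared_regions`),
#'   `n_filtered_reads`, and the parameters used.
#' @export
mbd_analyze <- function(reads, contig_lengths, cohort = default_cohort(),
                        min_mapq = 37, p_threshold = 1e-8,
                        fragment_extension = 250, window = 250,
                        min_rpm = 20, alpha = 0.05, dispersion = NULL) {
  stopifnot(all(reads$sample %in% cohort$sample_id))
  filtered <- filter_reads(reads, min_mapq)
  per_sample <- lapply(split(filtered, filtered$sample), function(r) {
    call_regions(r, contig_lengths, p_threshold = p_threshold,
                 fragment_extension = fragment_extension, window = window)
  })
  merged <- merge_region_sets(per_sample)
  mat <- count_matrix(merged, filtered, samples = cohort$sample_id,
                      fragment_extension = fragment_extension,
                      contig_lengths = contig_lengths)
  mat <- rpm_filter(mat, min_rpm)
  patients <- cohort$sample_id[cohort$group == "patient"]
  controls <- cohort$sample_id[cohort$group == "control"]
  diff <- mbd_diff(mat, patients, controls, alpha = alpha,
                   dispersion = dispersion)
  calls <- call_aberrant(diff)
  shared <- build_shared(calls, mat$regions)
  structure(list(
    counts = mat, diff = diff, calls = calls, shared = shared,
    n_filtered_reads = nrow(filtered),
    params = list(min_mapq = min_mapq, p_threshold = p_threshold,
                  fragment_extension = fragment_extension, window = window,
                  min_rpm = min_rpm, alpha = alpha,
                  dispersion = attr(diff, "phi"))
  ), class = "mbd_analysis")
}

#' @export
print.mbd_analysis <- function(x, ...) {
  cat("MBD-seq differential methylation analysis\n")
  cat(sprintf("  %d filtered reads, %d regions after the %g RPM floor\n",
              x$n_filtered_reads, nrow(x$counts$counts),
              x$params$min_rpm))
  cat(sprintf("  dispersion phi = %.4g, alpha = %g (BH-adjusted)\n",
              x$params$dispersion, x$params$alpha))
  s <- summary(x$diff)
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %s: %d aberrant (%d hypo, %d hyper)\n",
                s$sample_id[i], s$n_aberrant[i], s$n_hypo[i], s$n_hyper[i]))
  }
  k2 <- shared_at_least(x$shared, 2)
  cat(sprintf("  shared in >= 2 cases: %d hypo, %d hyper\n",
              nrow(k2$hypo), nrow(k2$hyper)))
  invisible(x)
}

#' Match called regions to simulation truth
#'
#' A truth region is recovered when a called region overlaps it by at
#' least `min_frac` of the truth region's length.
#'
#' @param called region data.frame (with `region_id`).
#' @param truth truth region data.frame.
#' @param min_frac required overlap fraction of the truth length (default
#'   0.8).
#' @return data.frame: one row per truth region, with `recovered` and the
#'   matching `region_id` (NA when not recovered; the best-overlapping
#'   match when several qualify).
#' @export
match_truth <- function(called, truth, min_frac = 0.8) {
  check_regions(truth)
  out <- data.frame(truth_id = region_ids(truth), recovered = FALSE,
                    region_id = NA_character_, stringsAsFactors = FALSE)
  if (nrow(called) == 0 || nrow(truth) == 0) return(out)
  if (!"region_id" %in% names(called)) called$region_id <- region_ids(called)
  hits <- IRanges::findOverlaps(regions_to_granges(truth),
                                regions_to_granges(called))
  if (!length(hits)) return(out)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- pmin(truth$end[q], called$end[s]) - pmax(truth$start[q],
                                                 called$start[s])
  frac <- ov / (truth$end[q] - truth$start[q])
  ok <- frac >= min_frac
  for (i in unique(q[ok])) {
    cand <- which(q == i & ok)
    best <- cand[which.max(frac[cand])]
    out$recovered[i] <- TRUE
    out$region_id[i] <- called$region_id[s[best]]
  }
  out
}
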