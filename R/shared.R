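# Shared-region analysis: intersect per-case aberrant calls on the common
# merged-region universe, stratified by direction.

#' Build the shared-region report
#'
#' Regions are keyed by identity in the merged universe (every case was
#' tested on the same region set, so no positional re-intersection is
#' needed) and grouped by direction; a region aberrant in opposite
#' directions in different cases is reported once per direction.
#'
#' @param calls named list of per-case call data.frames (as from
#'   [call_aberrant()]), each with `region_id` and `direction`.
#' @param universe the merged region universe: a data.frame with
#'   `region_id`, `chrom`, `start`, `end`, or a character vector of region
#'   ids.
#' @return object of class `shared_regions`: data.frame with `region_id`,
#'   coordinates when available, `direction`, `patients` (comma-separated)
#'   and `n_patients`, sorted by `n_patients` descending then coordinate.
#' @export
build_shared <- function(calls, universe) {
  stopifnot(is.list(calls))
  ids <- if (is.data.frame(universe)) universe$region_id else
    as.character(universe)
  long <- do.call(rbind, lapply(names(calls), function(p) {
    d <- calls[[p]]
    if (is.null(d) || nrow(d) == 0) return(NULL)
    stopifnot(all(c("region_id", "direction") %in% names(d)))
    data.frame(region_id = d$region_id, direction = d$direction,
               patient = p, stringsAsFactors = FALSE)
  }))
  if (is.null(long) || nrow(long) == 0) {
    out <- data.frame(region_id = character(), direction = character(),
                      patients = character(), n_patients = integer(),
                      stringsAsFactors = FALSE)
    return(structure(out, class = c("shared_regions", "data.frame")))
  }
  if (!all(long$region_id %in% ids)) {
    stop("call references a region outside the merged universe")
  }
  stopifnot(all(long$direction %in% c("hypo", "hyper")))
  long <- unique(long)
  key <- paste(long$region_id, long$direction, sep = "\r")
  grp <- split(long$patient, key)
  parts <- strsplit(names(grp), "\r", fixed = TRUE)
  out <- data.frame(
    region_id = vapply(parts, `[`, character(1), 1),
    direction = vapply(parts, `[`, character(1), 2),
    patients = vapply(grp, function(p) paste(sort(p), collapse = ","),
                      character(1)),
    n_patients = lengths(grp),
    stringsAsFactors = FALSE)
  if (is.data.frame(universe) &&
      all(c("chrom", "start", "end") %in% names(universe))) {
    m <- match(out$region_id, universe$region_id)
    out$chrom <- universe$chrom[m]
    out$start <- universe$start[m]
    out$end <- universe$end[m]
    out <- out[order(-out$n_patients, out$chrom, out$start), , drop = FALSE]
  } else {
    out <- out[order(-out$n_patients, out$region_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  structure(out, class = c("shared_regions", "data.frame"))
}

#' @export
print.shared_regions <- function(x, ...) {
  cat(sprintf("Shared aberrant regions: %d (hypo %d, hyper %d)\n",
              nrow(x), sum(x$direction == "hypo"),
              sum(x$direction == "hyper")))
  if (nrow(x)) {
    tab <- table(factor(x$n_patients), x$direction)
    print(tab)
  }
  invisible(x)
}

#' Venn-style subset counts
#'
#' Partitions (region, direction) calls by the exact set of cases calling
#' them: each call contributes to exactly one subset cell, so the cell
#' counts sum to the number of distinct (region, direction) pairs.
#'
#' @param shared a `shared_regions` report.
#' @param patients the full vector of case ids defining the subset lattice.
#' @return data.frame with one row per non-empty patient subset: `subset`
#'   (comma-separated ids), `size`, `hypo`, `hyper`.
#' @export
venn_counts <- function(shared, patients) {
  stopifnot(inherits(shared, "shared_regions"), length(patients) >= 1)
  n <- length(patients)
  subsets <- lapply(seq_len(2^n - 1), function(mask) {
    patients[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
  })
  keys <- vapply(subsets, function(s) paste(sort(s), collapse = ","),
                 character(1))
  hypo <- integer(length(keys))
  hyper <- integer(length(keys))
  if (nrow(shared)) {
    idx <- match(shared$patients, keys)
    if (anyNA(idx)) stop("shared report contains cases outside `patients`")
    for (r in seq_len(nrow(shared))) {
      if (shared$direction[r] == "hypo") {
        hypo[idx[r]] <- hypo[idx[r]] + 1L
      } else {
        hyper[idx[r]] <- hyper[idx[r]] + 1L
      }
    }
  }
  data.frame(subset = keys, size = lengths(subsets), hypo = hypo,
             hyper = hyper, stringsAsFactors = FALSE)
}

#' Regions aberrant in at least k cases
#'
#' @param shared a `shared_regions` report.
#' @param k minimum number of cases (default 2).
#' @return list with elements `hypo` and `hyper`, each a data.frame sorted
#'   by `n_patients` descending then coordinate.
#' @export
shared_at_least <- function(shared, k = 2) {
  stopifnot(inherits(shared, "shared_regions"), k >= 1)
  sub <- shared[shared$n_patients >= k, , drop = FALSE]
  out <- lapply(c(hypo = "hypo", hyper = "hyper"), function(d) {
    r <- sub[sub$direction == d, , drop = FALSE]
    rownames(r) <- NULL
    r
  })
  out
}
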