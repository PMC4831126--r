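# Bisulfite amplicon validation arm: inline-index demultiplexing,
# conversion-aware ungapped alignment to the amplicon reference, per-CpG
# and per-amplicon methylation summaries, and MBD-vs-BS concordance.

#' Demultiplex reads on their inline index prefix
#'
#' Exact prefix match over the first `index_len` bases; the matched prefix
#' is stripped.  The function refuses to run if truncating the indexes to
#' `index_len` makes any pair identical.
#'
#' @param reads character vector of read sequences, or a data.frame with a
#'   `sequence` column (as from [simulate_bisulfite_reads()]).
#' @param index_table data.frame with columns `sample_id` and `index`.
#' @param index_len prefix length used for matching; defaults to the full
#'   index length.
#' @return list with `assigned` (named list of index-stripped reads per
#'   sample; every sample in the table is present), `unassigned` (reads
#'   with unmatched prefix) and `counts`.
#' @export
demultiplex <- function(reads, index_table, index_len = NULL) {
  if (is.data.frame(reads)) reads <- reads$sequence
  stopifnot(is.character(reads),
            all(c("sample_id", "index") %in% names(index_table)))
  if (is.null(index_len)) index_len <- min(nchar(index_table$index))
  stopifnot(index_len >= 1, index_len <= min(nchar(index_table$index)))
  pref <- substr(index_table$index, 1, index_len)
  if (anyDuplicated(pref)) {
    stop("index table is ambiguous at the chosen prefix length")
  }
  hit <- match(substr(reads, 1, index_len), pref)
  assigned <- lapply(seq_len(nrow(index_table)), function(i) {
    r <- reads[!is.na(hit) & hit == i]
    substr(r, index_len + 1, nchar(r))
  })
  names(assigned) <- index_table$sample_id
  unassigned <- reads[is.na(hit)]
  list(assigned = assigned, unassigned = unassigned,
       counts = c(setNames(lengths(assigned), index_table$sample_id),
                  unassigned = length(unassigned)))
}

#' Conversion-aware ungapped alignment of bisulfite reads to an amplicon
#'
#' Each read is compared at every offset against the reference under two
#' conversion models: forward (a reference C may read T without penalty)
#' and reverse (the reverse complement of the read is compared, and a
#' reference G may read A without penalty).  The placement with the fewest
#' counted mismatches wins (forward preferred on ties, then the smaller
#' offset) and is accepted when its mismatch fraction is at most
#' `max_mismatch_frac`.  At each covered CpG, a forward read calls
#' methylated on C and unmethylated on T (other bases give no call); a
#' reverse read calls on the paired G/A one base downstream.
#'
#' @param reads character vector of index-stripped read sequences.
#' @param amplicon an [amplicon_spec()].
#' @param max_mismatch_frac maximum counted-mismatch fraction (default
#'   0.1).
#' @param min_read_length reads shorter than this are rejected (default
#'   20).
#' @return list with `alignments` (data.frame `read`, `offset` 0-based,
#'   `strand`, `mismatches`; NA rows for rejected reads), `calls`
#'   (data.frame `read`, `cpg_pos` 1-based, `call` "meth"/"unmeth") and
#'   `n_rejected`.
#' @export
bisulfite_align <- function(reads, amplicon, max_mismatch_frac = 0.1,
                            min_read_length = 20) {
  stopifnot(inherits(amplicon, "amplicon_spec"), is.character(reads))
  ref <- strsplit(amplicon$sequence, "")[[1]]
  L <- length(ref)
  cpg <- amplicon$cpg_pos
  n <- length(reads)
  offset <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n)
  mism <- rep(NA_integer_, n)
  calls <- vector("list", n)

  lens <- nchar(reads)
  cache <- new.env(parent = emptyenv())
  window_mats <- function(rl) {
    key <- as.character(rl)
    if (!is.null(cache[[key]])) return(cache[[key]])
    n_off <- L - rl + 1L
    idx <- outer(seq_len(rl), 0:(n_off - 1L), `+`)   # rl x n_off
    W <- matrix(ref[idx], rl, n_off)
    val <- list(W = W, WC = W == "C", WG = W == "G", n_off = n_off)
    cache[[key]] <- val
    val
  }

  for (r in seq_len(n)) {
    rl <- lens[r]
    if (rl < min_read_length || rl > L) next
    m <- window_mats(rl)
    rb <- strsplit(reads[r], "")[[1]]
    rcb <- rev(chartr("ACGT", "TGCA", rb))
    mmF <- colSums((m$W != rb) & !(m$WC & (rb == "T")))
    mmR <- colSums((m$W != rcb) & !(m$WG & (rcb == "A")))
    bF <- which.min(mmF)
    bR <- which.min(mmR)
    if (mmF[bF] <= mmR[bR]) {
      best <- mmF[bF]; o <- bF - 1L; st <- "+"
    } else {
      best <- mmR[bR]; o <- bR - 1L; st <- "-"
    }
    if (best / rl > max_mismatch_frac) next
    offset[r] <- o
    strand[r] <- st
    mism[r] <- best
    if (st == "+") {
      cov <- cpg[cpg >= o + 1L & cpg <= o + rl]
      base <- rb[cov - o]
      call <- ifelse(base == "C", "meth", ifelse(base == "T", "unmeth", NA))
    } else {
      # a reverse read informs on the CpG through its paired G
      cov <- cpg[cpg + 1L >= o + 1L & cpg + 1L <= o + rl]
      base <- rcb[cov + 1L - o]
      call <- ifelse(base == "G", "meth", ifelse(base == "A", "unmeth", NA))
    }
    ok <- !is.na(call)
    if (any(ok)) {
      calls[[r]] <- data.frame(read = r, cpg_pos = cov[ok],
                               call = call[ok], stringsAsFactors = FALSE)
    }
  }
  call_df <- if (any(!vapply(calls, is.null, logical(1)))) {
    do.call(rbind, calls)
  } else {
    data.frame(read = integer(), cpg_pos = integer(), call = character(),
               stringsAsFactors = FALSE)
  }
  rownames(call_df) <- NULL
  list(alignments = data.frame(read = seq_len(n), offset = offset,
                               strand = strand, mismatches = mism,
                               stringsAsFactors = FALSE),
       calls = call_df,
       n_rejected = sum(is.na(offset)))
}

#' Summarize per-CpG calls into amplicon methylation
#'
#' Per CpG: methylated fraction `m / (m + u)`.  The overall amplicon value
#' is the unweighted mean of per-CpG fractions over CpGs with coverage at
#' least `min_cov`; CpGs below the floor are excluded and reported.
#'
#' @param calls data.frame of per-CpG calls (`cpg_pos`, `call`) as from
#'   [bisulfite_align()].
#' @param amplicon the [amplicon_spec()] the calls refer to.
#' @param sample_id optional sample label carried through.
#' @param min_cov minimum per-CpG coverage for inclusion in the overall
#'   mean (default 10).
#' @return object of class `amplicon_methylation`: list with `sample_id`,
#'   `amplicon`, `per_cpg` (data.frame `cpg_pos`, `n_meth`, `n_unmeth`,
#'   `coverage`, `fraction`), `overall` (NA, with `overall_defined =
#'   FALSE`, when no CpG reaches `min_cov`) and `low_coverage_cpgs`.
#' @export
summarize_amplicon <- function(calls, amplicon, sample_id = NA_character_,
                               min_cov = 10) {
  stopifnot(inherits(amplicon, "amplicon_spec"), is.data.frame(calls))
  cpg <- amplicon$cpg_pos
  n_meth <- n_unmeth <- integer(length(cpg))
  if (nrow(calls)) {
    stopifnot(all(calls$cpg_pos %in% cpg),
              all(calls$call %in% c("meth", "unmeth")))
    mt <- table(factor(calls$cpg_pos[calls$call == "meth"], levels = cpg))
    ut <- table(factor(calls$cpg_pos[calls$call == "unmeth"], levels = cpg))
    n_meth <- as.integer(mt)
    n_unmeth <- as.integer(ut)
  }
  coverage <- n_meth + n_unmeth
  fraction <- ifelse(coverage > 0, n_meth / coverage, NA_real_)
  usable <- coverage >= min_cov
  overall <- if (any(usable)) mean(fraction[usable]) else NA_real_
  structure(list(
    sample_id = sample_id, amplicon = amplicon$name,
    per_cpg = data.frame(cpg_pos = cpg, n_meth = n_meth,
                         n_unmeth = n_unmeth, coverage = coverage,
                         fraction = fraction),
    overall = overall, overall_defined = any(usable),
    low_coverage_cpgs = cpg[!usable], min_cov = min_cov
  ), class = "amplicon_methylation")
}

#' @export
print.amplicon_methylation <- function(x, ...) {
  cat(sprintf("Amplicon %s, sample %s: %d CpGs, overall methylation %s\n",
              x$amplicon, x$sample_id, nrow(x$per_cpg),
              if (x$overall_defined) sprintf("%.3f", x$overall) else
                "undefined (coverage below floor)"))
  invisible(x)
}

#' MBD-seq versus bisulfite log2-ratio concordance
#'
#' For each non-control individual and locus, forms the bisulfite log2
#' ratio `log2((overall + eps) / (control mean overall + eps))` and the
#' capture log2 ratio `log2((RPM + eps) / (control mean RPM + eps))`, and
#' their Pearson correlation across all (individual, locus) pairs.
#'
#' @param bs data.frame with `sample_id`, `locus`, `overall` (bisulfite
#'   methylation fraction per amplicon).
#' @param mbd data.frame with `sample_id`, `locus`, `rpm`.
#' @param controls control sample ids (present in both tables).
#' @param eps pseudo-value avoiding log of zero (default 0.01).
#' @return list with `table` (data.frame `sample_id`, `locus`, `bs_log2`,
#'   `mbd_log2`), `r` (Pearson correlation; NA with `degenerate = TRUE`
#'   when either side has zero variance) and `degenerate`.
#' @export
concordance <- function(bs, mbd, controls, eps = 0.01) {
  stopifnot(all(c("sample_id", "locus", "overall") %in% names(bs)),
            all(c("sample_id", "locus", "rpm") %in% names(mbd)),
            length(controls) >= 1)
  loci <- sort(unique(c(bs$locus, mbd$locus)))
  samples <- sort(unique(c(bs$sample_id, mbd$sample_id)))
  key_bs <- paste(bs$sample_id, bs$locus)
  key_mbd <- paste(mbd$sample_id, mbd$locus)
  need <- as.vector(outer(samples, loci, paste))
  if (!all(need %in% key_bs) || !all(need %in% key_mbd)) {
    stop("incomplete pairing: every (sample, locus) needs both assays")
  }
  stopifnot(all(controls %in% samples))
  cases <- setdiff(samples, controls)
  bs_ctrl <- vapply(loci, function(l) {
    mean(bs$overall[bs$locus == l & bs$sample_id %in% controls])
  }, numeric(1))
  mbd_ctrl <- vapply(loci, function(l) {
    mean(mbd$rpm[mbd$locus == l & mbd$sample_id %in% controls])
  }, numeric(1))
  rows <- expand.grid(sample_id = cases, locus = loci,
                      stringsAsFactors = FALSE)
  rows$bs_log2 <- log2(
    (bs$overall[match(paste(rows$sample_id, rows$locus), key_bs)] + eps) /
      (bs_ctrl[rows$locus] + eps))
  rows$mbd_log2 <- log2(
    (mbd$rpm[match(paste(rows$sample_id, rows$locus), key_mbd)] + eps) /
      (mbd_ctrl[rows$locus] + eps))
  degenerate <- sd(rows$bs_log2) == 0 || sd(rows$mbd_log2) == 0
  r <- if (degenerate) NA_real_ else cor(rows$bs_log2, rows$mbd_log2)
  list(table = rows, r = r, degenerate = degenerate)
}
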