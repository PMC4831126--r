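# Independent brute-force oracles used by the dual-route checks.

# Position-by-position motif scan (forward + optional reverse complement).
brute_count_motif <- function(seq, motif = "TGCCGC", both_strands = TRUE) {
  count_one <- function(s, m) {
    n <- nchar(s)
    k <- nchar(m)
    if (n < k) return(0L)
    hits <- 0L
    for (i in seq_len(n - k + 1)) {
      if (substr(s, i, i + k - 1) == m) hits <- hits + 1L
    }
    hits
  }
  rc <- mbddiff::reverse_complement(motif)
  total <- count_one(seq, motif)
  if (both_strands && rc != motif) total <- total + count_one(seq, rc)
  total
}

# Quadratic all-pairs fragment/region overlap counter.
brute_overlap_counts <- function(regions, frags) {
  counts <- integer(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(frags))) {
      if (regions$chrom[i] == frags$chrom[j] &&
          min(regions$end[i], frags$end[j]) >
          max(regions$start[i], frags$start[j])) {
        counts[i] <- counts[i] + 1L
      }
    }
  }
  counts
}

# BH adjustment straight from the step-up definition.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (r in seq_len(m)) {
    i <- o[r]
    adj[i] <- min(vapply(r:m, function(j) p[o[j]] * m / j, numeric(1)), 1)
  }
  adj
}

# Fixpoint single-linkage region merging by quadratic pair scanning and
# label propagation (independent of the package's union-find route).
brute_merge <- function(regions, frac = 0.5) {
  cur <- unique(regions[order(regions$chrom, regions$start, regions$end),
                        c("chrom", "start", "end")])
  rownames(cur) <- NULL
  repeat {
    n <- nrow(cur)
    if (n <= 1) break
    qualifies <- function(i, j) {
      if (cur$chrom[i] != cur$chrom[j]) return(FALSE)
      ov <- min(cur$end[i], cur$end[j]) - max(cur$start[i], cur$start[j])
      shorter <- min(cur$end[i] - cur$start[i], cur$end[j] - cur$start[j])
      ov > frac * shorter
    }
    lab <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          if (lab[i] != lab[j] && qualifies(i, j)) {
            l <- min(lab[i], lab[j])
            lab[lab == lab[i] | lab == lab[j]] <- l
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    if (length(unique(lab)) == n) break
    cur <- do.call(rbind, lapply(unique(lab), function(l) {
      data.frame(chrom = cur$chrom[lab == l][1],
                 start = min(cur$start[lab == l]),
                 end = max(cur$end[lab == l]), stringsAsFactors = FALSE)
    }))
    cur <- unique(cur[order(cur$chrom, cur$start, cur$end), , drop = FALSE])
    rownames(cur) <- NULL
  }
  cur
}

# Duplicate-removal oracle: group reads by (sample, chrom, 5' pos, strand).
brute_filter <- function(reads, min_mapq = 37) {
  keep <- reads[reads$mapq >= min_mapq, , drop = FALSE]
  if (nrow(keep) == 0) return(keep)
  fp <- ifelse(keep$strand == "+", keep$start, keep$end)
  key <- paste(keep$sample, keep$chrom, fp, keep$strand)
  out <- keep[match(unique(key), key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exact-test oracle: conditional distribution built by explicit convolution
# of the n control NB pmfs (no closed-form NB-sum shortcut).
brute_exact_nb_p <- function(yp, yc, phi) {
  n <- length(yc)
  total <- yp + sum(yc)
  mu <- total / (n + 1)
  k <- 0:total
  pmf1 <- if (phi > 0) dnbinom(k, size = 1 / phi, mu = mu) else dpois(k, mu)
  ctrl <- pmf1
  if (n > 1) {
    for (i in 2:n) {
      new <- numeric(total + 1)
      for (t in 0:total) {
        new[t + 1] <- sum(ctrl[seq_len(t + 1)] * pmf1[(t:0) + 1])
      }
      ctrl <- new
    }
  }
  joint <- pmf1 * rev(ctrl)
  joint <- joint / sum(joint)
  sum(joint[joint <= joint[yp + 1] * (1 + 1e-10)])
}

# Small random toy genome regions for annotation tests.
random_regions <- function(n, contigs = c(a = 10000, b = 8000),
                           max_len = 500) {
  chrom <- sample(names(contigs), n, replace = TRUE)
  len <- sample(50:max_len, n, replace = TRUE)
  start <- floor(runif(n, 0, contigs[chrom] - len))
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + len), stringsAsFactors = FALSE)
}

small_cohort <- function() {
  data.frame(
    sample_id = c("P1", "C1", "C2", "C3", "C4", "C5"),
    group = c("patient", rep("control", 5)),
    stringsAsFactors = FALSE)
}
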