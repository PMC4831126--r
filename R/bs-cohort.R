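# End-to-end bisulfite validation cohort: a panel of amplicons at loci
# whose methylation multipliers drive both the capture counts and the
# bisulfite conversion probabilities, so the two assays can be compared.

# Deterministic amplicon sequence with CpGs planted at spaced positions.
make_amplicon_sequence <- function(length_bp, n_cpg) {
  b <- random_bases(length_bp, probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3))
  b <- deplete_cpg(b)
  pos <- as.integer(round(seq(10, length_bp - 10, length.out = n_cpg)))
  for (p in pos) {
    b[p] <- "C"
    b[p + 1L] <- "G"
    if (b[p - 1L] == "C") b[p - 1L] <- "A"   # avoid accidental extra CpG
    if (b[p + 2L] == "G") b[p + 2L] <- "T"
  }
  paste(b, collapse = "")
}

#' Default bisulfite validation multipliers
#'
#' Eight loci by nine samples (3 patients, 3 heterozygotes, 3 controls).
#' Loci span strong, intermediate and absent hypomethylation across
#' different patient subsets, one null locus, and a mild heterozygote
#' effect, giving the spread of true log2 ratios a concordance analysis
#' needs.
#'
#' @return numeric matrix, loci in rows (`locus1`..`locus8`), samples in
#'   columns.
#' @export
default_bs_multipliers <- function() {
  samples <- default_index_table()$sample_id
  m <- matrix(1, 8, length(samples),
              dimnames = list(paste0("locus", 1:8), samples))
  m["locus1", c("P1", "P2", "P3")] <- 0.1
  m["locus2", c("P1", "P2")] <- 0.3
  m["locus3", "P1"] <- 0.5
  m["locus4", c("P2", "P3")] <- 0.5
  m["locus5", "P3"] <- 0.3
  m["locus6", c("P1", "P2", "P3")] <- 0.7
  # locus7 is a null locus
  m["locus8", c("P1", "P2", "P3")] <- 0.5
  m["locus8", c("H1", "H2", "H3")] <- 0.8
  m
}

#' Simulate the bisulfite validation cohort
#'
#' Builds a panel of amplicons, simulates indexed bisulfite reads for every
#' sample at conversion probabilities `base_meth * multiplier` (capped at
#' 1), and draws matching capture counts `NB(mean = capture_mean *
#' multiplier, phi)` per locus and sample, reported as RPM against a fixed
#' library size of one million.
#'
#' @param seed RNG seed.
#' @param multipliers loci x samples truth matrix (default
#'   [default_bs_multipliers()]).
#' @param base_meth baseline methylation level of the loci (default 0.8).
#' @param n_reads bisulfite reads per amplicon per sample (default 200).
#' @param capture_mean expected capture count per locus at multiplier 1
#'   (default 500).
#' @param phi capture-count overdispersion (default 0.1).
#' @param amplicon_length amplicon length in bases (default 220).
#' @param n_cpg CpGs per amplicon (default 10).
#' @param read_length bisulfite read length (default 40).
#' @param error_rate bisulfite read substitution error rate (default
#'   0.002).
#' @return list with `amplicons` (list of [amplicon_spec()]), `reads`
#'   (named list: per amplicon, one pooled data.frame of indexed reads from
#'   all samples), `mbd` (data.frame `sample_id`, `locus`, `rpm`),
#'   `index_table`, `multipliers`, `base_meth`.
#' @export
simulate_bs_cohort <- function(seed = 1L,
                               multipliers = default_bs_multipliers(),
                               base_meth = 0.8, n_reads = 200,
                               capture_mean = 500, phi = 0.1,
                               amplicon_length = 220, n_cpg = 10,
                               read_length = 40, error_rate = 0.002) {
  index_table <- default_index_table()
  stopifnot(all(colnames(multipliers) %in% index_table$sample_id))
  loci <- rownames(multipliers)
  samples <- colnames(multipliers)
  with_seed(seed, {
    amplicons <- lapply(loci, function(l) {
      amplicon_spec(l, make_amplicon_sequence(amplicon_length, n_cpg))
    })
    names(amplicons) <- loci
    read_seeds <- matrix(
      sample.int(.Machine$integer.max, length(loci) * length(samples)),
      length(loci), dimnames = list(loci, samples))
    mbd_counts <- matrix(
      draw_region_counts(as.vector(capture_mean * multipliers), phi),
      nrow(multipliers), dimnames = dimnames(multipliers))
    reads <- lapply(loci, function(l) {
      per_sample <- lapply(samples, function(s) {
        p <- min(1, base_meth * multipliers[l, s])
        simulate_bisulfite_reads(
          amplicons[[l]], meth_prob = p, n_reads = n_reads,
          index = index_table$index[index_table$sample_id == s],
          index_table = index_table, seed = read_seeds[l, s],
          error_rate = error_rate, read_length = read_length)
      })
      do.call(rbind, per_sample)
    })
    names(reads) <- loci
    mbd <- data.frame(
      sample_id = rep(samples, each = length(loci)),
      locus = rep(loci, length(samples)),
      rpm = as.vector(mbd_counts),
      stringsAsFactors = FALSE)
    list(amplicons = amplicons, reads = reads, mbd = mbd,
         index_table = index_table, multipliers = multipliers,
         base_meth = base_meth)
  })
}

#' Run the bisulfite validation analysis on a simulated cohort
#'
#' Demultiplexes each amplicon's pooled reads, aligns per sample, forms
#' per-amplicon overall methylation, and computes MBD-vs-BS log2-ratio
#' concordance against the control group.
#'
#' @param sim output of [simulate_bs_cohort()].
#' @param min_cov per-CpG coverage floor for the overall value (default
#'   10).
#' @param max_mismatch_frac alignment rejection threshold (default 0.1).
#' @return list with `bs` (data.frame `sample_id`, `locus`, `overall`),
#'   `summaries` (nested list of `amplicon_methylation` objects),
#'   `concordance` (as from [concordance()]).
#' @export
run_bs_validation <- function(sim, min_cov = 10, max_mismatch_frac = 0.1) {
  index_table <- sim$index_table
  controls <- index_table$sample_id[index_table$group == "control"]
  rows <- list()
  summaries <- list()
  for (l in names(sim$reads)) {
    dmx <- demultiplex(sim$reads[[l]], index_table)
    summaries[[l]] <- list()
    for (s in index_table$sample_id) {
      aln <- bisulfite_align(dmx$assigned[[s]], sim$amplicons[[l]],
                             max_mismatch_frac = max_mismatch_frac)
      sm <- summarize_amplicon(aln$calls, sim$amplicons[[l]],
                               sample_id = s, min_cov = min_cov)
      summaries[[l]][[s]] <- sm
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, locus = l, overall = sm$overall,
        stringsAsFactors = FALSE)
    }
  }
  bs <- do.call(rbind, rows)
  conc <- concordance(bs, sim$mbd, controls)
  list(bs = bs, summaries = summaries, concordance = conc)
}
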