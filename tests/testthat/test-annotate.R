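# Annotation: motif counting, enrichment summaries, AMR scoring, CpG
# islands, transcript mapping.

test_that("motif counting handles construction cases and N", {
  expect_equal(count_motif(""), 0L)
  expect_equal(count_motif("TGCCGCTGCCGC"), 2L)
  expect_equal(count_motif("GCGGCA", both_strands = TRUE), 1L)
  expect_equal(count_motif("GCGGCA", both_strands = FALSE), 0L)
  expect_equal(count_motif("TGNCGC"), 0L)
  # palindromic motif is not double-counted
  expect_equal(count_motif("ACGT", motif = "ACGT"), 1L)
  expect_error(count_motif("ACGT", motif = ""), "non-empty")
})

test_that("motif counts equal a position-by-position scan", {
  set.seed(17)
  for (rep in 1:2) {
    seqs <- vapply(1:100, function(i) {
      paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE,
                   prob = c(0.2, 0.3, 0.3, 0.2)), collapse = "")
    }, character(1))
    expect_equal(count_motif(seqs),
                 vapply(seqs, brute_count_motif, integer(1),
                        USE.NAMES = FALSE))
    expect_equal(count_motif(seqs, both_strands = FALSE),
                 vapply(seqs, brute_count_motif, integer(1),
                        both_strands = FALSE, USE.NAMES = FALSE))
  }
})

test_that("motif histogram matches simulation ground truth", {
  cfg <- sim_config(seed = 23, n_contigs = 1, contig_length = 2e5,
                    n_regions = 80, motif_rate = 4,
                    effects = data.frame(region_index = 1:80,
                                         sample_id = "P1",
                                         multiplier = 0.5))
  sim <- simulate_genome(cfg)
  hist <- motif_distribution(sim$truth$regions, sim$genome)
  expect_equal(sum(hist$n_regions), 80)
  truth_tab <- tabulate(sim$truth$regions$motif_count + 1L,
                        nbins = max(sim$truth$regions$motif_count) + 1L)
  expect_equal(hist$n_regions, truth_tab)
  # motif-free set: all mass at zero
  cfg0 <- sim_config(seed = 24, n_contigs = 1, contig_length = 1e5,
                     n_regions = 20, motif_rate = 0)
  sim0 <- simulate_genome(cfg0)
  h0 <- motif_distribution(sim0$truth$regions, sim0$genome)
  expect_equal(h0$n_regions[h0$motif_count == 0], 20)
  # out-of-bounds region rejected
  bad <- data.frame(chrom = names(sim0$genome)[1], start = 0,
                    end = nchar(sim0$genome[1]) + 10)
  expect_error(motif_distribution(bad, sim0$genome), "beyond")
})

test_that("threshold fractions reproduce printed-count arithmetic", {
  expect_equal(fraction_at_least(c(rep(2, 28), rep(1, 24)), 2), 100 * 28 / 52)
  expect_equal(round(fraction_at_least(c(rep(2, 28), rep(1, 24)), 2)), 54)
  expect_equal(fraction_at_least(rep(c(3, 0), c(3560, 17123 - 3560)), 2),
               100 * 3560 / 17123)
  expect_equal(fraction_at_least(rep(c(2, 0), c(18, 13)), 2), 100 * 18 / 31)
  expect_equal(fraction_at_least(c(0, 5, 2), 0), 100)
  expect_error(fraction_at_least(integer(0)), "non-empty")
})

test_that("motif enrichment separates DMRs from background regions", {
  ok <- 0L
  for (seed in 1:20) {
    cfg <- sim_config(seed = seed + 300, n_contigs = 1,
                      contig_length = 2e5, n_regions = 60, motif_rate = 4,
                      background_motif_rate = 0.5)
    sim <- simulate_genome(cfg)
    counts <- count_motif(region_sequences(sim$genome, sim$truth$regions))
    dmr <- sim$truth$regions$is_dmr
    f_dmr <- fraction_at_least(counts[dmr], 2)
    f_bg <- fraction_at_least(counts[!dmr], 2)
    ok <- ok + (f_dmr > f_bg)
  }
  expect_gte(ok, 19)
})

test_that("AMR scoring is dataset-level and strict at the threshold", {
  regions <- data.frame(chrom = "c1", start = c(100, 1000),
                        end = c(500, 1400), stringsAsFactors = FALSE)
  # no datasets: all scores zero
  expect_equal(amr_overlap(regions, list())$scores$n_datasets, c(0, 0))
  # three intervals of ONE dataset overlapping a region count once
  ds <- data.frame(chrom = "c1", start = c(100, 200, 300),
                   end = c(150, 260, 360), stringsAsFactors = FALSE)
  expect_equal(amr_overlap(regions, list(ds))$scores$n_datasets, c(1, 0))
  # score equal to the threshold is NOT counted in the fraction
  five <- replicate(5, data.frame(chrom = "c1", start = 100, end = 500,
                                  stringsAsFactors = FALSE),
                    simplify = FALSE)
  out5 <- amr_overlap(regions, five, threshold = 5)
  expect_equal(out5$scores$n_datasets, c(5, 0))
  expect_equal(out5$fraction_above, 0)
  out6 <- amr_overlap(regions, c(five, five[1]), threshold = 5)
  expect_equal(out6$fraction_above, 50)
})

test_that("AMR scores match brute force and are monotone in datasets", {
  set.seed(29)
  regions <- random_regions(30)
  datasets <- lapply(1:8, function(i) random_regions(10))
  out <- amr_overlap(regions, datasets)
  brute <- rowSums(vapply(datasets, function(ds) {
    brute_overlap_counts(regions, ds) > 0
  }, logical(nrow(regions))))
  expect_equal(out$scores$n_datasets, unname(brute))
  more <- amr_overlap(regions, c(datasets, list(random_regions(10))))
  expect_true(all(more$scores$n_datasets >= out$scores$n_datasets))
})

test_that("CpG island detection: degenerate and closed-form cases", {
  polyA <- c(cA = strrep("A", 1000))
  expect_equal(nrow(detect_cpg_islands(polyA)), 0)
  # a pure (CG)_100 repeat: GC = 1, O/E = n_CG * L / (n_C * n_G) > 0.6
  cg <- c(cg = paste0(strrep("AT", 200), strrep("CG", 100),
                      strrep("AT", 200)))
  isl <- detect_cpg_islands(cg)
  expect_equal(nrow(isl), 1)
  expect_lte(isl$start, 400)
  expect_gte(isl$end, 600)
  # island coordinates mirror under reverse complement
  cfg <- sim_config(seed = 31, n_contigs = 1, contig_length = 3e4,
                    n_regions = 6, effects = NULL)
  sim <- simulate_genome(cfg)
  fwd <- detect_cpg_islands(sim$genome)
  rcg <- setNames(reverse_complement(sim$genome), names(sim$genome))
  rev <- detect_cpg_islands(rcg)
  L <- nchar(sim$genome[[1]])
  mirrored <- data.frame(chrom = rev$chrom, start = L - rev$end,
                         end = L - rev$start, stringsAsFactors = FALSE)
  mirrored <- mirrored[order(mirrored$start), , drop = FALSE]
  rownames(mirrored) <- NULL
  expect_equal(fwd[, c("chrom", "start", "end")], mirrored)
  # simulated methylated regions are CpG-island-like by construction
  m <- match_truth(fwd, sim$truth$regions, min_frac = 0.5)
  expect_true(all(m$recovered))
})

test_that("transcript mapping uses strict 1 kb and strand-aware 5' ends", {
  tr <- data.frame(chrom = "c1", start = c(5000, 9000),
                   end = c(7000, 12000), strand = c("+", "-"),
                   stringsAsFactors = FALSE)
  # centre exactly at a 5' end: distance 0, proximal
  r0 <- data.frame(chrom = "c1", start = 4900, end = 5100)
  out0 <- map_to_transcripts(r0, tr)
  expect_equal(out0$distance_to_5prime, 0)
  expect_true(out0$tss_proximal)
  # centre exactly 1000 away: still proximal (strict "more than 1 kb")
  r1 <- data.frame(chrom = "c1", start = 3900, end = 4100)
  expect_true(map_to_transcripts(r1, tr)$tss_proximal)
  r2 <- data.frame(chrom = "c1", start = 3898, end = 4100)
  expect_false(map_to_transcripts(r2, tr)$tss_proximal)
  # minus-strand 5' end is end - 1
  r3 <- data.frame(chrom = "c1", start = 11899, end = 12099)
  expect_equal(map_to_transcripts(r3, tr)$distance_to_5prime, 0)
  expect_error(map_to_transcripts(r0, tr[0, ]), "empty")
})

test_that("transcript mapping matches a brute-force minimum", {
  set.seed(37)
  for (rep in 1:5) {
    regions <- random_regions(25)
    tr <- random_regions(12)
    tr$strand <- sample(c("+", "-"), nrow(tr), replace = TRUE)
    out <- suppressWarnings(map_to_transcripts(regions, tr))
    for (i in sample(nrow(regions), 10)) {
      centre <- floor((regions$start[i] + regions$end[i]) / 2)
      same <- tr[tr$chrom == regions$chrom[i], , drop = FALSE]
      if (nrow(same) == 0) {
        expect_true(is.na(out$distance_to_5prime[i]))
        next
      }
      tss <- ifelse(same$strand == "+", same$start, same$end - 1)
      expect_equal(out$distance_to_5prime[i], min(abs(centre - tss)))
      expect_equal(out$within_transcript[i],
                   any(centre >= same$start & centre < same$end))
    }
  }
})
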