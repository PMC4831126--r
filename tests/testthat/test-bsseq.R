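# Bisulfite validation arm: demultiplexing, conversion-aware alignment,
# per-CpG summaries, concordance.

test_amp <- function(seed = 1) {
  set.seed(seed)
  amplicon_spec("amp", mbddiff:::make_amplicon_sequence(180, 8))
}

test_that("demultiplexing assigns by exact prefix and conserves reads", {
  tab <- default_index_table()
  reads <- c(paste0("ACCAAT", "TTTT"), paste0("AGAGAT", "GGGG"),
             paste0("NNNNNN", "AAAA"))
  out <- demultiplex(reads, tab)
  expect_equal(out$assigned$P1, "TTTT")
  expect_equal(out$assigned$P2, "GGGG")
  expect_equal(out$unassigned, "NNNNNNAAAA")
  expect_equal(sum(lengths(out$assigned)) + length(out$unassigned),
               length(reads))
  # ambiguous truncation refused
  tab2 <- data.frame(sample_id = c("a", "b"),
                     index = c("ACCAAT", "ACCAGT"),
                     stringsAsFactors = FALSE)
  expect_error(demultiplex(reads, tab2, index_len = 4), "ambiguous")
  expect_equal(length(demultiplex(reads, tab2, index_len = 5)$unassigned), 2)
})

test_that("demultiplex partition matches brute force on random reads", {
  set.seed(43)
  tab <- default_index_table()
  for (rep in 1:3) {
    n <- 300
    pick <- sample(c(tab$index, "TTTTTT", "ACGTAC"), n, replace = TRUE)
    body <- vapply(1:n, function(i) {
      paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
            collapse = "")
    }, character(1))
    reads <- paste0(pick, body)
    out <- demultiplex(reads, tab)
    expect_equal(sum(lengths(out$assigned)) + length(out$unassigned), n)
    for (s in tab$sample_id) {
      idx <- tab$index[tab$sample_id == s]
      expect_equal(sort(out$assigned[[s]]), sort(body[pick == idx]))
    }
  }
})

test_that("alignment is conversion-aware on exact constructions", {
  amp <- test_amp()
  ref <- amp$sequence
  # unconverted read (all CpG C retained, non-CpG C retained): offset 0;
  # non-CpG C vs reference C is C==C, so zero mismatches, all CpGs meth
  aln <- bisulfite_align(ref, amp)
  expect_equal(aln$alignments$offset, 0)
  expect_equal(aln$alignments$mismatches, 0)
  expect_equal(aln$alignments$strand, "+")
  expect_true(all(aln$calls$call == "meth"))
  expect_equal(sort(aln$calls$cpg_pos), amp$cpg_pos)
  # fully converted read: C/T wobble is not counted as mismatch
  conv <- chartr("C", "T", ref)
  aln2 <- bisulfite_align(conv, amp)
  expect_equal(aln2$alignments$mismatches, 0)
  expect_true(all(aln2$calls$call == "unmeth"))
  # fully converted reverse-complement read aligns on the minus strand
  rc <- reverse_complement(chartr("G", "A", ref))
  aln3 <- bisulfite_align(rc, amp)
  expect_equal(aln3$alignments$strand, "-")
  expect_equal(aln3$alignments$mismatches, 0)
  expect_true(all(aln3$calls$call == "unmeth"))
  # garbage is rejected and counted
  aln4 <- bisulfite_align(strrep("A", 50), amp)
  expect_equal(aln4$n_rejected, 1)
  # too-short reads are rejected
  expect_equal(bisulfite_align("ACGTACGTAC", amp)$n_rejected, 1)
})

test_that("alignment placements match a brute-force all-offsets oracle", {
  amp <- test_amp(7)
  ref <- strsplit(amp$sequence, "")[[1]]
  L <- length(ref)
  set.seed(19)
  reads <- simulate_bisulfite_reads(amp, 0.5, 60, "ACCAAT", seed = 20,
                                    error_rate = 0.01, read_length = 45)
  stripped <- substr(reads$sequence, 7, nchar(reads$sequence))
  aln <- bisulfite_align(stripped, amp)
  for (r in seq_along(stripped)) {
    rb <- strsplit(stripped[r], "")[[1]]
    rcb <- rev(chartr("ACGT", "TGCA", rb))
    rl <- length(rb)
    best <- Inf
    b_off <- NA
    b_st <- NA
    for (o in 0:(L - rl)) {
      w <- ref[(o + 1):(o + rl)]
      mf <- sum(w != rb & !(w == "C" & rb == "T"))
      mr <- sum(w != rcb & !(w == "G" & rcb == "A"))
      if (mf < best) { best <- mf; b_off <- o; b_st <- "+" }
      if (mr < best) { best <- mr; b_off <- o; b_st <- "-" }
    }
    if (best / rl > 0.1) {
      expect_true(is.na(aln$alignments$offset[r]))
    } else {
      expect_equal(aln$alignments$mismatches[r], best)
      expect_equal(aln$alignments$offset[r], b_off)
    }
  }
})

test_that("simulated methylation levels are recovered through alignment", {
  amp <- test_amp(3)
  reads <- simulate_bisulfite_reads(amp, 0.3, 1000, "ACCAAT", seed = 5,
                                    error_rate = 0, read_length = 60)
  stripped <- substr(reads$sequence, 7, nchar(reads$sequence))
  aln <- bisulfite_align(stripped, amp)
  sm <- summarize_amplicon(aln$calls, amp, min_cov = 100)
  expect_equal(sm$sample_id, NA_character_)
  for (i in seq_len(nrow(sm$per_cpg))) {
    cov <- sm$per_cpg$coverage[i]
    if (cov < 100) next
    se <- sqrt(0.3 * 0.7 / cov)
    expect_lt(abs(sm$per_cpg$fraction[i] - 0.3), 3 * se)
  }
  expect_lt(abs(sm$overall - 0.3), 0.06)
})

test_that("amplicon summaries tally calls exactly", {
  amp <- amplicon_spec("two", "ATTACGTTTAGGGATTTTAAACGTTTAGGAT")
  p <- amp$cpg_pos
  expect_equal(length(p), 2)
  calls <- data.frame(
    read = 1:30,
    cpg_pos = rep(p, c(10, 20)),
    call = c(rep(c("meth", "unmeth"), c(2, 8)),
             rep(c("meth", "unmeth"), c(16, 4))),
    stringsAsFactors = FALSE)
  sm <- summarize_amplicon(calls, amp, min_cov = 10)
  expect_equal(sm$per_cpg$fraction, c(0.2, 0.8))
  expect_equal(sm$overall, 0.5)
  # all methylated
  calls1 <- data.frame(read = 1:20, cpg_pos = rep(p, each = 10),
                       call = "meth", stringsAsFactors = FALSE)
  expect_equal(summarize_amplicon(calls1, amp)$overall, 1)
  # low-coverage CpGs are excluded and reported
  sm2 <- summarize_amplicon(calls[calls$cpg_pos == p[2], ], amp,
                            min_cov = 10)
  expect_equal(sm2$low_coverage_cpgs, p[1])
  expect_equal(sm2$overall, 0.8)
  # nothing reaches the floor: overall undefined but flagged
  sm3 <- summarize_amplicon(calls[1:3, ], amp, min_cov = 10)
  expect_false(sm3$overall_defined)
  expect_true(is.na(sm3$overall))
  # random tally oracle
  set.seed(47)
  for (rep in 1:5) {
    rcalls <- data.frame(
      read = 1:200,
      cpg_pos = sample(p, 200, replace = TRUE),
      call = sample(c("meth", "unmeth"), 200, replace = TRUE),
      stringsAsFactors = FALSE)
    smr <- summarize_amplicon(rcalls, amp, min_cov = 1)
    for (j in seq_along(p)) {
      sel <- rcalls$cpg_pos == p[j]
      expect_equal(smr$per_cpg$n_meth[j],
                   sum(rcalls$call[sel] == "meth"))
      expect_equal(smr$per_cpg$fraction[j],
                   mean(rcalls$call[sel] == "meth"))
    }
  }
})

test_that("concordance flags degenerate input and tracks halved loci", {
  loci <- paste0("L", 1:3)
  samples <- c("P1", "C1", "C2")
  base <- expand.grid(sample_id = samples, locus = loci,
                      stringsAsFactors = FALSE)
  bs <- base
  bs$overall <- 0.8
  mbd <- base
  mbd$rpm <- 100
  out <- concordance(bs, mbd, controls = c("C1", "C2"))
  expect_true(out$degenerate)
  expect_true(is.na(out$r))
  expect_true(all(out$table$bs_log2 == 0))
  # halving one locus in the case moves both ratios to about -1
  bs2 <- bs
  bs2$overall[bs2$sample_id == "P1" & bs2$locus == "L1"] <- 0.4
  mbd2 <- mbd
  mbd2$rpm[mbd2$sample_id == "P1" & mbd2$locus == "L1"] <- 50
  out2 <- concordance(bs2, mbd2, controls = c("C1", "C2"))
  t1 <- out2$table[out2$table$locus == "L1", ]
  expect_lt(abs(t1$bs_log2 - log2(0.41 / 0.81)), 1e-10)
  expect_lt(abs(t1$mbd_log2 - log2(50.01 / 100.01)), 1e-10)
  # missing pairing is an error
  expect_error(concordance(bs[-1, ], mbd, controls = c("C1", "C2")),
               "pairing")
})

test_that("the simulated validation cohort is concordant across assays", {
  sim <- simulate_bs_cohort(seed = 9, n_reads = 120)
  out <- run_bs_validation(sim)
  expect_gte(out$concordance$r, 0.8)
  # overall levels track base_meth * multiplier for a strong-loss locus
  p1 <- out$bs$overall[out$bs$sample_id == "P1" & out$bs$locus == "locus1"]
  c1 <- out$bs$overall[out$bs$sample_id == "C1" & out$bs$locus == "locus1"]
  expect_lt(p1, 0.2)
  expect_gt(c1, 0.6)
})
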