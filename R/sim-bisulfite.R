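# Bisulfite amplicon read simulator.
#
# Each read is an inline sample index followed by a bisulfite-converted
# fragment of the amplicon.  Methylation is symmetric at CpGs: on the
# forward strand an unmethylated CpG cytosine reads T, on the reverse
# strand the paired cytosine sits under the forward-strand G, which then
# reads A.  Non-CpG cytosines always convert.

#' Amplicon specification
#'
#' @param name amplicon name.
#' @param sequence forward-strand reference sequence (A/C/G/T).
#' @return object of class `amplicon_spec` with the sequence and the
#'   1-based positions of CpG cytosines on the forward strand.
#' @export
amplicon_spec <- function(name, sequence) {
  stopifnot(nzchar(name), nzchar(sequence))
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) stop("amplicon sequence must be A/C/G/T")
  hits <- unlist(gregexpr("CG", sequence, fixed = TRUE))
  cpg_pos <- as.integer(hits[hits > 0])
  structure(list(name = name, sequence = sequence, cpg_pos = cpg_pos),
            class = "amplicon_spec")
}

#' @export
print.amplicon_spec <- function(x, ...) {
  cat(sprintf("Amplicon %s: %d bp, %d CpGs\n", x$name, nchar(x$sequence),
              length(x$cpg_pos)))
  invisible(x)
}

#' Default inline index table
#'
#' Nine 6-mer indexes assigned to three patients, three heterozygotes and
#' three controls -- the sample layout of the bisulfite validation arm.
#' Demultiplexing defaults to the full 6-mer; [demultiplex()] verifies that
#' whatever prefix length is chosen keeps the table unambiguous.
#'
#' @return data.frame with columns `sample_id`, `group`, `index`.
#' @export
default_index_table <- function() {
  data.frame(
    sample_id = c("P1", "P2", "P3", "H1", "H2", "H3", "C1", "C2", "C3"),
    group = rep(c("patient", "heterozygote", "control"), each = 3),
    index = c("ACCAAT", "AGAGAT", "AGTCAT", "CAGTCT", "CCGGCT", "CGATCT",
              "CGTACT", "GAGAGT", "GCCGGT"),
    stringsAsFactors = FALSE
  )
}

#' Simulate indexed bisulfite amplicon reads
#'
#' Reads cover random windows of the amplicon on either strand.  On the
#' forward strand every non-CpG C reads T and each CpG C reads C with its
#' per-CpG methylation probability (T otherwise); reverse-strand reads are
#' the reverse complement of the analogously converted bottom strand, i.e.
#' every non-CpG G reads A and each CpG G reads G with the CpG's
#' methylation probability.  Uniform substitution errors are applied at
#' `error_rate`, then the sample index is prepended.
#'
#' @param amplicon an [amplicon_spec()].
#' @param meth_prob per-CpG methylation probabilities, recycled if scalar;
#'   must cover every CpG of the amplicon.
#' @param n_reads number of reads.
#' @param index the sample's inline index; must appear in `index_table`.
#' @param index_table data.frame with columns `sample_id`, `index`.
#' @param seed RNG seed.
#' @param error_rate per-base substitution error probability.
#' @param read_length read length excluding the index; capped at the
#'   amplicon length.
#' @param strands strands to simulate from (default both).
#' @return data.frame with columns `id`, `sequence`, `quality`; attribute
#'   `truth` holds the per-CpG probabilities used.
#' @export
simulate_bisulfite_reads <- function(amplicon, meth_prob, n_reads, index,
                                     index_table = default_index_table(),
                                     seed = 1L, error_rate = 0.002,
                                     read_length = 40L,
                                     strands = c("+", "-")) {
  stopifnot(inherits(amplicon, "amplicon_spec"), n_reads >= 1,
            error_rate >= 0, error_rate < 1,
            all(strands %in% c("+", "-")))
  if (!index %in% index_table$index) {
    stop(sprintf("index %s is not in the configured index table", index))
  }
  cpg <- amplicon$cpg_pos
  if (length(meth_prob) == 1) meth_prob <- rep(meth_prob, length(cpg))
  if (length(meth_prob) != length(cpg)) {
    stop("meth_prob must give a probability for every CpG in the amplicon")
  }
  stopifnot(all(meth_prob >= 0 & meth_prob <= 1))

  ref <- strsplit(amplicon$sequence, "")[[1]]
  L <- length(ref)
  rl <- min(as.integer(read_length), L)

  # fully converted templates; methylated positions are restored per read
  fwd_conv <- ref
  fwd_conv[fwd_conv == "C"] <- "T"
  rev_conv <- ref
  rev_conv[rev_conv == "G"] <- "A"
  bases <- c("A", "C", "G", "T")

  with_seed(seed, {
    offs <- sample.int(L - rl + 1L, n_reads, replace = TRUE) - 1L
    strand <- sample(strands, n_reads, replace = TRUE)
    meth <- matrix(runif(n_reads * length(cpg)), n_reads) <=
      matrix(meth_prob, n_reads, length(cpg), byrow = TRUE)
    seqs <- character(n_reads)
    for (r in seq_len(n_reads)) {
      win <- (offs[r] + 1L):(offs[r] + rl)
      if (strand[r] == "+") {
        x <- fwd_conv[win]
        keep <- which(cpg >= win[1] & cpg <= win[rl] & meth[r, ])
        if (length(keep)) x[cpg[keep] - offs[r]] <- "C"
      } else {
        x <- rev_conv[win]
        g <- cpg + 1L
        keep <- which(g >= win[1] & g <= win[rl] & meth[r, ])
        if (length(keep)) x[g[keep] - offs[r]] <- "G"
        x <- rev(chartr("ACGT", "TGCA", x))
      }
      if (error_rate > 0) {
        err <- which(runif(rl) < error_rate)
        for (e in err) x[e] <- sample(setdiff(bases, x[e]), 1)
      }
      seqs[r] <- paste0(index, paste(x, collapse = ""))
    }
    structure(
      data.frame(id = sprintf("%s_bs%05d", index, seq_len(n_reads)),
                 sequence = seqs,
                 quality = strrep("I", nchar(index) + rl),
                 stringsAsFactors = FALSE),
      truth = data.frame(cpg_pos = cpg, meth_prob = meth_prob))
  })
}
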