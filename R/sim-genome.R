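# Toy genome generator.
#
# Background sequence is CpG-depleted (every CG dinucleotide is destroyed)
# so that methylated regions -- generated GC-rich with ordinary CpG content
# -- stand out as islands.  Designated DMRs receive a Poisson number of
# exact TGCCGC insertions at recorded offsets; all region sequences are
# scrubbed of chance motif occurrences first so the recorded count equals a
# direct scan of the emitted sequence.

MOTIF_FWD <- "TGCCGC"
MOTIF_REV <- "GCGGCA"

# Replace every CG dinucleotide's G by A or T; a single pass leaves no CG
# because the replacement bases can form neither half of a new CG pair.
deplete_cpg <- function(bases) {
  is_cg <- which(bases == "C" & c(bases[-1] == "G", FALSE))
  if (length(is_cg)) {
    bases[is_cg + 1L] <- sample(c("A", "T"), length(is_cg), replace = TRUE)
  }
  bases
}

# Remove all occurrences of both motif strands from a base vector by
# mutating one internal position per hit, iterating until clean.
scrub_motif <- function(bases) {
  for (iter in 1:20) {
    s <- paste(bases, collapse = "")
    hits <- c(unlist(gregexpr(MOTIF_FWD, s, fixed = TRUE)),
              unlist(gregexpr(MOTIF_REV, s, fixed = TRUE)))
    hits <- hits[hits > 0]
    if (!length(hits)) return(bases)
    for (h in hits) {
      pos <- h + 2L
      bases[pos] <- sample(setdiff(c("A", "C", "G", "T"), bases[pos]), 1)
    }
  }
  stop("failed to scrub motif occurrences from region sequence")
}

# Insert exactly k copies of the motif at spaced offsets; verify by scan.
insert_motifs <- function(bases, k) {
  if (k == 0) return(list(bases = bases, offsets = integer()))
  len <- length(bases)
  if (k * 6L > len) stop("region too short for requested motif insertions")
  motif <- strsplit(MOTIF_FWD, "")[[1]]
  for (attempt in 1:50) {
    off <- sort(sample.int(len - 5L, k))
    if (k > 1 && any(diff(off) < 6L)) next
    cand <- bases
    for (o in off) cand[o:(o + 5L)] <- motif
    s <- paste(cand, collapse = "")
    n_fwd <- sum(unlist(gregexpr(MOTIF_FWD, s, fixed = TRUE)) > 0)
    n_rev <- sum(unlist(gregexpr(MOTIF_REV, s, fixed = TRUE)) > 0)
    if (n_fwd == k && n_rev == 0) {
      return(list(bases = cand, offsets = off - 1L))  # 0-based offsets
    }
  }
  stop("failed to place motif insertions without junction artifacts")
}

#' Simulate a toy genome with designated methylated regions
#'
#' Generates CpG-depleted background contigs carrying non-overlapping
#' GC-rich methylated regions.  Regions named in `config$effects` are the
#' designated DMRs and receive `Poisson(motif_rate)` exact TGCCGC
#' insertions at recorded offsets; other regions receive
#' `Poisson(background_motif_rate)` insertions.  All region sequences are
#' scrubbed of chance TGCCGC/GCGGCA occurrences before insertion, so the
#' recorded motif count equals a brute-force scan of the emitted sequence.
#'
#' @param config a [sim_config()] object.
#' @return object of class `mbd_sim`: a list with elements
#'   \describe{
#'     \item{genome}{named character vector, one string per contig}
#'     \item{contig_lengths}{named integer vector}
#'     \item{truth}{list: `regions` (data.frame with `region_id`, `chrom`,
#'       `start`, `end`, `is_dmr`, `motif_count`, `baseline_weight`),
#'       `multiplier` (region x sample matrix), `motif_offsets` (list of
#'       0-based offsets per region)}
#'     \item{config}{the configuration}
#'   }
#'   Coordinates are 0-based half-open.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_regions
    lens <- pmax(100L, as.integer(round(
      rnorm(n, config$region_length_mean, config$region_length_mean / 5))))
    contig_of <- rep(seq_len(config$n_contigs), length.out = n)
    min_gap <- 300L

    genome <- character(config$n_contigs)
    names(genome) <- sprintf("contig%02d", seq_len(config$n_contigs))
    region_rows <- vector("list", config$n_contigs)

    for (ci in seq_len(config$n_contigs)) {
      idx <- which(contig_of == ci)
      k <- length(idx)
      L <- config$contig_length
      need <- sum(lens[idx]) + min_gap * (k + 1L)
      if (need > L) {
        stop(sprintf(
          "cannot place %d regions (%d bp + gaps) on a %d bp contig", k,
          sum(lens[idx]), L))
      }
      free <- L - need
      extra <- diff(c(0, sort(runif(k, 0, free)), free))
      gaps <- min_gap + extra
      starts <- integer(k)
      pos <- 0
      for (j in seq_len(k)) {
        pos <- pos + gaps[j]
        starts[j] <- as.integer(floor(pos))
        pos <- starts[j] + lens[idx[j]]
      }
      bases <- deplete_cpg(random_bases(L))
      for (j in seq_len(k)) {
        reg <- scrub_motif(random_bases(
          lens[idx[j]], probs = c(A = 0.2, C = 0.3, G = 0.3, T = 0.2)))
        bases[(starts[j] + 1L):(starts[j] + lens[idx[j]])] <- reg
      }
      genome[ci] <- paste(bases, collapse = "")
      region_rows[[ci]] <- data.frame(
        orig_index = idx, chrom = names(genome)[ci], start = starts,
        end = starts + lens[idx], stringsAsFactors = FALSE)
    }

    regions <- do.call(rbind, region_rows)
    regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
    # region identity = genomic order, which is how effects index regions
    rownames(regions) <- NULL
    regions$region_index <- seq_len(n)

    samples <- config$cohort$sample_id
    multiplier <- matrix(1, n, length(samples),
                         dimnames = list(NULL, samples))
    dmr_idx <- sort(unique(config$effects$region_index))
    for (r in seq_len(nrow(config$effects))) {
      e <- config$effects[r, ]
      multiplier[e$region_index, e$sample_id] <- e$multiplier
    }

    motif_count <- integer(n)
    motif_offsets <- vector("list", n)
    for (i in seq_len(n)) {
      rate <- if (i %in% dmr_idx) config$motif_rate else
        config$background_motif_rate
      k <- if (rate > 0) rpois(1, rate) else 0L
      if (k > 0) {
        ci <- regions$chrom[i]
        seq_i <- strsplit(substr(genome[ci], regions$start[i] + 1L,
                                 regions$end[i]), "")[[1]]
        ins <- insert_motifs(seq_i, k)
        substr(genome[ci], regions$start[i] + 1L, regions$end[i]) <-
          paste(ins$bases, collapse = "")
        motif_offsets[[i]] <- ins$offsets
      } else {
        motif_offsets[[i]] <- integer()
      }
      motif_count[i] <- k
    }

    baseline_weight <- rgamma(n, shape = 8, rate = 8)

    truth_regions <- data.frame(
      region_id = sprintf("%s:%d-%d", regions$chrom, regions$start,
                          regions$end),
      chrom = regions$chrom, start = regions$start, end = regions$end,
      is_dmr = regions$region_index %in% dmr_idx,
      motif_count = motif_count,
      baseline_weight = baseline_weight,
      stringsAsFactors = FALSE)

    structure(list(
      genome = genome,
      contig_lengths = setNames(nchar(genome), names(genome)),
      truth = list(regions = truth_regions, multiplier = multiplier,
                   motif_offsets = motif_offsets),
      config = config
    ), class = "mbd_sim")
  })
}

#' @export
print.mbd_sim <- function(x, ...) {
  cat(sprintf(
    "Simulated genome: %d contig(s), %d bp total, %d regions (%d DMRs)\n",
    length(x$genome), sum(x$contig_lengths), nrow(x$truth$regions),
    sum(x$truth$regions$is_dmr)))
  invisible(x)
}
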