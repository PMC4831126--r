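# Capture-read simulator.
#
# Region counts are negative binomial around depth * weight_fraction *
# multiplier; background reads add a further background_fraction * depth
# uniformly over the genome.  Reads are
# emitted as already-aligned BED-like records (alignment itself is outside
# the pipeline's remit), 36 bp by default, read from either end of a 250 bp
# fragment whose centre is uniform within the region.

# NB draw with variance = mu + phi * mu^2; phi = 0 gives Poisson.
draw_region_counts <- function(mu, phi) {
  if (phi < 0) stop("dispersion must be >= 0")
  if (phi == 0) return(rpois(length(mu), mu))
  rnbinom(length(mu), size = 1 / phi, mu = mu)
}

#' Simulate aligned methyl-capture reads for a cohort
#'
#' For sample `s` and region `i`, the in-region read count is drawn
#' `NB(mean = depth * w_i / sum(w) * m_is, dispersion = phi)` where `w` are
#' the baseline capture weights and `m` the methylation multipliers of the
#' simulation truth.  Background reads are added uniformly over the genome
#' at `background_fraction` of depth.  A configured fraction of reads gets
#' mapping quality below 37 and a configured fraction is duplicated at an
#' identical position, so that read filtering has something to do.
#'
#' @param sim an `mbd_sim` object from [simulate_genome()].
#' @param seed RNG seed; defaults to `config$seed + 1000` so that genome and
#'   reads are jointly reproducible but separately re-drawable.
#' @return data.frame of aligned reads with columns `chrom`, `start`, `end`
#'   (0-based half-open), `name`, `mapq`, `strand`, `sample` -- the BED6+1
#'   layout used throughout the package.
#' @export
simulate_capture_reads <- function(sim, seed = NULL) {
  stopifnot(inherits(sim, "mbd_sim"))
  config <- sim$config
  if (is.null(seed)) seed <- config$seed + 1000L
  with_seed(seed, {
    regions <- sim$truth$regions
    w <- regions$baseline_weight
    wfrac <- w / sum(w)
    fl <- config$fragment_length
    rl <- config$read_length
    clens <- sim$contig_lengths
    samples <- config$cohort$sample_id

    out <- vector("list", length(samples))
    for (si in seq_along(samples)) {
      s <- samples[si]
      mu <- config$depth_per_sample * wfrac * sim$truth$multiplier[, s]
      n_i <- draw_region_counts(mu, config$dispersion)

      ridx <- rep.int(seq_len(nrow(regions)), n_i)
      chrom <- regions$chrom[ridx]
      centre <- runif(length(ridx), regions$start[ridx], regions$end[ridx])
      fstart <- as.integer(round(centre - fl / 2))

      n_bg <- rpois(1, config$depth_per_sample * config$background_fraction)
      if (n_bg > 0) {
        bg_contig <- sample(names(clens), n_bg, replace = TRUE,
                            prob = clens / sum(clens))
        bg_start <- as.integer(floor(runif(n_bg, 0, clens[bg_contig] - fl)))
        chrom <- c(chrom, bg_contig)
        fstart <- c(fstart, bg_start)
      }
      fstart <- pmax(0L, pmin(fstart, as.integer(clens[chrom]) - fl))
      n <- length(fstart)
      strand <- sample(c("+", "-"), n, replace = TRUE)
      start <- ifelse(strand == "+", fstart, fstart + fl - rl)
      end <- start + rl
      low <- runif(n) < config$mapq_low_fraction
      mapq <- ifelse(low, sample(0:36, n, replace = TRUE),
                     sample(37:60, n, replace = TRUE))
      df <- data.frame(chrom = chrom, start = start, end = end,
                       name = paste0(s, "_r", seq_len(n)),
                       mapq = mapq, strand = strand, sample = s,
                       stringsAsFactors = FALSE)
      dup <- which(runif(n) < config$duplicate_rate)
      if (length(dup)) {
        d <- df[dup, , drop = FALSE]
        d$name <- paste0(s, "_d", seq_along(dup))
        df <- rbind(df, d)
      }
      rownames(df) <- NULL
      out[[si]] <- df
    }
    do.call(rbind, out)
  })
}
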