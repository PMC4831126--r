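#' Default simulated cohort
#'
#' Twelve individuals mirroring the study design the analysis is built for:
#' four patients, three heterozygous relatives, and five unrelated controls.
#'
#' @return data.frame with columns `sample_id` and
#'   `group` (one of `"patient"`, `"heterozygote"`, `"control"`).
#' @export
default_cohort <- function() {
  data.frame(
    sample_id = c(paste0("P", 1:4), paste0("H", 1:3), paste0("C", 1:5)),
    group = c(rep("patient", 4), rep("heterozygote", 3), rep("control", 5)),
    stringsAsFactors = FALSE
  )
}

#' Default methylation effects
#'
#' The ground-truth aberrations applied to designated DMRs in the simulated
#' cohort.  Three regions suffer total loss of methylation (multiplier 0) in
#' all four patients, mirroring the handful of loci a maintenance-factor
#' defect erases in every affected individual; further regions carry partial
#' loss (multiplier 0.5) in patient subsets, two regions gain methylation,
#' and one region is mildly reduced in heterozygotes.
#'
#' @param cohort cohort data.frame as from [default_cohort()].
#' @return data.frame with columns `region_index`, `sample_id`, `multiplier`.
#' @export
default_effects <- function(cohort = default_cohort()) {
  pats <- cohort$sample_id[cohort$group == "patient"]
  hets <- cohort$sample_id[cohort$group == "heterozygote"]
  rows <- list(
    list(1, pats, 0),                 # total loss, all patients
    list(2, pats, 0),
    list(3, pats, 0),
    list(4, pats[1:3], 0.5),          # partial loss in patient subsets
    list(5, pats[1:2], 0.5),
    list(6, pats[c(2, 4)], 0.5),
    list(7, pats[1], 0.5),
    list(8, pats[2], 0.5),
    list(9, pats[3], 0.5),
    list(10, pats[1:2], 2),           # hypermethylation
    list(11, pats[4], 2),
    list(12, hets, 0.7)               # mild heterozygote effect
  )
  do.call(rbind, lapply(rows, function(r) {
    data.frame(region_index = r[[1]], sample_id = r[[2]], multiplier = r[[3]],
               stringsAsFactors = FALSE)
  }))
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator.  The defaults are
#' the desk-scale study conditions used throughout the package's tests: a
#' 12-sample cohort on a 0.6 Mb toy genome carrying 100 methylated regions,
#' capture depth 30,000 aligned reads per sample with 30% genomic
#' background, negative-binomial overdispersion 0.1, and the effect table
#' of [default_effects()].
#'
#' @param seed integer RNG seed; a fixed seed makes every generator output
#'   byte-identical across runs.
#' @param n_contigs number of toy contigs.
#' @param contig_length length of each contig in bases.
#' @param n_regions number of methylated regions placed on the genome.
#' @param region_length_mean mean region length in bases (sd is 20% of the
#'   mean, floor 100 bp).
#' @param motif_rate expected number of TGCCGC insertions per designated DMR
#'   (Poisson).
#' @param background_motif_rate expected TGCCGC insertions per
#'   non-DMR region (default 0: background regions are motif-free).
#' @param cohort data.frame of `sample_id`, `group`.
#' @param depth_per_sample expected aligned reads per sample.
#' @param dispersion negative-binomial overdispersion phi >= 0
#'   (variance = mean + phi * mean^2); 0 gives Poisson counts.
#' @param background_fraction fraction of depth falling uniformly outside
#'   regions.
#' @param read_length sequenced read length in bases.
#' @param fragment_length capture fragment length in bases.
#' @param mapq_low_fraction fraction of reads given mapping quality below 37
#'   (to exercise read filtering).
#' @param duplicate_rate fraction of reads duplicated at an identical
#'   position (to exercise duplicate removal).
#' @param effects data.frame of `region_index`, `sample_id`, `multiplier`
#'   (0 = total loss, 0.5 = partial loss, >1 = gain). Regions appearing here
#'   are the designated DMRs.
#' @return object of class `sim_config`.
#' @seealso [simulate_genome()], [simulate_capture_reads()]
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 2L,
                       contig_length = 3e5,
                       n_regions = 100L,
                       region_length_mean = 600,
                       motif_rate = 4,
                       background_motif_rate = 0,
                       cohort = default_cohort(),
                       depth_per_sample = 3e4,
                       dispersion = 0.1,
                       background_fraction = 0.3,
                       read_length = 36L,
                       fragment_length = 250L,
                       mapq_low_fraction = 0.05,
                       duplicate_rate = 0.05,
                       effects = default_effects(cohort)) {
  stopifnot(
    length(seed) == 1, is.finite(seed),
    n_contigs >= 1, contig_length > 0, n_regions >= 1,
    region_length_mean >= 100,
    motif_rate >= 0, background_motif_rate >= 0,
    is.data.frame(cohort), all(c("sample_id", "group") %in% names(cohort)),
    !anyDuplicated(cohort$sample_id),
    all(cohort$group %in% c("patient", "heterozygote", "control")),
    depth_per_sample > 0,
    background_fraction >= 0, background_fraction < 1,
    read_length > 0, fragment_length >= read_length,
    mapq_low_fraction >= 0, mapq_low_fraction <= 1,
    duplicate_rate >= 0, duplicate_rate < 1
  )
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (!is.null(effects) && nrow(effects) > 0) {
    stopifnot(all(c("region_index", "sample_id", "multiplier") %in%
                    names(effects)))
    if (any(effects$multiplier < 0)) stop("effect multipliers must be >= 0")
    if (any(effects$region_index < 1 | effects$region_index > n_regions)) {
      stop("effect region_index out of range")
    }
    if (!all(effects$sample_id %in% cohort$sample_id)) {
      stop("effect sample_id not in cohort")
    }
    if (anyDuplicated(effects[, c("region_index", "sample_id")])) {
      stop("duplicate (region_index, sample_id) in effects")
    }
  } else {
    effects <- data.frame(region_index = integer(), sample_id = character(),
                          multiplier = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(
    seed = as.integer(seed), n_contigs = as.integer(n_contigs),
    contig_length = as.integer(contig_length),
    n_regions = as.integer(n_regions),
    region_length_mean = region_length_mean,
    motif_rate = motif_rate,
    background_motif_rate = background_motif_rate,
    cohort = cohort, depth_per_sample = depth_per_sample,
    dispersion = dispersion, background_fraction = background_fraction,
    read_length = as.integer(read_length),
    fragment_length = as.integer(fragment_length),
    mapq_low_fraction = mapq_low_fraction,
    duplicate_rate = duplicate_rate,
    effects = effects
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  genome : %d contig(s) x %d bp, %d regions (mean %.0f bp)\n",
              x$n_contigs, x$contig_length, x$n_regions,
              x$region_length_mean))
  cat(sprintf("  cohort : %d samples (%d patients / %d het / %d controls)\n",
              nrow(x$cohort), sum(x$cohort$group == "patient"),
              sum(x$cohort$group == "heterozygote"),
              sum(x$cohort$group == "control")))
  cat(sprintf("  reads  : %g per sample, %d bp, phi = %g, background %.0f%%\n",
              x$depth_per_sample, x$read_length, x$dispersion,
              100 * x$background_fraction))
  cat(sprintf("  effects: %d (region, sample) aberrations over %d DMRs\n",
              nrow(x$effects), length(unique(x$effects$region_index))))
  invisible(x)
}
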