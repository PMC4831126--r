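# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of sequences over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @examples
#' reverse_complement("TGCCGC")  # "GCGGCA"
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(b) paste(rev(b), collapse = ""), character(1))
}

# Random DNA as a character vector of single bases.
random_bases <- function(n, probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# Validate a BED-like region data.frame (0-based half-open coordinates).
check_regions <- function(regions) {
  stopifnot(is.data.frame(regions),
            all(c("chrom", "start", "end") %in% names(regions)))
  if (nrow(regions) > 0) {
    if (any(!nzchar(as.character(regions$chrom)))) {
      stop("region chrom names must be non-empty")
    }
    if (any(regions$start < 0) || any(regions$start >= regions$end)) {
      stop("regions must satisfy 0 <= start < end")
    }
  }
  invisible(regions)
}

# Convert 0-based half-open regions to GRanges (1-based closed internally).
regions_to_granges <- function(regions) {
  check_regions(regions)
  GenomicRanges::GRanges(
    seqnames = as.character(regions$chrom),
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
}

# Canonical region identifier used to key merged-universe regions.
region_ids <- function(regions) {
  sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end)
}

# Stable sort of a region data.frame by (chrom, start, end).
sort_regions <- function(regions) {
  regions[order(as.character(regions$chrom), regions$start, regions$end), ,
          drop = FALSE]
}
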