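# Plain-text interchange: FASTA via Biostrings, BED-like reads and
# regions, count-matrix TSV with a library-size header, FASTQ.

#' Write a simulated genome as FASTA
#'
#' @param sim an `mbd_sim` object or a named character vector of contigs.
#' @param path output file.
#' @export
write_genome_fasta <- function(sim, path) {
  genome <- if (inherits(sim, "mbd_sim")) sim$genome else sim
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
}

#' Read a genome FASTA into a named character vector
#'
#' @param path FASTA file.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write aligned reads as BED6+1
#'
#' Columns: chrom, start, end, name, mapq (score column), strand, sample.
#'
#' @param reads read data.frame.
#' @param path output file.
#' @export
write_reads_bed <- function(reads, path) {
  write.table(reads[, c("chrom", "start", "end", "name", "mapq", "strand",
                        "sample")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' Read aligned reads from BED6+1
#'
#' @param path input file written by [write_reads_bed()].
#' @export
read_reads_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "name", "mapq",
                                 "strand", "sample"),
                   colClasses = c("character", "integer", "integer",
                                  "character", "integer", "character",
                                  "character"))
  df
}

#' Write regions as BED3(+1)
#'
#' @param regions region data.frame.
#' @param path output file.
#' @export
write_regions_bed <- function(regions, path) {
  cols <- intersect(c("chrom", "start", "end", "region_id"),
                    names(regions))
  write.table(regions[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

#' Read regions from BED
#'
#' @param path BED3 or BED4 file.
#' @export
read_regions_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  df[[1]] <- as.character(df[[1]])
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "region_id"
  check_regions(df)
  df
}

#' Write a region count matrix as TSV
#'
#' The first line is a `#library_sizes:` header; the table has region
#' coordinates followed by one count column per sample.
#'
#' @param mat a `region_count_matrix`.
#' @param path output file.
#' @export
write_count_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "region_count_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#library_sizes:\t",
                    paste(sprintf("%s=%d", names(mat$library_sizes),
                                  mat$library_sizes), collapse = "\t")),
             con)
  df <- cbind(mat$regions[, c("region_id", "chrom", "start", "end")],
              as.data.frame(mat$counts, optional = TRUE))
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
}

#' Read a region count matrix TSV
#'
#' @param path file written by [write_count_matrix()].
#' @return a `region_count_matrix`.
#' @export
read_count_matrix <- function(path) {
  first <- readLines(path, n = 1)
  stopifnot(startsWith(first, "#library_sizes:"))
  parts <- strsplit(sub("^#library_sizes:\t", "", first), "\t")[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  lib <- setNames(as.integer(vapply(kv, `[`, character(1), 2)),
                  vapply(kv, `[`, character(1), 1))
  df <- read.table(path, sep = "\t", header = TRUE, skip = 1,
                   check.names = FALSE, stringsAsFactors = FALSE)
  regions <- df[, c("region_id", "chrom", "start", "end")]
  counts <- as.matrix(df[, names(lib), drop = FALSE])
  rownames(counts) <- regions$region_id
  structure(list(regions = regions, samples = names(lib), counts = counts,
                 library_sizes = lib),
            class = "region_count_matrix")
}

#' Write bisulfite reads as FASTQ
#'
#' @param reads data.frame with `id`, `sequence`, `quality`.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$id), reads$sequence,
                           "+", reads$quality))
  writeLines(lines, path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file (uncompressed).
#' @return data.frame with `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  stopifnot(length(lines) %% 4 == 0)
  idx <- seq(1, length(lines), by = 4)
  data.frame(id = sub("^@", "", lines[idx]),
             sequence = lines[idx + 1],
             quality = lines[idx + 3],
             stringsAsFactors = FALSE)
}
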