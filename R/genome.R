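#' Read a genome from FASTA
#'
#' Sequences are returned as a named character vector of uppercase bases,
#' one element per chromosome. Ambiguity codes other than N are not expected
#' but pass through unchanged.
#'
#' @param path path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("no records in FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stop("duplicate chromosome names in FASTA: ", path)
  out <- toupper(as.character(ss))
  names(out) <- nm
  out
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Chromosome lengths of a genome
#' @param genome named character vector of sequences.
#' @return Named integer vector.
#' @export
chrom_lengths <- function(genome) {
  vapply(genome, nchar, integer(1))
}

#' Read an excluded-region mask from BED
#'
#' The mask lists centromeric, telomeric and rDNA intervals to exclude from
#' arm analyses. Intervals are normalized (sorted, overlaps merged).
#'
#' @param path BED file (0-based half-open, as the format defines).
#' @return Interval `data.frame`.
#' @export
read_arm_mask <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  gi_reduce(gr2gi(gr))
}

#' Chromosome arms: complement of the mask
#'
#' @param chrom_lengths named vector of chromosome lengths.
#' @param mask interval `data.frame` of excluded regions (may be empty).
#' @return Interval `data.frame` of arm segments.
#' @export
genome_arms <- function(chrom_lengths, mask = NULL) {
  universe <- gi(names(chrom_lengths), 0, as.numeric(chrom_lengths))
  if (is.null(mask) || nrow(mask) == 0) return(universe)
  gi_complement(gi_reduce(mask), universe)
}
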