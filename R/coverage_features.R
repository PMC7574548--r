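#' Length of the transcription-poor region in a window (L_ntx)
#'
#' Longest contiguous run of positions whose per-base RNA-seq depth is at or
#' below `max_count`, truncated at the window edges. Setting
#' `mode = "total"` instead counts all qualifying positions.
#'
#' @param coverage per-base depth vector for the chromosome.
#' @param start,end 0-based half-open analysis window.
#' @param max_count depth cutoff defining "transcription-poor".
#' @param mode `"longest_run"` (default) or `"total"`.
#' @return Length in bp.
#' @export
l_ntx <- function(coverage, start, end, max_count = 1,
                  mode = c("longest_run", "total")) {
  mode <- match.arg(mode)
  stopifnot(start >= 0, end <= length(coverage), end > start)
  low <- coverage[(start + 1):end] <= max_count
  if (mode == "total") return(sum(low))
  r <- rle(low)
  m <- r$lengths[r$values]
  if (length(m) == 0) 0L else max(m)
}

#' Per-bin DNA copy-number ratio
#'
#' Depth-normalized elementwise ratio of sample to reference binned counts.
#' Bins with zero reference counts are `NA` rather than infinite.
#'
#' @param sample_bins,reference_bins numeric vectors of per-bin counts on the
#'   same grid.
#' @return Numeric vector of raw ratios.
#' @export
copy_number_ratio <- function(sample_bins, reference_bins) {
  if (length(sample_bins) != length(reference_bins))
    stop("sample and reference bin grids differ")
  st <- sum(sample_bins); rt <- sum(reference_bins)
  if (st <= 0 || rt <= 0) stop("bin totals must be > 0")
  out <- (sample_bins / st) / (reference_bins / rt)
  out[reference_bins == 0] <- NA_real_
  out
}

#' LOESS smoothing of a genomic profile
#'
#' Locally weighted polynomial regression (degree 2, tricube weights, no
#' robustness iterations) with neighbourhood fraction `span`, evaluated at
#' each input position. `NA` values are dropped from the fit and returned as
#' `NA`.
#'
#' @param values numeric response (e.g. per-bin copy-number ratios).
#' @param positions numeric predictor (bin coordinates); defaults to the
#'   index.
#' @param span neighbourhood fraction.
#' @param degree local polynomial degree.
#' @return Smoothed values at `positions`.
#' @export
loess_smooth <- function(values, positions = seq_along(values),
                         span = 0.005, degree = 2) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (span * n < 3) stop("span too small: fewer than 3 points per fit")
  fit <- stats::loess(values[ok] ~ positions[ok], span = span,
                      degree = degree, family = "gaussian",
                      control = stats::loess.control(surface = "direct",
                                                     iterations = 1))
  out <- rep(NA_real_, length(values))
  out[ok] <- stats::predict(fit, data.frame(`positions[ok]` = positions[ok],
                                            check.names = FALSE))
  out
}

#' Scale a profile so its 25th percentile equals 1
#'
#' @param values numeric vector (NA ignored for the quantile).
#' @return Scaled values.
#' @export
scale_quartile <- function(values) {
  q25 <- stats::quantile(values, 0.25, na.rm = TRUE, names = FALSE)
  if (q25 <= 0) stop("25th percentile must be positive for scaling")
  values / q25
}

#' Read and write per-base coverage as bedGraph
#'
#' Runs of equal depth are written as single intervals; zero-depth runs are
#' omitted (bedGraph sparse convention) and restored as 0 on read.
#'
#' @param coverage named list of per-base depth vectors.
#' @param path bedGraph file.
#' @param chrom_lengths named vector of chromosome lengths (read direction).
#' @return `write_coverage_bedgraph()` returns `path` invisibly;
#'   `read_coverage_bedgraph()` returns a named list of depth vectors.
#' @export
write_coverage_bedgraph <- function(coverage, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chr in names(coverage)) {
    v <- coverage[[chr]]
    r <- rle(as.numeric(v))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%.6g", chr, starts[keep], ends[keep],
                         r$values[keep]), con)
  }
  invisible(path)
}

#' @rdname write_coverage_bedgraph
#' @export
read_coverage_bedgraph <- function(path, chrom_lengths) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- gr2gi(gr)
  df$score <- gr$score
  out <- lapply(names(chrom_lengths), function(chr) {
    v <- numeric(as.numeric(chrom_lengths[chr]))
    d <- df[df$chrom == chr, , drop = FALSE]
    for (r in seq_len(nrow(d)))
      v[(d$start[r] + 1):d$end[r]] <- d$score[r]
    v
  })
  names(out) <- names(chrom_lengths)
  out
}
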