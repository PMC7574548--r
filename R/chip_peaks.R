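#' Fold-enrichment tracks
#'
#' A fold-enrichment (FE) track stores one FE value per fixed-width genomic
#' bin (default 10 bp), as a named list of per-chromosome numeric vectors.
#'
#' @param values named list, one numeric vector per chromosome.
#' @param bin_width bin width in bp.
#' @return An object of class `fe_track`.
#' @export
fe_track <- function(values, bin_width = 10L) {
  stopifnot(is.list(values), length(values) > 0, !is.null(names(values)))
  if (any(vapply(values, function(v) any(v < 0), logical(1))))
    stop("fold enrichment must be >= 0")
  structure(list(values = values, bin_width = as.integer(bin_width)),
            class = "fe_track")
}

#' @export
print.fe_track <- function(x, ...) {
  cat("Fold-enrichment track:", length(x$values), "chromosome(s),",
      x$bin_width, "bp bins\n")
  for (chr in names(x$values))
    cat(sprintf("  %s: %d bins, FE range %.2f-%.2f\n", chr,
                length(x$values[[chr]]), min(x$values[[chr]]),
                max(x$values[[chr]])))
  invisible(x)
}

#' Compute fold enrichment from binned read counts
#'
#' Depth-normalized ratio of ChIP to input per bin:
#' `FE = ((chip + pc) / chip_total) / ((input + pc) / input_total)` where the
#' totals include the pseudocounts, so all-zero tracks stay finite.
#'
#' @param chip_counts,input_counts named lists of per-bin counts on the same
#'   bin grid.
#' @param bin_width bin width in bp.
#' @param pseudocount added to every bin before normalization.
#' @return An `fe_track`.
#' @export
compute_fe <- function(chip_counts, input_counts, bin_width = 10L,
                       pseudocount = 1) {
  if (!identical(names(chip_counts), names(input_counts)))
    stop("chip and input tracks cover different chromosomes")
  for (chr in names(chip_counts))
    if (length(chip_counts[[chr]]) != length(input_counts[[chr]]))
      stop("mismatched bin grids on ", chr)
  ct <- sum(unlist(chip_counts)) +
    pseudocount * sum(lengths(chip_counts))
  it <- sum(unlist(input_counts)) +
    pseudocount * sum(lengths(input_counts))
  vals <- lapply(names(chip_counts), function(chr) {
    ((chip_counts[[chr]] + pseudocount) / ct) /
      ((input_counts[[chr]] + pseudocount) / it)
  })
  names(vals) <- names(chip_counts)
  fe_track(vals, bin_width)
}

#' Call peaks from a fold-enrichment track
#'
#' A peak is a maximal run of consecutive bins with FE at or above the
#' threshold; runs narrower than `min_width` bp are judged false positives
#' and discarded. The summit is the centre of the highest-FE bin in the run
#' (leftmost on ties), so a multi-summit supra-threshold region is reported
#' as a single peak with the summit at the highest component.
#'
#' @param fe an `fe_track`.
#' @param fe_threshold FE threshold (e.g. 6 for Orc4, 2 for Mcm2).
#' @param min_width minimum peak width in bp.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `summit`,
#'   `max_fe`, sorted and pairwise disjoint.
#' @export
call_peaks <- function(fe, fe_threshold, min_width = 50) {
  stopifnot(inherits(fe, "fe_track"), fe_threshold > 0)
  bw <- fe$bin_width
  out <- list()
  for (chr in names(fe$values)) {
    v <- fe$values[[chr]]
    above <- v >= fe_threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- which(r$values)
    for (k in runs) {
      b0 <- starts[k]; b1 <- ends[k]
      width <- (b1 - b0 + 1) * bw
      if (width < min_width) next
      seg <- v[b0:b1]
      imax <- b0 + which.max(seg) - 1  # leftmost maximal bin
      out[[length(out) + 1]] <- data.frame(
        chrom = chr, start = (b0 - 1) * bw, end = b1 * bw,
        summit = (imax - 1) * bw + floor(bw / 2), max_fe = max(seg),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), summit = numeric(0),
                      max_fe = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Remove peaks overlapping the exclusion mask
#'
#' Drops any peak sharing at least 1 bp with a masked interval
#' (centromere/telomere/rDNA).
#'
#' @param peaks peak `data.frame` from [call_peaks()].
#' @param arm_mask interval `data.frame` of excluded regions.
#' @return Filtered peak `data.frame`.
#' @export
apply_mask <- function(peaks, arm_mask) {
  if (is.null(arm_mask) || nrow(arm_mask) == 0 || nrow(peaks) == 0)
    return(peaks)
  hits <- gi_overlap_pairs(peaks, arm_mask)
  if (nrow(hits) == 0) return(peaks)
  out <- peaks[-unique(hits$i), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify Orc/Mcm co-localization into OM, O and M-only sites
#'
#' An Orc peak with a >= 1 bp overlap with any Mcm peak is an OM site (pre-RC
#' proxy), paired to the Mcm peak with the largest overlap (leftmost on
#' ties); Orc peaks with no Mcm overlap are O sites; Mcm peaks overlapping no
#' Orc peak are M-only.
#'
#' @param orc_peaks,mcm_peaks peak `data.frame`s from [call_peaks()].
#' @return An object of class `site_set`: list with elements `om` (paired
#'   peak table), `o`, `m_only`.
#' @export
classify_sites <- function(orc_peaks, mcm_peaks) {
  hits <- gi_overlap_pairs(orc_peaks, mcm_peaks)
  om_idx <- sort(unique(hits$i))
  om <- NULL
  if (length(om_idx) > 0) {
    best <- vapply(om_idx, function(i) {
      h <- hits[hits$i == i, , drop = FALSE]
      h <- h[order(-h$width, mcm_peaks$start[h$j]), , drop = FALSE]
      h$j[1]
    }, integer(1))
    om <- data.frame(
      chrom = orc_peaks$chrom[om_idx],
      orc_start = orc_peaks$start[om_idx], orc_end = orc_peaks$end[om_idx],
      orc_summit = orc_peaks$summit[om_idx],
      orc_max_fe = orc_peaks$max_fe[om_idx],
      mcm_start = mcm_peaks$start[best], mcm_end = mcm_peaks$end[best],
      mcm_summit = mcm_peaks$summit[best],
      mcm_max_fe = mcm_peaks$max_fe[best],
      stringsAsFactors = FALSE)
  } else {
    om <- data.frame(chrom = character(0), orc_start = numeric(0),
                     orc_end = numeric(0), orc_summit = numeric(0),
                     orc_max_fe = numeric(0), mcm_start = numeric(0),
                     mcm_end = numeric(0), mcm_summit = numeric(0),
                     mcm_max_fe = numeric(0), stringsAsFactors = FALSE)
  }
  o_idx <- setdiff(seq_len(nrow(orc_peaks)), om_idx)
  m_idx <- setdiff(seq_len(nrow(mcm_peaks)), unique(hits$j))
  o <- orc_peaks[o_idx, , drop = FALSE]; rownames(o) <- NULL
  m <- mcm_peaks[m_idx, , drop = FALSE]; rownames(m) <- NULL
  structure(list(om = om, o = o, m_only = m), class = "site_set")
}

#' @export
print.site_set <- function(x, ...) {
  cat("Pre-RC site classification:\n")
  cat(sprintf("  OM sites (Orc+Mcm): %d\n", nrow(x$om)))
  cat(sprintf("  O sites (Orc only): %d\n", nrow(x$o)))
  cat(sprintf("  M-only sites:       %d\n", nrow(x$m_only)))
  invisible(x)
}

#' Venn counts of a site set
#'
#' @param site_set a `site_set` from [classify_sites()].
#' @return Named numeric vector `c(n_o, n_om, n_m_only)`.
#' @export
venn_counts <- function(site_set) {
  c(n_o = nrow(site_set$o), n_om = nrow(site_set$om),
    n_m_only = nrow(site_set$m_only))
}

#' Signed Mcm-minus-Orc summit offsets at OM sites
#'
#' @param site_set a `site_set`.
#' @return Numeric vector of `mcm_summit - orc_summit` distances (bp).
#' @export
summit_offsets <- function(site_set) {
  site_set$om$mcm_summit - site_set$om$orc_summit
}

#' Read and write fold-enrichment tracks as bedGraph
#'
#' One bedGraph line per bin. Reading requires a bin grid consistent with
#' `bin_width`; positions not covered default to `fill`.
#'
#' @param fe an `fe_track`.
#' @param path bedGraph file path.
#' @param chrom_lengths named vector of chromosome lengths (read direction).
#' @param bin_width bin width in bp.
#' @param fill value for uncovered bins when reading.
#' @return `write_fe_bedgraph()` returns `path` invisibly;
#'   `read_fe_bedgraph()` returns an `fe_track`.
#' @export
write_fe_bedgraph <- function(fe, path) {
  bw <- fe$bin_width
  con <- file(path, "w")
  on.exit(close(con))
  for (chr in names(fe$values)) {
    v <- fe$values[[chr]]
    starts <- (seq_along(v) - 1) * bw
    writeLines(sprintf("%s\t%d\t%d\t%.6g", chr, starts, starts + bw, v), con)
  }
  invisible(path)
}

#' @rdname write_fe_bedgraph
#' @export
read_fe_bedgraph <- function(path, chrom_lengths, bin_width = 10L,
                             fill = 0) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- gr2gi(gr)
  df$score <- gr$score
  vals <- lapply(names(chrom_lengths), function(chr) {
    n <- ceiling(as.numeric(chrom_lengths[chr]) / bin_width)
    v <- rep(fill, n)
    d <- df[df$chrom == chr, , drop = FALSE]
    if (nrow(d) > 0) {
      if (any((d$start %% bin_width) != 0))
        stop("bedGraph intervals not aligned to the bin grid")
      v[d$start / bin_width + 1] <- d$score
    }
    v
  })
  names(vals) <- names(chrom_lengths)
  fe_track(vals, bin_width)
}
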