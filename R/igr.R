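#' Orientation class from flanking-gene strands
#'
#' An intergenic region is `divergent` when both neighbours transcribe away
#' from it (left gene on `-`, right gene on `+`), `convergent` when both
#' transcribe into it (left `+`, right `-`), and `tandem` when both genes lie
#' on the same strand. A missing neighbour (chromosome-arm edge) gives
#' `edge`.
#'
#' @param left_strand,right_strand strand characters (`"+"`/`"-"`), `NA` for
#'   a missing neighbour. Vectorized.
#' @return Character vector of orientation classes.
#' @export
classify_orientation <- function(left_strand, right_strand) {
  out <- rep("edge", length(left_strand))
  ok <- !is.na(left_strand) & !is.na(right_strand)
  out[ok & left_strand == "-" & right_strand == "+"] <- "divergent"
  out[ok & left_strand == "+" & right_strand == "-"] <- "convergent"
  out[ok & left_strand == right_strand] <- "tandem"
  out
}

#' Derive intergenic regions
#'
#' IGRs are the chromosome-arm segments not covered by any UTR-extended gene
#' span. Overlapping genes leave no IGR between them; zero-length gaps are
#' dropped; segments overlapping the exclusion mask are clipped out.
#' Each IGR records its flanking genes and the orientation class of the
#' nearest and second-nearest neighbours.
#'
#' @param genes gene models from [read_genes()].
#' @param chrom_lengths named vector of chromosome lengths.
#' @param arm_mask optional interval `data.frame` of excluded regions.
#' @return `data.frame` with columns `igr_id`, `chrom`, `start`, `end`,
#'   `length`, `left_gene`, `right_gene`, `orientation`,
#'   `second_orientation`.
#' @export
derive_igrs <- function(genes, chrom_lengths, arm_mask = NULL) {
  res <- list()
  for (chr in names(chrom_lengths)) {
    g <- genes[genes$chrom == chr, , drop = FALSE]
    g <- g[order(g$span_start, g$span_end), , drop = FALSE]
    len <- as.numeric(chrom_lengths[chr])
    if (nrow(g) == 0) {
      gaps <- data.frame(start = 0, end = len, left = NA_integer_,
                         right = NA_integer_)
    } else {
      # merge overlapping/bookended gene spans into clusters
      cl_id <- cumsum(c(1, as.integer(g$span_start[-1] >
                                        cummax(g$span_end)[-nrow(g)])))
      cl_end <- tapply(g$span_end, cl_id, max)
      cl_start <- tapply(g$span_start, cl_id, min)
      ncl <- length(cl_end)
      starts <- c(0, unname(cl_end))
      ends <- c(unname(cl_start), len)
      gaps <- data.frame(start = starts, end = ends,
                         left = c(NA_integer_, seq_len(ncl)),
                         right = c(seq_len(ncl), NA_integer_))
    }
    gaps <- gaps[gaps$end > gaps$start, , drop = FALSE]
    if (nrow(gaps) == 0) next

    flank_info <- function(cluster, side) {
      # innermost gene of the flanking cluster plus the next one outward
      if (is.na(cluster)) return(c(NA_character_, NA_character_,
                                   NA_character_, NA_character_))
      if (side == "left") {
        pool <- g[cl_id <= cluster, , drop = FALSE]
        pool <- pool[order(-pool$span_end, -pool$span_start), , drop = FALSE]
      } else {
        pool <- g[cl_id >= cluster, , drop = FALSE]
        pool <- pool[order(pool$span_start, pool$span_end), , drop = FALSE]
      }
      c(pool$gene_id[1], pool$strand[1],
        if (nrow(pool) >= 2) pool$gene_id[2] else NA_character_,
        if (nrow(pool) >= 2) pool$strand[2] else NA_character_)
    }
    li <- t(vapply(gaps$left, flank_info, character(4), side = "left"))
    ri <- t(vapply(gaps$right, flank_info, character(4), side = "right"))
    res[[chr]] <- data.frame(
      chrom = chr, start = gaps$start, end = gaps$end,
      left_gene = li[, 1], right_gene = ri[, 1],
      left_strand = li[, 2], right_strand = ri[, 2],
      left2_strand = li[, 4], right2_strand = ri[, 4],
      stringsAsFactors = FALSE)
  }
  igrs <- do.call(rbind, res)
  if (is.null(igrs) || nrow(igrs) == 0) stop("no intergenic regions derived")

  # clip to arms
  if (!is.null(arm_mask) && nrow(arm_mask) > 0) {
    arms <- genome_arms(chrom_lengths, arm_mask)
    hits <- gi_overlap_pairs(igrs, arms)
    pieces <- igrs[hits$i, , drop = FALSE]
    pieces$start <- pmax(pieces$start, arms$start[hits$j])
    pieces$end <- pmin(pieces$end, arms$end[hits$j])
    igrs <- pieces[pieces$end > pieces$start, , drop = FALSE]
  }
  igrs <- igrs[order(igrs$chrom, igrs$start), , drop = FALSE]
  igrs$orientation <- classify_orientation(igrs$left_strand,
                                           igrs$right_strand)
  igrs$second_orientation <- classify_orientation(igrs$left2_strand,
                                                  igrs$right2_strand)
  igrs$length <- igrs$end - igrs$start
  igrs$igr_id <- sprintf("IGR_%s_%d", igrs$chrom, as.integer(igrs$start))
  rownames(igrs) <- NULL
  igrs[, c("igr_id", "chrom", "start", "end", "length", "left_gene",
           "right_gene", "left_strand", "right_strand", "orientation",
           "second_orientation")]
}
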