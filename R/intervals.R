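#' Genomic interval tables
#'
#' All coordinates inside the package are 0-based half-open (`[start, end)`),
#' the BED convention. GFF3 input is converted on read. `gi()` builds a
#' validated interval `data.frame` with columns `chrom`, `start`, `end` and
#' `strand` (one of `"+"`, `"-"`, `"."`).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `0 <= start < end`.
#' @param strand strand characters, recycled; default `"."`.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @export
gi <- function(chrom, start, end, strand = ".") {
  n <- max(length(chrom), length(start), length(end))
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = rep_len(as.numeric(start), n),
                   end = rep_len(as.numeric(end), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  validate_gi(df)
  df
}

validate_gi <- function(df, chrom_lengths = NULL) {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  if (any(df$start < 0)) stop("interval start must be >= 0")
  if (any(df$end <= df$start)) stop("interval end must exceed start")
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[df$chrom]
    if (any(is.na(len))) stop("interval on unknown chromosome")
    if (any(df$end > len)) stop("interval extends past chromosome end")
  }
  invisible(df)
}

#' Convert between interval tables and GRanges
#'
#' `gi2gr()` maps 0-based half-open rows to a 1-based closed
#' [GenomicRanges::GRanges]; `gr2gi()` is the inverse.
#'
#' @param df interval `data.frame` as built by [gi()].
#' @param gr a `GRanges` object.
#' @return A `GRanges` object, or an interval `data.frame`.
#' @export
gi2gr <- function(df) {
  strand <- if ("strand" %in% names(df)) df$strand else "."
  strand[strand == "."] <- "*"
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end),
                         strand = strand)
}

#' @rdname gi2gr
#' @export
gr2gi <- function(gr) {
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1,
             end = BiocGenerics::end(gr),
             strand = strand,
             stringsAsFactors = FALSE)
}

# Merge intervals overlapping by >= 1 bp (strand ignored); sorted output.
gi_reduce <- function(df) {
  if (nrow(df) == 0) return(gi_empty())
  gr <- gi2gr(df)
  BiocGenerics::strand(gr) <- "*"
  out <- gr2gi(GenomicRanges::reduce(gr, min.gapwidth = 0L))
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Pairs (i, j) such that a[i, ] and b[j, ] share >= 1 bp.
gi_overlap_pairs <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0)
    return(data.frame(i = integer(0), j = integer(0), width = integer(0)))
  ga <- gi2gr(a); gb <- gi2gr(b)
  BiocGenerics::strand(ga) <- "*"; BiocGenerics::strand(gb) <- "*"
  h <- GenomicRanges::findOverlaps(ga, gb, minoverlap = 1L)
  i <- S4Vectors::queryHits(h); j <- S4Vectors::subjectHits(h)
  w <- pmin(a$end[i], b$end[j]) - pmax(a$start[i], b$start[j])
  data.frame(i = i, j = j, width = w)
}

# Per-chromosome complement of df within the intervals of `universe`.
gi_complement <- function(df, universe) {
  gu <- gi2gr(universe)
  if (nrow(df) == 0) return(gr2gi(gu))
  gd <- gi2gr(df)
  BiocGenerics::strand(gu) <- "*"; BiocGenerics::strand(gd) <- "*"
  out <- gr2gi(GenomicRanges::setdiff(gu, gd, ignore.strand = TRUE))
  out[order(out$chrom, out$start), , drop = FALSE]
}

gi_empty <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             strand = character(0), stringsAsFactors = FALSE)
}

# Deterministic seed scoping: run `expr` under `seed` and restore the RNG
# state afterwards, so library code never perturbs the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a stage seed from a master seed; stays inside 32-bit integer range.
derive_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}
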