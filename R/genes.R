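#' Read gene models from GFF3
#'
#' Builds UTR-extended gene models. Genes carrying explicit
#' `five_prime_UTR`/`three_prime_UTR` children keep them; genes without are
#' extended by the genome-wide mean UTR lengths of fission yeast protein-coding
#' genes (293 bp 5', 430 bp 3'), strand-mirrored and clamped to the
#' chromosome. Dubious ORFs, flagged by a keyword in any attribute column,
#' are excluded.
#'
#' Output coordinates are 0-based half-open. `tss` and `tts` are the
#' transcription start/termination coordinates (for a minus-strand gene
#' `tss > tts`); `span_start`/`span_end` bound the transcript extent used for
#' intergenic-region derivation.
#'
#' @param path GFF3 file (1-based inclusive, converted on read).
#' @param utr5_default,utr3_default default UTR extensions in bp.
#' @param chrom_lengths optional named vector used for clamping and bounds
#'   checks.
#' @param dubious_keywords character vector; a gene whose attributes contain
#'   any of these (case-insensitive) is dropped.
#' @return `data.frame` with columns `gene_id`, `chrom`, `orf_start`,
#'   `orf_end`, `strand`, `tss`, `tts`, `span_start`, `span_end`, `rpkm`.
#' @export
read_genes <- function(path, utr5_default = 293, utr3_default = 430,
                       chrom_lengths = NULL,
                       dubious_keywords = c("dubious")) {
  gff <- rtracklayer::import(path, format = "GFF3")
  df <- as.data.frame(gff)
  types <- as.character(df$type)
  genes <- df[types == "gene", , drop = FALSE]
  if (nrow(genes) == 0) stop("no gene records in GFF3: ", path)
  ids <- as.character(genes$ID)
  if (anyDuplicated(ids)) stop("duplicate gene IDs in GFF3: ", path)
  strand <- as.character(genes$strand)
  if (any(!strand %in% c("+", "-")))
    stop("gene without strand in GFF3: ",
         paste(ids[!strand %in% c("+", "-")], collapse = ", "))

  # attribute keyword filter for dubious ORFs
  chr_cols <- names(df)[vapply(df, is.character, logical(1))]
  attr_text <- do.call(paste, c(lapply(chr_cols, function(cn) {
    v <- genes[[cn]]; v[is.na(v)] <- ""
    v
  }), sep = " "))
  pat <- paste(dubious_keywords, collapse = "|")
  keep <- !grepl(pat, attr_text, ignore.case = TRUE)
  genes <- genes[keep, , drop = FALSE]
  ids <- ids[keep]; strand <- strand[keep]

  orf_start <- genes$start - 1  # to 0-based half-open
  orf_end <- genes$end
  chrom <- as.character(genes$seqnames)
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[chrom]
    if (any(is.na(len))) stop("gene on unknown chromosome")
    if (any(orf_start < 0 | orf_end > len))
      stop("CDS outside chromosome bounds")
  }

  # explicit UTRs, matched to parents
  utr5 <- rep(NA_real_, length(ids)); utr3 <- rep(NA_real_, length(ids))
  utr <- df[types %in% c("five_prime_UTR", "three_prime_UTR"), , drop = FALSE]
  if (nrow(utr) > 0 && "Parent" %in% names(df)) {
    parent <- vapply(utr$Parent, function(p) as.character(p)[1], character(1))
    m <- match(parent, ids)
    for (r in which(!is.na(m))) {
      i <- m[r]
      w <- utr$end[r] - (utr$start[r] - 1)
      if (as.character(utr$type[r]) == "five_prime_UTR") utr5[i] <- w
      else utr3[i] <- w
    }
  }
  utr5[is.na(utr5)] <- utr5_default
  utr3[is.na(utr3)] <- utr3_default

  plus <- strand == "+"
  tss <- ifelse(plus, orf_start - utr5, orf_end + utr5)
  tts <- ifelse(plus, orf_end + utr3, orf_start - utr3)
  if (!is.null(chrom_lengths)) {
    len <- as.numeric(chrom_lengths[chrom])
    tss <- pmin(pmax(tss, 0), len)
    tts <- pmin(pmax(tts, 0), len)
  } else {
    tss <- pmax(tss, 0); tts <- pmax(tts, 0)
  }
  out <- data.frame(gene_id = ids, chrom = chrom,
                    orf_start = orf_start, orf_end = orf_end,
                    strand = strand, tss = tss, tts = tts,
                    span_start = pmin(tss, tts), span_end = pmax(tss, tts),
                    rpkm = NA_real_, stringsAsFactors = FALSE)
  out[order(out$chrom, out$span_start), , drop = FALSE]
}

#' Write gene models to GFF3
#'
#' Companion writer used by the synthetic-genome generator; emits one `gene`
#' row per model (ORF coordinates, 1-based inclusive).
#'
#' @param genes gene model `data.frame` (see [read_genes()]).
#' @param path output path.
#' @param dubious optional logical vector; flagged genes get a
#'   `note=dubious` attribute.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(genes, path, dubious = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  note <- if (is.null(dubious)) rep("", nrow(genes)) else
    ifelse(dubious, ";note=dubious", "")
  lines <- sprintf("%s\toriscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s%s",
                   genes$chrom, as.integer(genes$orf_start + 1),
                   as.integer(genes$orf_end), genes$strand,
                   genes$gene_id, note)
  writeLines(lines, con)
  invisible(path)
}

#' Reads per kilobase of exon per million mapped reads
#'
#' @param count mapped reads on the gene's exons.
#' @param exon_length_bp summed exon length in bp (> 0).
#' @param total_mapped total mapped reads in the library (> 0).
#' @return RPKM value(s).
#' @export
compute_rpkm <- function(count, exon_length_bp, total_mapped) {
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0")
  if (any(exon_length_bp <= 0)) stop("exon_length_bp must be > 0")
  count / ((exon_length_bp / 1000) * (total_mapped / 1e6))
}

#' Attach expression levels to gene models
#'
#' @param genes gene model `data.frame`.
#' @param expression `data.frame` with columns `gene_id` and `rpkm`, e.g.
#'   read from a TSV.
#' @return `genes` with the `rpkm` column filled (unmatched genes keep `NA`).
#' @export
attach_expression <- function(genes, expression) {
  m <- match(genes$gene_id, expression$gene_id)
  genes$rpkm <- expression$rpkm[m]
  genes
}
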