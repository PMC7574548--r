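#' Motif positions around sites, oriented toward the nearest motif
#'
#' For each site, the signed offsets of motif-union midpoints within
#' `half_width` bp of the Orc4 summit; sites whose nearest motif lies
#' leftward are flipped (offsets negated) so the nearest motif is always on
#' the right, the convention used for motif-positioning heatmaps.
#'
#' @param summits `data.frame` with columns `chrom`, `summit`.
#' @param union_sites motif-union `data.frame`.
#' @param half_width window half-width in bp.
#' @return `data.frame` with `site`, `offset` (bp, flipped), `flipped`.
#' @export
motif_position_matrix <- function(summits, union_sites, half_width = 1000) {
  rows <- list()
  for (i in seq_len(nrow(summits))) {
    u <- union_sites[union_sites$chrom == summits$chrom[i], , drop = FALSE]
    off <- (u$start + u$end) / 2 - summits$summit[i]
    off <- off[abs(off) <= half_width]
    if (length(off) == 0) next
    flip <- off[which.min(abs(off))] < 0
    if (flip) off <- -off
    rows[[length(rows) + 1]] <- data.frame(site = i, offset = sort(off),
                                           flipped = flip)
  }
  if (length(rows) == 0)
    return(data.frame(site = integer(0), offset = numeric(0),
                      flipped = logical(0)))
  do.call(rbind, rows)
}

#' Fold enrichment grouped by nearby motif count
#'
#' Groups sites by the number of motif-union sites within `radius` bp of the
#' summit, reporting each site's summit FE, per-group medians, and
#' Mann-Whitney p-values between adjacent motif-count groups.
#'
#' @param summits `data.frame` with `chrom`, `summit`, `max_fe`.
#' @param union_sites motif-union `data.frame`.
#' @param radius half-width in bp.
#' @return List: `table` (site-level), `medians`, `adjacent_p`.
#' @export
fe_by_motif_count <- function(summits, union_sites, radius = 250) {
  n <- vapply(seq_len(nrow(summits)), function(i)
    count_motifs_near(union_sites, summits$chrom[i], summits$summit[i],
                      radius), integer(1))
  tab <- data.frame(motif_count = n, fe = summits$max_fe)
  counts <- sort(unique(n))
  med <- vapply(counts, function(k) stats::median(tab$fe[n == k]),
                numeric(1))
  names(med) <- counts
  adj <- NULL
  if (length(counts) > 1) {
    adj <- vapply(seq_len(length(counts) - 1), function(j)
      mann_whitney_two_sided(tab$fe[n == counts[j]],
                             tab$fe[n == counts[j + 1]]), numeric(1))
    names(adj) <- paste(counts[-length(counts)], counts[-1], sep = "_vs_")
  }
  list(table = tab, medians = med, adjacent_p = adj)
}

#' Summit-offset class of an OM site
#'
#' Sign of the Mcm-minus-Orc summit offset, with a dead zone within which
#' the peaks are called overlapping.
#'
#' @param offset signed offset(s) `mcm_summit - orc_summit` in bp.
#' @param dead_zone absolute offset at or below which the class is
#'   `"overlap"`.
#' @return Character vector in `{"left", "overlap", "right"}`.
#' @export
offset_class <- function(offset, dead_zone = 100) {
  ifelse(abs(offset) <= dead_zone, "overlap",
         ifelse(offset > 0, "right", "left"))
}

#' Flanking AT content joined with summit-offset class
#'
#' AT fractions of the two 400 bp segments flanking each OM Orc4 summit
#' (`-500..-100` and `+100..+500`) together with the site's offset class,
#' the table behind the flank-asymmetry analysis: Mcm-shifted sites are
#' AT-richer on the Mcm side.
#'
#' @param site_set a `site_set`.
#' @param genome named character vector of sequences.
#' @param dead_zone see [offset_class()].
#' @return `data.frame` with `chrom`, `orc_summit`, `left_at`, `right_at`,
#'   `offset`, `offset_class`.
#' @export
flank_asymmetry_table <- function(site_set, genome, dead_zone = 100) {
  om <- site_set$om
  if (nrow(om) == 0)
    return(data.frame(chrom = character(0), orc_summit = numeric(0),
                      left_at = numeric(0), right_at = numeric(0),
                      offset = numeric(0), offset_class = character(0)))
  fl <- t(vapply(seq_len(nrow(om)), function(i)
    flank_at(genome[[om$chrom[i]]], om$orc_summit[i]), numeric(2)))
  off <- om$mcm_summit - om$orc_summit
  data.frame(chrom = om$chrom, orc_summit = om$orc_summit,
             left_at = fl[, 1], right_at = fl[, 2], offset = off,
             offset_class = offset_class(off, dead_zone),
             stringsAsFactors = FALSE)
}

#' Intergenic/intragenic placement of sites
#'
#' Assigns each site by its Orc4 summit point: inside an IGR interval it is
#' intergenic, otherwise intragenic. Returns per-class proportions.
#'
#' @param site_set a `site_set`.
#' @param igrs IGR `data.frame`.
#' @return `data.frame` with rows `OM`/`O` and columns `n`, `intergenic`,
#'   `intragenic`, `prop_intergenic`.
#' @export
placement_table <- function(site_set, igrs) {
  place <- function(chrom, pos) {
    idx <- point_in_igr(igrs, chrom, pos)
    c(inter = sum(!is.na(idx)), intra = sum(is.na(idx)))
  }
  om <- place(site_set$om$chrom, site_set$om$orc_summit)
  o <- place(site_set$o$chrom, site_set$o$summit)
  out <- data.frame(class = c("OM", "O"),
                    n = c(sum(om), sum(o)),
                    intergenic = c(om["inter"], o["inter"]),
                    intragenic = c(om["intra"], o["intra"]))
  out$prop_intergenic <- ifelse(out$n > 0, out$intergenic / out$n, NA)
  rownames(out) <- NULL
  out
}

#' Stratified feature histogram of IGRs
#'
#' Cross-tabulates IGRs by an L_AT stratum and a second feature stratum
#' (motif count or L_ntx), split by site class (OM / O / other), the
#' stacked-histogram summary relating the core features to OM-site
#' presence.
#'
#' @param features `data.frame` with columns `l_at`, plus the `by` column
#'   and `class` in `{OM, O, other}`.
#' @param by second stratification column name (e.g. `"n_mt"`, `"l_ntx"`).
#' @param l_at_breaks lower edges of the L_AT strata (a first stratum below
#'   the smallest break is added).
#' @param by_breaks breaks for the second feature.
#' @return `data.frame` of counts per `(l_at_stratum, by_stratum, class)`.
#' @export
stratified_feature_histogram <- function(features, by = "n_mt",
                                         l_at_breaks = c(200, 250, 400),
                                         by_breaks = c(1, 2, 3)) {
  lab <- function(x, breaks) {
    b <- c(-Inf, breaks, Inf)
    cut(x, b, right = FALSE)
  }
  f <- data.frame(l_at_stratum = lab(features$l_at, l_at_breaks),
                  by_stratum = lab(features[[by]], by_breaks),
                  class = factor(features$class,
                                 levels = c("OM", "O", "other")))
  out <- as.data.frame(table(f), stringsAsFactors = FALSE)
  names(out)[4] <- "count"
  out
}
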