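#' Build a fixed-width analysis window around an anchor
#'
#' The window is `[anchor - floor(width/2), anchor + ceiling(width/2))`
#' (left-biased for odd widths).
#'
#' @param anchor 0-based anchor coordinate (peak summit or IGR midpoint).
#' @param width window width in bp.
#' @param chrom_length chromosome length for the bounds check.
#' @return Named vector `c(start, end)`.
#' @export
build_window <- function(anchor, width = 1000, chrom_length) {
  start <- anchor - floor(width / 2)
  end <- anchor + ceiling(width / 2)
  if (start < 0 || end > chrom_length)
    stop("window extends outside the chromosome")
  c(start = start, end = end)
}

# shift an anchor inward so its window fits the chromosome
shift_anchor_inbounds <- function(anchor, width, chrom_length) {
  lo <- floor(width / 2)
  hi <- chrom_length - ceiling(width / 2)
  min(max(anchor, lo), hi)
}

#' Names of the default per-window feature set
#' @return Character vector of the 13 feature names.
#' @export
feature_names <- function() {
  c("n_mt", "l_at", "l_ntx", "at_mean", "at_max_101", "dg_min_200",
    "motif_score_sum", "motif_dist_center", "run_max_at", "igr_length",
    "rpkm_min_flank", "is_divergent", "is_convergent")
}

#' Score the per-window feature vector
#'
#' Computes the default 13-feature vector for a 1 kb window: the core trio
#' `n_mt` (motif-union sites in the window), `l_at` (bp with 101 bp-window AT
#' fraction >= 0.75) and `l_ntx` (longest run of RNA-seq depth <= 1), plus
#' AT-content summaries (`at_mean`, `at_max_101`, `run_max_at`), melting
#' energy minimum (`dg_min_200`), motif score/position summaries, and the
#' IGR context (length, min flanking expression, orientation indicators;
#' zero for intragenic windows).
#'
#' @param genome named character vector of sequences.
#' @param union_sites motif-union `data.frame`.
#' @param coverage named list of per-base RNA-seq depth vectors.
#' @param chrom chromosome name.
#' @param anchor 0-based window anchor.
#' @param width window width in bp.
#' @param igr_length length of the host IGR (0 when intragenic).
#' @param orientation host IGR orientation class (`"edge"` when intragenic).
#' @param rpkm_flank minimum flanking-gene expression (RPKM).
#' @param at_threshold,at_w L_AT parameters.
#' @param melt_window delta-G window width.
#' @param max_count L_ntx depth cutoff.
#' @return Named numeric vector, see [feature_names()].
#' @export
extract_features <- function(genome, union_sites, coverage, chrom, anchor,
                             width = 1000, igr_length = 0,
                             orientation = "edge", rpkm_flank = 0,
                             at_threshold = 0.75, at_w = 101,
                             melt_window = 200, max_count = 1) {
  seq <- genome[[chrom]]
  n <- nchar(seq)
  win <- build_window(anchor, width, n)
  start <- win["start"]; end <- win["end"]

  lat <- l_at(seq, start, end, w = at_w, threshold = at_threshold)
  lntx <- l_ntx(coverage[[chrom]], start, end, max_count = max_count)

  u <- union_sites[union_sites$chrom == chrom, , drop = FALSE]
  mid <- (u$start + u$end) / 2
  inwin <- mid >= anchor - width / 2 & mid <= anchor + width / 2
  nmt <- sum(inwin)
  score_sum <- if (nmt > 0) sum(u$score[inwin]) else 0
  dist_center <- if (nmt > 0) min(abs(mid[inwin] - anchor)) else width / 2

  excerpt <- substr(seq, start + 1, end)
  pad <- floor(melt_window / 2)
  mlo <- max(start - pad, 0); mhi <- min(end + pad, n)
  dg <- delta_g_melt_profile(substr(seq, mlo + 1, mhi), window = melt_window)
  idx <- (start - mlo + 1):(end - mlo)
  dgw <- dg[idx]
  dg_min <- if (all(is.na(dgw))) 0 else min(dgw, na.rm = TRUE)

  # local AT profile over the window (windows may reach into flanks)
  apad <- floor(at_w / 2)
  alo <- max(start - apad, 0); ahi <- min(end + apad, n)
  b <- seq_ints(substr(seq, alo + 1, ahi))
  prof <- centered_window_mean(as.numeric(b %in% c(1, 4)), at_w)
  at_max <- max(prof[(start - alo + 1):(end - alo)])

  c(n_mt = nmt, l_at = lat, l_ntx = lntx,
    at_mean = at_fraction(excerpt),
    at_max_101 = at_max, dg_min_200 = dg_min,
    motif_score_sum = score_sum, motif_dist_center = dist_center,
    run_max_at = run_max_at(excerpt),
    igr_length = igr_length, rpkm_min_flank = rpkm_flank,
    is_divergent = as.numeric(orientation == "divergent"),
    is_convergent = as.numeric(orientation == "convergent"))
}

# feature matrix for a table of (chrom, anchor, igr_length, orientation,
# rpkm_flank) rows
extract_feature_matrix <- function(windows, genome, union_sites, coverage,
                                   width = 1000, ...) {
  X <- t(vapply(seq_len(nrow(windows)), function(i) {
    extract_features(genome, union_sites, coverage,
                     chrom = windows$chrom[i], anchor = windows$anchor[i],
                     width = width, igr_length = windows$igr_length[i],
                     orientation = windows$orientation[i],
                     rpkm_flank = windows$rpkm_flank[i], ...)
  }, numeric(13)))
  colnames(X) <- feature_names()
  X
}

# index of the IGR containing each point (NA when intergenic to none)
point_in_igr <- function(igrs, chrom, pos) {
  vapply(seq_along(pos), function(k) {
    hit <- which(igrs$chrom == chrom[k] & igrs$start <= pos[k] &
                   igrs$end > pos[k])
    if (length(hit) == 0) NA_integer_ else hit[1]
  }, integer(1))
}

min_flank_rpkm <- function(igrs, genes, idx) {
  vapply(idx, function(i) {
    r <- c(genes$rpkm[match(igrs$left_gene[i], genes$gene_id)],
           genes$rpkm[match(igrs$right_gene[i], genes$gene_id)])
    r <- r[!is.na(r)]
    if (length(r) == 0) 0 else min(r)
  }, numeric(1))
}

#' Build the intergenic classification dataset
#'
#' Positive windows are centred on the Orc4 summits of intergenic OM sites;
#' negative windows on the midpoints of IGRs containing no OM site. Under
#' `policy = "holdout_o"` the IGRs containing O sites are excluded from the
#' negatives and returned separately for probability scoring; under
#' `"include_o"` they are negatives.
#'
#' @param igrs IGR `data.frame` from [derive_igrs()].
#' @param site_set a `site_set` from [classify_sites()].
#' @param genome,union_sites,coverage feature inputs, see
#'   [extract_features()].
#' @param genes gene models with expression attached.
#' @param policy O-site IGR handling.
#' @param width window width in bp.
#' @return List with elements `X` (feature matrix), `y` (factor
#'   `pos`/`neg`), `meta` (window table) and, under the hold-out policy,
#'   `heldout_X`/`heldout_meta` for the O-site IGR windows.
#' @export
build_igr_dataset <- function(igrs, site_set, genome, union_sites, coverage,
                              genes, policy = c("holdout_o", "include_o"),
                              width = 1000) {
  policy <- match.arg(policy)
  lens <- chrom_lengths(genome)

  om <- site_set$om
  om_igr <- point_in_igr(igrs, om$chrom, om$orc_summit)
  pos_sel <- !is.na(om_igr)
  if (!any(pos_sel)) stop("no intergenic OM sites: nothing to train on")
  pos <- data.frame(
    chrom = om$chrom[pos_sel],
    anchor = vapply(which(pos_sel), function(k)
      shift_anchor_inbounds(om$orc_summit[k], width,
                            lens[om$chrom[k]]), numeric(1)),
    igr_length = igrs$length[om_igr[pos_sel]],
    orientation = igrs$orientation[om_igr[pos_sel]],
    rpkm_flank = min_flank_rpkm(igrs, genes, om_igr[pos_sel]),
    igr_id = igrs$igr_id[om_igr[pos_sel]],
    stringsAsFactors = FALSE)

  o <- site_set$o
  o_igr <- unique(stats::na.omit(point_in_igr(igrs, o$chrom, o$summit)))
  om_igr_ids <- unique(stats::na.omit(om_igr))

  neg_idx <- setdiff(seq_len(nrow(igrs)), om_igr_ids)
  held_idx <- setdiff(o_igr, om_igr_ids)
  if (policy == "holdout_o") neg_idx <- setdiff(neg_idx, held_idx)

  igr_windows <- function(idx) {
    if (length(idx) == 0) return(NULL)
    data.frame(
      chrom = igrs$chrom[idx],
      anchor = vapply(idx, function(i)
        shift_anchor_inbounds(floor((igrs$start[i] + igrs$end[i]) / 2),
                              width, lens[igrs$chrom[i]]), numeric(1)),
      igr_length = igrs$length[idx],
      orientation = igrs$orientation[idx],
      rpkm_flank = min_flank_rpkm(igrs, genes, idx),
      igr_id = igrs$igr_id[idx],
      stringsAsFactors = FALSE)
  }
  neg <- igr_windows(neg_idx)
  held <- igr_windows(held_idx)

  meta <- rbind(cbind(pos, class = "pos", stringsAsFactors = FALSE),
                cbind(neg, class = "neg", stringsAsFactors = FALSE))
  X <- extract_feature_matrix(meta, genome, union_sites, coverage, width)
  out <- list(X = X, y = factor(meta$class, levels = c("neg", "pos")),
              meta = meta)
  if (policy == "holdout_o" && !is.null(held)) {
    out$heldout_X <- extract_feature_matrix(held, genome, union_sites,
                                            coverage, width)
    out$heldout_meta <- held
  }
  out
}

#' Build the intragenic evaluation dataset
#'
#' Positives are the intragenic OM sites (Orc4 summit inside a gene span);
#' controls are sampled uniformly from arm positions farther than `min_dist`
#' from any OM or O peak interval. Only the core trio (`n_mt`, `l_at`,
#' `l_ntx`) is scored, matching the intragenic analysis design.
#'
#' @param site_set a `site_set`.
#' @param igrs IGR table (used to decide intergenic placement).
#' @param genome,union_sites,coverage feature inputs.
#' @param arms interval `data.frame` of chromosome arms.
#' @param n_controls_per_pos controls per positive.
#' @param min_dist minimum distance (bp) from any OM/O interval.
#' @param width window width.
#' @param seed RNG seed for control sampling.
#' @return List with `X` (trio feature matrix), `y`, `meta`.
#' @export
build_intragenic_dataset <- function(site_set, igrs, genome, union_sites,
                                     coverage, arms,
                                     n_controls_per_pos = 5,
                                     min_dist = 1000, width = 1000,
                                     seed = NULL) {
  lens <- chrom_lengths(genome)
  om <- site_set$om
  om_igr <- point_in_igr(igrs, om$chrom, om$orc_summit)
  intra <- which(is.na(om_igr))
  if (length(intra) == 0) stop("no intragenic OM sites")
  pos <- data.frame(chrom = om$chrom[intra],
                    anchor = om$orc_summit[intra],
                    stringsAsFactors = FALSE)
  pos <- pos[pos$anchor - floor(width / 2) >= 0 &
               pos$anchor + ceiling(width / 2) <= lens[pos$chrom], ,
             drop = FALSE]

  occupied <- rbind(
    data.frame(chrom = om$chrom, start = om$orc_start, end = om$orc_end),
    if (nrow(site_set$o) > 0)
      data.frame(chrom = site_set$o$chrom, start = site_set$o$start,
                 end = site_set$o$end))
  n_controls <- n_controls_per_pos * nrow(pos)
  controls <- with_seed(seed, {
    picked <- data.frame(chrom = character(0), anchor = numeric(0))
    arm_w <- arms$end - arms$start
    while (nrow(picked) < n_controls) {
      k <- sample.int(nrow(arms), 1, prob = arm_w)
      p <- floor(stats::runif(1, arms$start[k], arms$end[k]))
      chr <- arms$chrom[k]
      if (p - floor(width / 2) < 0 || p + ceiling(width / 2) > lens[chr])
        next
      occ <- occupied[occupied$chrom == chr, , drop = FALSE]
      d <- if (nrow(occ) == 0) Inf else
        min(pmax(occ$start - p, p - occ$end + 1, 0))
      if (d > min_dist)
        picked <- rbind(picked, data.frame(chrom = chr, anchor = p))
    }
    picked
  })

  meta <- rbind(cbind(pos, class = "pos", stringsAsFactors = FALSE),
                cbind(controls, class = "neg", stringsAsFactors = FALSE))
  meta$igr_length <- 0; meta$orientation <- "edge"; meta$rpkm_flank <- 0
  X <- extract_feature_matrix(meta, genome, union_sites, coverage, width)
  X <- X[, c("n_mt", "l_at", "l_ntx"), drop = FALSE]
  list(X = X, y = factor(meta$class, levels = c("neg", "pos")), meta = meta)
}
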