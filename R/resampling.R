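#' Percentile bootstrap confidence interval
#'
#' Resamples `values` with replacement `reps` times, applies `statistic`,
#' and reports the 2.5 and 97.5 empirical percentiles.
#'
#' @param values numeric sample.
#' @param statistic function of a numeric vector; default mean.
#' @param reps bootstrap resamples.
#' @param seed RNG seed.
#' @return List with `estimate`, `lower`, `upper`, `n_reps`.
#' @export
bootstrap_ci <- function(values, statistic = mean, reps = 10000,
                         seed = NULL) {
  if (length(values) == 0) stop("empty input to bootstrap_ci")
  stat <- with_seed(seed, {
    vapply(seq_len(reps), function(i)
      statistic(values[sample.int(length(values), replace = TRUE)]),
      numeric(1))
  })
  q <- stats::quantile(stat, c(0.025, 0.975), names = FALSE)
  list(estimate = statistic(values), lower = q[1], upper = q[2],
       n_reps = reps)
}

#' Monte Carlo motif-proximity expectation at random sites
#'
#' Null model for the fraction of sites with at least one poly(dA)
#' motif-union site within `radius` bp: each replicate draws `n_sites`
#' positions uniformly from the unmasked arms (excluding positions whose
#' `radius` window leaves the arm) and measures the fraction with a motif
#' midpoint in the closed `+/- radius` interval. The 2.5/97.5 percentiles
#' across replicates give the 95% band.
#'
#' @param arms interval `data.frame` of chromosome arms.
#' @param union_sites motif-union `data.frame`.
#' @param n_sites sites per replicate (e.g. the observed OM count).
#' @param radius half-width in bp.
#' @param reps Monte Carlo replicates.
#' @param seed RNG seed.
#' @return List as in [bootstrap_ci()] (estimate = mean fraction).
#' @export
random_site_motif_expectation <- function(arms, union_sites, n_sites,
                                          radius = 250, reps = 200,
                                          seed = NULL) {
  arms <- arms[arms$end - arms$start > 2 * radius, , drop = FALSE]
  if (nrow(arms) == 0) stop("no arm wide enough for the radius")
  w <- arms$end - arms$start - 2 * radius
  mids <- lapply(unique(arms$chrom), function(chr) {
    m <- union_sites[union_sites$chrom == chr, , drop = FALSE]
    sort((m$start + m$end) / 2)
  })
  names(mids) <- unique(arms$chrom)
  fracs <- with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      k <- sample.int(nrow(arms), n_sites, replace = TRUE, prob = w)
      pos <- floor(stats::runif(n_sites, arms$start[k] + radius,
                                arms$end[k] - radius))
      hit <- vapply(seq_len(n_sites), function(j) {
        m <- mids[[arms$chrom[k[j]]]]
        if (length(m) == 0) return(FALSE)
        i1 <- findInterval(pos[j] - radius - 1e-9, m)
        i2 <- findInterval(pos[j] + radius + 1e-9, m)
        i2 > i1
      }, logical(1))
      mean(hit)
    }, numeric(1))
  })
  q <- stats::quantile(fracs, c(0.025, 0.975), names = FALSE)
  list(estimate = mean(fracs), lower = q[1], upper = q[2], n_reps = reps)
}

#' Monte Carlo orientation profile of randomly sampled IGRs
#'
#' Each replicate samples `n_sample` IGRs without replacement and records
#' the proportion of each orientation class; percentile bands are computed
#' per class.
#'
#' @param igrs IGR `data.frame`.
#' @param n_sample IGRs per replicate.
#' @param reps replicates.
#' @param seed RNG seed.
#' @return Named list of per-class `list(estimate, lower, upper)` for
#'   `divergent`, `tandem`, `convergent`.
#' @export
random_igr_orientation <- function(igrs, n_sample, reps = 200,
                                   seed = NULL) {
  cls <- c("divergent", "tandem", "convergent")
  props <- with_seed(seed, {
    t(vapply(seq_len(reps), function(i) {
      s <- igrs$orientation[sample.int(nrow(igrs), n_sample)]
      vapply(cls, function(cl) mean(s == cl), numeric(1))
    }, numeric(3)))
  })
  out <- lapply(seq_along(cls), function(j) {
    q <- stats::quantile(props[, j], c(0.025, 0.975), names = FALSE)
    list(estimate = mean(props[, j]), lower = q[1], upper = q[2])
  })
  names(out) <- cls
  out
}

#' Length-controlled Monte Carlo orientation profile
#'
#' Samples IGRs so that each replicate's length distribution matches a
#' target set of lengths (e.g. the lengths of OM-site IGRs): lengths are
#' stratified into `n_strata` quantile bins of the pooled IGR length
#' distribution (default vigintiles, fine enough to track a long-IGR
#' target set through the heavy upper tail) and
#' each target draws uniformly from its stratum, falling back to the
#' nearest-length IGR not yet used in the replicate when a stratum is
#' exhausted.
#'
#' @param igrs IGR `data.frame`.
#' @param target_lengths lengths to match, one sampled IGR per entry.
#' @param reps replicates.
#' @param n_strata number of quantile strata.
#' @param seed RNG seed.
#' @return List with per-class CIs (as [random_igr_orientation()]) plus
#'   `sampled_lengths` from the final replicate.
#' @export
length_matched_igr_sample <- function(igrs, target_lengths, reps = 200,
                                      n_strata = 20, seed = NULL) {
  cls <- c("divergent", "tandem", "convergent")
  br <- unique(stats::quantile(igrs$length,
                               probs = seq(0, 1, length.out = n_strata + 1),
                               names = FALSE))
  stratum <- findInterval(igrs$length, br, rightmost.closed = TRUE,
                          all.inside = TRUE)
  t_stratum <- findInterval(target_lengths, br, rightmost.closed = TRUE,
                            all.inside = TRUE)
  last <- NULL
  props <- with_seed(seed, {
    t(vapply(seq_len(reps), function(i) {
      used <- rep(FALSE, nrow(igrs))
      pick <- integer(length(target_lengths))
      ord <- sample.int(length(target_lengths))
      for (t in ord) {
        cand <- which(stratum == t_stratum[t] & !used)
        if (length(cand) == 0) {
          free <- which(!used)
          cand <- free[which.min(abs(igrs$length[free] -
                                       target_lengths[t]))]
        }
        j <- if (length(cand) == 1) cand else
          cand[sample.int(length(cand), 1)]
        used[j] <- TRUE
        pick[t] <- j
      }
      last <<- pick
      s <- igrs$orientation[pick]
      vapply(cls, function(cl) mean(s == cl), numeric(1))
    }, numeric(3)))
  })
  out <- lapply(seq_along(cls), function(j) {
    q <- stats::quantile(props[, j], c(0.025, 0.975), names = FALSE)
    list(estimate = mean(props[, j]), lower = q[1], upper = q[2])
  })
  names(out) <- cls
  out$sampled_lengths <- igrs$length[last]
  out
}

#' Two-sided Mann-Whitney U test
#'
#' Thin wrapper around [stats::wilcox.test()] (two-sided, tie-corrected)
#' used for group comparisons in the report tables.
#'
#' @param a,b numeric samples.
#' @return p-value.
#' @export
mann_whitney_two_sided <- function(a, b) {
  suppressWarnings(stats::wilcox.test(a, b,
                                      alternative = "two.sided")$p.value)
}
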