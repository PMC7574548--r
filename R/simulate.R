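#' Simulation configuration for the synthetic origin study
#'
#' Defines the fission-yeast-like study conditions emulated by the
#' generator: an AT-rich multi-chromosome genome with gene/IGR structure,
#' planted OM-like IGRs (poly(dA) motifs at an Orc anchor, an adjacent
#' ~150-400 bp AT-rich segment at the Mcm anchor, a transcription-free span
#' over 1 kb), O-like IGRs (motifs only), background IGRs (small fractions
#' carrying a stray motif or AT segment, so AT content alone is an imperfect
#' predictor), plus ChIP fold-enrichment and RNA-seq coverage tracks
#' consistent with the planted truth.
#'
#' @param n_chroms chromosomes.
#' @param n_om,n_o,n_bg planted intergenic OM, O and background IGR counts.
#' @param n_om_intragenic OM sites planted inside silent host genes.
#' @param at_background genomic AT fraction.
#' @param bg_igr_meanlog,bg_igr_sdlog,bg_igr_min background IGR length
#'   log-normal parameters and floor (bp).
#' @param om_igr_meanlog,om_igr_sdlog,om_igr_min OM IGR length parameters.
#' @param o_igr_meanlog,o_igr_sdlog,o_igr_min O IGR length parameters.
#' @param orf_meanlog,orf_sdlog,orf_min ORF length parameters.
#' @param host_orf_len ORF length of intragenic-OM host genes.
#' @param utr5,utr3 UTR extensions applied to ORFs when sizing gaps, matching
#'   the annotation defaults.
#' @param motif_pwm `pwm` planted at Orc anchors.
#' @param motif_count_probs probabilities of 1, 2, 3 motifs per OM/O site.
#' @param motif_fidelity 1 plants the consensus; below 1 samples each base
#'   from the PWM columns.
#' @param bg_motif_leak,bg_at_leak per-background-IGR probabilities of a
#'   stray motif / AT-rich segment.
#' @param at_seg_min,at_seg_max,at_seg_frac AT-rich segment length range and
#'   AT fraction.
#' @param offset_near_sd,offset_far_min,offset_far_max Mcm-vs-Orc summit
#'   offset model: half the sites near-zero (half-normal, sd
#'   `offset_near_sd`), half uniform in `[offset_far_min, offset_far_max]`
#'   with random sign.
#' @param rpkm_meanlog,rpkm_sdlog gene expression log-normal parameters.
#' @param depth_per_rpkm per-base Poisson coverage rate per RPKM unit.
#' @param noise_rate background per-base coverage rate.
#' @param fe_bin FE bin width (bp).
#' @param orc_height_meanlog,orc_height_sdlog,orc_height_min,orc_sd Orc FE
#'   bump height distribution and Gaussian width (bp).
#' @param mcm_height_meanlog,mcm_height_sdlog,mcm_height_min,mcm_sd Mcm FE
#'   bump parameters.
#' @param fe_noise_sdlog multiplicative log-normal FE noise around 1.
#' @param n_m_only stray Mcm-only FE bumps per genome.
#' @param telomere_len,centromere_len masked end/central block lengths (bp).
#' @param edge_igr_len IGR length adjacent to masked blocks (bp).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 3,
                       n_om = 280, n_o = 175, n_bg = 3000,
                       n_om_intragenic = 25,
                       at_background = 0.64,
                       bg_igr_meanlog = log(250), bg_igr_sdlog = 0.6,
                       bg_igr_min = 20,
                       om_igr_meanlog = log(1500), om_igr_sdlog = 0.25,
                       om_igr_min = 1100,
                       o_igr_meanlog = log(700), o_igr_sdlog = 0.35,
                       o_igr_min = 400,
                       orf_meanlog = log(300), orf_sdlog = 0.45,
                       orf_min = 60,
                       host_orf_len = 2200,
                       utr5 = 293, utr3 = 430,
                       motif_pwm = default_polya_pwm(),
                       motif_count_probs = c(0.45, 0.35, 0.20),
                       motif_fidelity = 1,
                       bg_motif_leak = 0.10, bg_at_leak = 0.06,
                       at_seg_min = 150, at_seg_max = 400,
                       at_seg_frac = 0.85,
                       offset_near_sd = 25, offset_far_min = 100,
                       offset_far_max = 500,
                       rpkm_meanlog = log(20), rpkm_sdlog = 1,
                       depth_per_rpkm = 0.1, noise_rate = 0.02,
                       fe_bin = 10,
                       orc_height_meanlog = log(12),
                       orc_height_sdlog = 0.3, orc_height_min = 8,
                       orc_sd = 220,
                       mcm_height_meanlog = log(5),
                       mcm_height_sdlog = 0.25, mcm_height_min = 3.5,
                       mcm_sd = 215,
                       fe_noise_sdlog = 0.12,
                       n_m_only = 5,
                       telomere_len = 3000, centromere_len = 5000,
                       edge_igr_len = 200) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_om >= 0, cfg$n_o >= 0, cfg$n_bg >= 0,
            cfg$at_background > 0, cfg$at_background < 1,
            inherits(cfg$motif_pwm, "pwm"),
            abs(sum(cfg$motif_count_probs) - 1) < 1e-9)
  structure(cfg, class = "sim_config")
}

random_bases <- function(n, at_frac) {
  if (n <= 0) return(character(0))
  sample(c("A", "T", "C", "G"), n, replace = TRUE,
         prob = c(at_frac / 2, at_frac / 2, (1 - at_frac) / 2,
                  (1 - at_frac) / 2))
}

motif_instance <- function(p, fidelity) {
  bases <- c("A", "C", "G", "T")
  if (fidelity >= 1) {
    paste(bases[apply(p$matrix, 1, which.max)], collapse = "")
  } else {
    paste(vapply(seq_len(nrow(p$matrix)), function(j)
      sample(bases, 1, prob = p$matrix[j, ]), character(1)), collapse = "")
  }
}

#' Simulate the synthetic genome, annotation and ground truth
#'
#' Lays out genes and IGRs chromosome by chromosome (masked telomeres at the
#' ends and a masked centromere block mid-chromosome), plants the configured
#' OM/O/background IGR features into an i.i.d. background sequence, samples
#' gene expression, and records machine-readable ground truth.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (required; the simulation is a pure function of
#'   config and seed).
#' @return List with `genome` (named character), `genes` (gene-model
#'   `data.frame` with `rpkm`), `mask` (interval `data.frame`),
#'   `truth` (list: `sites`, `motifs` data.frames).
#' @export
simulate_genome <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, simulate_genome_impl(config))
}

simulate_genome_impl <- function(cfg) {
  n_igr <- cfg$n_om + cfg$n_o + cfg$n_bg
  classes <- sample(c(rep("OM", cfg$n_om), rep("O", cfg$n_o),
                      rep("bg", cfg$n_bg)))
  chrom_of <- sort(rep_len(seq_len(cfg$n_chroms), n_igr))

  genome <- character(cfg$n_chroms)
  names(genome) <- paste0("chr", utils::as.roman(seq_len(cfg$n_chroms)))
  genes_l <- list(); mask_l <- list(); sites_l <- list(); motifs_l <- list()
  gene_no <- 0; site_no <- 0

  sample_igr_len <- function(cl) {
    if (cl == "OM")
      max(cfg$om_igr_min, round(stats::rlnorm(1, cfg$om_igr_meanlog,
                                              cfg$om_igr_sdlog)))
    else if (cl == "O")
      max(cfg$o_igr_min, round(stats::rlnorm(1, cfg$o_igr_meanlog,
                                             cfg$o_igr_sdlog)))
    else
      max(cfg$bg_igr_min, round(stats::rlnorm(1, cfg$bg_igr_meanlog,
                                              cfg$bg_igr_sdlog)))
  }
  ext_r <- function(strand) if (strand == "+") cfg$utr3 else cfg$utr5
  ext_l <- function(strand) if (strand == "+") cfg$utr5 else cfg$utr3

  L <- nrow(cfg$motif_pwm$matrix)

  for (ci in seq_len(cfg$n_chroms)) {
    chr <- names(genome)[ci]
    cls <- classes[chrom_of == ci]
    n_genes <- length(cls) + 1
    # intragenic OM host genes, spread across chromosomes
    n_hosts <- sum(rep_len(seq_len(cfg$n_chroms),
                           cfg$n_om_intragenic) == ci)
    host_at <- if (n_hosts > 0)
      sample(seq_len(n_genes), n_hosts) else integer(0)

    orf_len <- pmax(cfg$orf_min,
                    round(stats::rlnorm(n_genes, cfg$orf_meanlog,
                                        cfg$orf_sdlog)))
    orf_len[host_at] <- cfg$host_orf_len
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    cen_after <- floor(n_genes / 2)  # centromere after this gene

    pos <- 0
    mask_l[[length(mask_l) + 1]] <- data.frame(chrom = chr, start = 0,
                                               end = cfg$telomere_len)
    pos <- cfg$telomere_len + cfg$edge_igr_len
    plant <- list()  # deferred sequence overwrites
    g_start <- numeric(n_genes); g_end <- numeric(n_genes)
    igr_iv <- matrix(0, length(cls), 2)

    for (j in seq_len(n_genes)) {
      orf0 <- pos + ext_l(strand[j])
      g_start[j] <- orf0; g_end[j] <- orf0 + orf_len[j]
      pos <- g_end[j] + ext_r(strand[j])
      if (j %in% host_at) {
        site_no <- site_no + 1
        anch <- plant_site(plant, cfg, chr,
                           floor((g_start[j] + g_end[j]) / 2) - 300,
                           floor((g_start[j] + g_end[j]) / 2) + 300,
                           "OM_intragenic", site_no, L)
        plant <- anch$plant
        sites_l[[length(sites_l) + 1]] <- anch$site
        motifs_l[[length(motifs_l) + 1]] <- anch$motifs
      }
      if (j <= length(cls)) {
        if (j == cen_after) {
          mask_l[[length(mask_l) + 1]] <- data.frame(
            chrom = chr, start = pos + 150,
            end = pos + 150 + cfg$centromere_len)
          pos <- pos + 300 + cfg$centromere_len
        }
        len <- sample_igr_len(cls[j])
        igr_iv[j, ] <- c(pos, pos + len)
        if (cls[j] %in% c("OM", "O")) {
          site_no <- site_no + 1
          anch <- plant_site(plant, cfg, chr, pos, pos + len, cls[j],
                             site_no, L)
          plant <- anch$plant
          sites_l[[length(sites_l) + 1]] <- anch$site
          motifs_l[[length(motifs_l) + 1]] <- anch$motifs
        } else {
          plant <- plant_background_leak(plant, cfg, pos, pos + len, L)
        }
        pos <- pos + len
      }
    }
    pos <- pos + cfg$edge_igr_len
    mask_l[[length(mask_l) + 1]] <- data.frame(
      chrom = chr, start = pos, end = pos + cfg$telomere_len)
    chrom_len <- pos + cfg$telomere_len

    # background sequence, then planted overwrites
    seq <- random_bases(chrom_len, cfg$at_background)
    for (p in plant) {
      idx <- (p$start + 1):(p$start + length(p$bases))
      seq[idx] <- p$bases
    }
    genome[chr] <- paste(seq, collapse = "")

    rpkm <- stats::rlnorm(n_genes, cfg$rpkm_meanlog, cfg$rpkm_sdlog)
    rpkm[host_at] <- 0
    gene_ids <- sprintf("SPSIM%d.%03d", ci, seq_len(n_genes))
    plus <- strand == "+"
    genes_l[[length(genes_l) + 1]] <- data.frame(
      gene_id = gene_ids, chrom = chr, orf_start = g_start,
      orf_end = g_end, strand = strand,
      tss = ifelse(plus, g_start - cfg$utr5, g_end + cfg$utr5),
      tts = ifelse(plus, g_end + cfg$utr3, g_start - cfg$utr3),
      span_start = g_start - ifelse(plus, cfg$utr5, cfg$utr3),
      span_end = g_end + ifelse(plus, cfg$utr3, cfg$utr5),
      rpkm = rpkm, stringsAsFactors = FALSE)
  }

  sites <- do.call(rbind, sites_l)
  sites <- if (is.null(sites)) data.frame() else sites
  motifs <- do.call(rbind, motifs_l)
  list(genome = genome, genes = do.call(rbind, genes_l),
       mask = do.call(rbind, mask_l),
       truth = list(sites = sites,
                    motifs = if (is.null(motifs)) data.frame() else motifs))
}

# plan the planted features of one OM/O site inside [start, end)
plant_site <- function(plant, cfg, chr, start, end, class, site_no, L) {
  center <- floor((start + end) / 2)
  if (class == "O") {
    orc <- center; mcm <- NA_real_
  } else {
    off <- if (stats::runif(1) < 0.5)
      round(abs(stats::rnorm(1, 0, cfg$offset_near_sd)))
    else
      round(stats::runif(1, cfg$offset_far_min, cfg$offset_far_max))
    off <- off * sample(c(-1, 1), 1)
    orc <- center - round(off / 2)
    mcm <- orc + off
  }
  # AT segment first, motifs afterwards: a motif falling inside the segment
  # must survive the overwrite (as in real origins, where the poly(dA)
  # motif lies within the broader AT-rich region)
  at_iv <- c(NA_real_, NA_real_)
  if (class != "O") {
    seg <- round(stats::runif(1, cfg$at_seg_min, cfg$at_seg_max))
    a0 <- mcm - floor(seg / 2)
    a0 <- min(max(a0, start + 20), end - seg - 20)
    plant[[length(plant) + 1]] <- list(
      start = a0, bases = random_bases(seg, cfg$at_seg_frac))
    at_iv <- c(a0, a0 + seg)
  }
  n_mot <- sample(seq_along(cfg$motif_count_probs), 1,
                  prob = cfg$motif_count_probs)
  mot_start <- numeric(0)
  tries <- 0
  while (length(mot_start) < n_mot && tries < 100) {
    tries <- tries + 1
    cand <- orc + round(stats::runif(1, -100, 100 - L))
    if (cand < start || cand + L > end) next
    if (any(abs(cand - mot_start) < L)) next
    mot_start <- c(mot_start, cand)
  }
  for (ms in mot_start)
    plant[[length(plant) + 1]] <- list(
      start = ms,
      bases = strsplit(motif_instance(cfg$motif_pwm, cfg$motif_fidelity),
                       "")[[1]])
  list(plant = plant,
       site = data.frame(site_id = site_no, class = class, chrom = chr,
                         orc_anchor = orc, mcm_anchor = mcm,
                         at_start = at_iv[1], at_end = at_iv[2],
                         region_start = start, region_end = end,
                         n_motifs = length(mot_start),
                         stringsAsFactors = FALSE),
       motifs = if (length(mot_start) > 0)
         data.frame(site_id = site_no, chrom = chr, start = mot_start,
                    end = mot_start + L, stringsAsFactors = FALSE)
       else NULL)
}

plant_background_leak <- function(plant, cfg, start, end, L) {
  len <- end - start
  if (stats::runif(1) < cfg$bg_at_leak && len >= 100) {
    seg <- min(round(stats::runif(1, cfg$at_seg_min, cfg$at_seg_max)),
               len - 40)
    a0 <- start + floor((len - seg) / 2)
    plant[[length(plant) + 1]] <- list(
      start = a0, bases = random_bases(seg, cfg$at_seg_frac))
  }
  if (stats::runif(1) < cfg$bg_motif_leak && len >= L + 20) {
    ms <- start + floor((len - L) / 2)
    plant[[length(plant) + 1]] <- list(
      start = ms,
      bases = strsplit(motif_instance(cfg$motif_pwm, cfg$motif_fidelity),
                       "")[[1]])
  }
  plant
}

#' Simulate RNA-seq coverage from gene expression
#'
#' Per-base depth is Poisson with rate proportional to the host gene's
#' expression over its tss-tts span, plus a low uniform background rate, and
#' approximately zero over transcription-free spans.
#'
#' @param genome named character vector (for chromosome lengths).
#' @param genes gene models with `rpkm`.
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return Named list of per-base depth vectors.
#' @export
simulate_rnaseq <- function(genome, genes, config, seed) {
  lens <- chrom_lengths(genome)
  with_seed(seed, {
    cov <- lapply(names(lens), function(chr) {
      v <- stats::rpois(lens[chr], config$noise_rate)
      g <- genes[genes$chrom == chr, , drop = FALSE]
      for (i in seq_len(nrow(g))) {
        s <- max(g$span_start[i], 0) + 1
        e <- min(g$span_end[i], lens[chr])
        lam <- g$rpkm[i] * config$depth_per_rpkm
        if (lam > 0 && e >= s)
          v[s:e] <- v[s:e] + stats::rpois(e - s + 1, lam)
      }
      as.numeric(v)
    })
    names(cov) <- names(lens)
    cov
  })
}

#' Simulate Orc and Mcm fold-enrichment tracks
#'
#' Gaussian-shaped FE bumps at each planted Orc anchor (OM and O sites) and
#' each OM Mcm anchor, on top of multiplicative log-normal noise around
#' FE = 1; a few stray Mcm-only bumps are added at random arm positions.
#'
#' @param truth ground truth from [simulate_genome()].
#' @param lens named chromosome lengths.
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return List with `orc` and `mcm` [fe_track()]s.
#' @export
simulate_fe_tracks <- function(truth, lens, config, seed) {
  bw <- config$fe_bin
  with_seed(seed, {
    mk <- function(anchors, chroms, hml, hsd, hmin, sd) {
      h <- pmax(hmin, stats::rlnorm(length(anchors), hml, hsd))
      vals <- lapply(names(lens), function(chr) {
        n <- ceiling(as.numeric(lens[chr]) / bw)
        fe <- exp(stats::rnorm(n, 0, config$fe_noise_sdlog))
        bump <- rep(0, n)
        sel <- which(chroms == chr)
        centers <- (seq_len(n) - 0.5) * bw
        for (k in sel) {
          rng <- which(abs(centers - anchors[k]) < 3 * sd)
          # flat-topped bump (Gaussian of order 4): steep flanks keep the
          # supra-threshold run contiguous under multiplicative noise, the
          # shape of a read-pileup FE profile rather than a point spread
          bump[rng] <- bump[rng] +
            (h[k] - 1) * exp(-(centers[rng] - anchors[k])^4 / (2 * sd^4))
        }
        fe * (1 + bump)
      })
      names(vals) <- names(lens)
      fe_track(vals, bw)
    }
    s <- truth$sites
    if (is.null(s) || nrow(s) == 0)
      s <- data.frame(site_id = integer(0), class = character(0),
                      chrom = character(0), orc_anchor = numeric(0),
                      mcm_anchor = numeric(0))
    orc_anchors <- s$orc_anchor
    orc_chroms <- s$chrom
    om <- s[s$class %in% c("OM", "OM_intragenic"), , drop = FALSE]
    m_extra_chr <- sample(names(lens), config$n_m_only, replace = TRUE)
    m_extra_pos <- vapply(m_extra_chr, function(chr)
      floor(stats::runif(1, 0.1, 0.9) * as.numeric(lens[chr])), numeric(1))
    list(orc = mk(orc_anchors, orc_chroms, config$orc_height_meanlog,
                  config$orc_height_sdlog, config$orc_height_min,
                  config$orc_sd),
         mcm = mk(c(om$mcm_anchor, m_extra_pos),
                  c(om$chrom, m_extra_chr), config$mcm_height_meanlog,
                  config$mcm_height_sdlog, config$mcm_height_min,
                  config$mcm_sd))
  })
}

#' Run the full simulation and optionally write study files
#'
#' Convenience wrapper: genome + annotation + coverage + FE tracks from one
#' master seed (sub-stage seeds are derived deterministically). With `dir`
#' set, writes `genome.fa`, `genes.gff3`, `mask.bed`, `expression.tsv`,
#' `rnaseq.bedGraph`, `orc_fe.bedGraph`, `mcm_fe.bedGraph` and
#' `truth.json`.
#'
#' @param config a [sim_config()].
#' @param seed master seed.
#' @param dir optional output directory.
#' @return List: `genome`, `genes`, `mask`, `truth`, `coverage`, `orc_fe`,
#'   `mcm_fe`, `files` (when written).
#' @export
simulate_origin_study <- function(config = sim_config(), seed, dir = NULL) {
  sim <- simulate_genome(config, derive_seed(seed, "genome"))
  sim$coverage <- simulate_rnaseq(sim$genome, sim$genes, config,
                                  derive_seed(seed, "rnaseq"))
  fe <- simulate_fe_tracks(sim$truth, chrom_lengths(sim$genome), config,
                           derive_seed(seed, "fe"))
  sim$orc_fe <- fe$orc
  sim$mcm_fe <- fe$mcm
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    f <- list(
      genome = file.path(dir, "genome.fa"),
      gff = file.path(dir, "genes.gff3"),
      mask = file.path(dir, "mask.bed"),
      expression = file.path(dir, "expression.tsv"),
      rnaseq = file.path(dir, "rnaseq.bedGraph"),
      orc_fe = file.path(dir, "orc_fe.bedGraph"),
      mcm_fe = file.path(dir, "mcm_fe.bedGraph"),
      truth = file.path(dir, "truth.json"))
    write_genome(sim$genome, f$genome)
    write_genes_gff3(sim$genes, f$gff)
    utils::write.table(
      data.frame(chrom = sim$mask$chrom, start = sim$mask$start,
                 end = sim$mask$end),
      f$mask, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
    utils::write.table(sim$genes[, c("gene_id", "rpkm")], f$expression,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_coverage_bedgraph(sim$coverage, f$rnaseq)
    write_fe_bedgraph(sim$orc_fe, f$orc_fe)
    write_fe_bedgraph(sim$mcm_fe, f$mcm_fe)
    jsonlite::write_json(sim$truth, f$truth, dataframe = "columns",
                         digits = NA, na = "null")
    sim$files <- f
  }
  sim
}
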