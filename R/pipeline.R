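#' Pipeline configuration
#'
#' A single flat configuration object consumed by [run_stage()]. Defaults
#' follow the study's analysis constants: Orc4/Mcm2 FE thresholds 6 and 2,
#' 50 bp minimum peak width, 5% motif FDR, 101 bp AT window at 0.75, 200 bp
#' melting window, 1 kb feature windows, RBF-SVM sigma 0.01 / C 10, 10 x
#' 4-fold CV. `...` overrides any default; `sim` is a list of
#' [sim_config()] overrides used by the `simulate` stage.
#'
#' @param dir working directory for stage inputs/outputs.
#' @param seed master seed; each stage derives its own seed from it.
#' @param ... overrides of the default keys.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(dir = ".", seed = 1, ...) {
  cfg <- list(
    dir = dir, seed = seed,
    fe_orc = 6, fe_mcm = 2, min_peak = 50, fe_bin = 10,
    fdr = 0.05, at_threshold = 0.75, at_w = 101, melt_window = 200,
    window = 1000, utr5 = 293, utr3 = 430,
    sigma = 0.01, C = 10, cv_k = 4, cv_rounds = 10,
    loess_span = 0.005, cn_bin = 100,
    n_controls_per_pos = 5, control_min_dist = 1000,
    mc_reps = 200, motif_radius = 250,
    feature_set = c("n_mt", "l_at", "l_ntx"),
    motifs = NULL,           # MEME file; NULL uses the built-in test PWM
    sim = list())
  override <- list(...)
  cfg[names(override)] <- override
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys in the file override [pipeline_config()] defaults; unknown keys are
#' an error naming the offending key.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  base <- pipeline_config()
  unknown <- setdiff(names(vals), c(names(base), "dir", "seed"))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

stage_path <- function(config, name) file.path(config$dir, name)

require_input <- function(config, name, key) {
  p <- stage_path(config, name)
  if (!file.exists(p))
    stop("missing input '", p, "' (config key: dir); run the '", key,
         "' stage first or place the file there")
  p
}

write_manifest <- function(config, stage, params, inputs, outputs) {
  man <- list(stage = stage, seed = derive_seed(config$seed, stage),
              params = params,
              inputs = as.list(tools::md5sum(inputs)),
              outputs = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(man, stage_path(config,
                                       paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(man)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

load_study <- function(config) {
  genome <- read_genome(require_input(config, "genome.fa", "simulate"))
  lens <- chrom_lengths(genome)
  mask <- read_arm_mask(require_input(config, "mask.bed", "simulate"))
  genes <- read_genes(require_input(config, "genes.gff3", "simulate"),
                      utr5_default = config$utr5,
                      utr3_default = config$utr3, chrom_lengths = lens)
  expr <- read_tsv(require_input(config, "expression.tsv", "simulate"))
  genes <- attach_expression(genes, expr)
  list(genome = genome, lens = lens, mask = mask, genes = genes,
       arms = genome_arms(lens, mask))
}

load_sites <- function(config) {
  tab <- read_tsv(require_input(config, "sites.tsv", "classify_sites"))
  om <- tab[tab$class == "OM", , drop = FALSE]
  o <- tab[tab$class == "O", , drop = FALSE]
  m <- tab[tab$class == "M_only", , drop = FALSE]
  structure(list(
    om = data.frame(chrom = om$chrom, orc_start = om$orc_start,
                    orc_end = om$orc_end, orc_summit = om$orc_summit,
                    orc_max_fe = om$orc_max_fe, mcm_start = om$mcm_start,
                    mcm_end = om$mcm_end, mcm_summit = om$mcm_summit,
                    mcm_max_fe = om$mcm_max_fe, stringsAsFactors = FALSE),
    o = data.frame(chrom = o$chrom, start = o$orc_start, end = o$orc_end,
                   summit = o$orc_summit, max_fe = o$orc_max_fe,
                   stringsAsFactors = FALSE),
    m_only = data.frame(chrom = m$chrom, start = m$mcm_start,
                        end = m$mcm_end, summit = m$mcm_summit,
                        max_fe = m$mcm_max_fe, stringsAsFactors = FALSE)),
    class = "site_set")
}

pipeline_pwms <- function(config) {
  if (is.null(config$motifs)) list(default_polya_pwm())
  else read_meme_motifs(config$motifs)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic study files), `call_peaks`,
#' `classify_sites`, `scan_motifs`, `features`, `train_eval`,
#' `intragenic_eval`, `montecarlo`, `copy_number`, `report`. Each stage
#' reads its inputs from `config$dir`, writes its outputs there, and drops a
#' `manifest_<stage>.json` with parameters, the derived seed and md5
#' checksums of inputs and outputs; reruns with the same config and seed
#' are byte-identical.
#'
#' @param name stage name.
#' @param config a [pipeline_config()].
#' @return Invisibly, the stage's main result object.
#' @export
run_stage <- function(name, config) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- list(simulate = stage_simulate, call_peaks = stage_call_peaks,
                 classify_sites = stage_classify_sites,
                 scan_motifs = stage_scan_motifs,
                 features = stage_features, train_eval = stage_train_eval,
                 intragenic_eval = stage_intragenic_eval,
                 montecarlo = stage_montecarlo,
                 copy_number = stage_copy_number, report = stage_report)
  if (!name %in% names(stages))
    stop("unknown stage '", name, "'; stages: ",
         paste(names(stages), collapse = ", "))
  dir.create(config$dir, recursive = TRUE, showWarnings = FALSE)
  stages[[name]](config)
}

stage_simulate <- function(config) {
  cfg <- do.call(sim_config, config$sim)
  sim <- simulate_origin_study(cfg, derive_seed(config$seed, "simulate"),
                               dir = config$dir)
  write_manifest(config, "simulate", config$sim, character(0),
                 unlist(sim$files))
  invisible(sim)
}

stage_call_peaks <- function(config) {
  genome <- read_genome(require_input(config, "genome.fa", "simulate"))
  lens <- chrom_lengths(genome)
  mask <- read_arm_mask(require_input(config, "mask.bed", "simulate"))
  ins <- c(stage_path(config, "orc_fe.bedGraph"),
           stage_path(config, "mcm_fe.bedGraph"))
  orc <- read_fe_bedgraph(require_input(config, "orc_fe.bedGraph",
                                        "simulate"), lens, config$fe_bin)
  mcm <- read_fe_bedgraph(require_input(config, "mcm_fe.bedGraph",
                                        "simulate"), lens, config$fe_bin)
  orc_p <- apply_mask(call_peaks(orc, config$fe_orc, config$min_peak), mask)
  mcm_p <- apply_mask(call_peaks(mcm, config$fe_mcm, config$min_peak), mask)
  outs <- c(write_tsv(orc_p, stage_path(config, "orc_peaks.tsv")),
            write_tsv(mcm_p, stage_path(config, "mcm_peaks.tsv")),
            write_peaks_bed(orc_p, stage_path(config, "orc_peaks.bed")),
            write_peaks_bed(mcm_p, stage_path(config, "mcm_peaks.bed")))
  write_manifest(config, "call_peaks",
                 config[c("fe_orc", "fe_mcm", "min_peak")], ins, outs)
  invisible(list(orc = orc_p, mcm = mcm_p))
}

#' Write peaks as BED6 with the summit in the name field
#'
#' @param peaks peak `data.frame`.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  lines <- sprintf("%s\t%d\t%d\tsummit=%d\t%.4g\t.", peaks$chrom,
                   as.integer(peaks$start), as.integer(peaks$end),
                   as.integer(peaks$summit), peaks$max_fe)
  writeLines(lines, path)
  invisible(path)
}

stage_classify_sites <- function(config) {
  orc <- read_tsv(require_input(config, "orc_peaks.tsv", "call_peaks"))
  mcm <- read_tsv(require_input(config, "mcm_peaks.tsv", "call_peaks"))
  ss <- classify_sites(orc, mcm)
  na0 <- function(n) rep(NA_real_, n)
  tab <- rbind(
    data.frame(site_id = sprintf("OM_%03d", seq_len(nrow(ss$om))),
               class = "OM", ss$om, stringsAsFactors = FALSE),
    if (nrow(ss$o) > 0)
      data.frame(site_id = sprintf("O_%03d", seq_len(nrow(ss$o))),
                 class = "O", chrom = ss$o$chrom, orc_start = ss$o$start,
                 orc_end = ss$o$end, orc_summit = ss$o$summit,
                 orc_max_fe = ss$o$max_fe, mcm_start = na0(nrow(ss$o)),
                 mcm_end = na0(nrow(ss$o)), mcm_summit = na0(nrow(ss$o)),
                 mcm_max_fe = na0(nrow(ss$o)), stringsAsFactors = FALSE),
    if (nrow(ss$m_only) > 0)
      data.frame(site_id = sprintf("M_%03d", seq_len(nrow(ss$m_only))),
                 class = "M_only", chrom = ss$m_only$chrom,
                 orc_start = na0(nrow(ss$m_only)),
                 orc_end = na0(nrow(ss$m_only)),
                 orc_summit = na0(nrow(ss$m_only)),
                 orc_max_fe = na0(nrow(ss$m_only)),
                 mcm_start = ss$m_only$start, mcm_end = ss$m_only$end,
                 mcm_summit = ss$m_only$summit,
                 mcm_max_fe = ss$m_only$max_fe, stringsAsFactors = FALSE))
  out <- write_tsv(tab, stage_path(config, "sites.tsv"))
  write_manifest(config, "classify_sites", list(),
                 c(stage_path(config, "orc_peaks.tsv"),
                   stage_path(config, "mcm_peaks.tsv")), out)
  invisible(ss)
}

stage_scan_motifs <- function(config) {
  genome <- read_genome(require_input(config, "genome.fa", "simulate"))
  hits <- lapply(pipeline_pwms(config), function(p)
    scan_pwm(genome, p, fdr = config$fdr))
  union <- do.call(union_motif_sites, hits)
  out <- write_tsv(union, stage_path(config, "motif_union.tsv"))
  write_manifest(config, "scan_motifs", config["fdr"],
                 stage_path(config, "genome.fa"), out)
  invisible(union)
}

stage_features <- function(config) {
  st <- load_study(config)
  union <- read_tsv(require_input(config, "motif_union.tsv",
                                  "scan_motifs"))
  cov <- read_coverage_bedgraph(require_input(config, "rnaseq.bedGraph",
                                              "simulate"), st$lens)
  ss <- load_sites(config)
  igrs <- derive_igrs(st$genes, st$lens, st$mask)
  ds <- build_igr_dataset(igrs, ss, st$genome, union, cov, st$genes,
                          width = config$window)
  tab <- cbind(ds$meta, as.data.frame(ds$X))
  outs <- write_tsv(tab, stage_path(config, "features.tsv"))
  if (!is.null(ds$heldout_X))
    outs <- c(outs, write_tsv(
      cbind(ds$heldout_meta, as.data.frame(ds$heldout_X)),
      stage_path(config, "features_heldout_o.tsv")))
  write_manifest(config, "features",
                 config[c("window", "at_threshold", "at_w")],
                 stage_path(config, c("genome.fa", "genes.gff3",
                                      "mask.bed", "motif_union.tsv",
                                      "rnaseq.bedGraph", "sites.tsv")),
                 outs)
  invisible(ds)
}

stage_train_eval <- function(config) {
  tab <- read_tsv(require_input(config, "features.tsv", "features"))
  X <- as.matrix(tab[, feature_names()])
  y <- factor(tab$class, levels = c("neg", "pos"))
  cv <- origin_cv(X, y, features = config$feature_set, k = config$cv_k,
                  rounds = config$cv_rounds, sigma = config$sigma,
                  C = config$C,
                  seed = derive_seed(config$seed, "train_eval"))
  rep_path <- write_tsv(cv$per_fold, stage_path(config, "cv_report.tsv"))
  summ <- list(features = cv$features, roc_auc = cv$roc_auc,
               pr_auc = cv$pr_auc, roc_auc_ci = cv$roc_auc_ci,
               pr_auc_ci = cv$pr_auc_ci,
               fscore = as.list(feature_fscore(X, y)))
  json_path <- stage_path(config, "cv_summary.json")
  jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = 10)
  outs <- c(rep_path, json_path)
  held_file <- stage_path(config, "features_heldout_o.tsv")
  if (file.exists(held_file)) {
    held <- read_tsv(held_file)
    held$prob <- score_heldout(cv, as.matrix(held[, cv$features]))
    outs <- c(outs, write_tsv(held[, c("igr_id", "prob")],
                              stage_path(config, "heldout_o_scores.tsv")))
  }
  write_manifest(config, "train_eval",
                 config[c("sigma", "C", "cv_k", "cv_rounds",
                          "feature_set")],
                 stage_path(config, "features.tsv"), outs)
  invisible(cv)
}

stage_intragenic_eval <- function(config) {
  st <- load_study(config)
  union <- read_tsv(require_input(config, "motif_union.tsv",
                                  "scan_motifs"))
  cov <- read_coverage_bedgraph(require_input(config, "rnaseq.bedGraph",
                                              "simulate"), st$lens)
  ss <- load_sites(config)
  igrs <- derive_igrs(st$genes, st$lens, st$mask)
  ids <- build_intragenic_dataset(
    ss, igrs, st$genome, union, cov, st$arms,
    n_controls_per_pos = config$n_controls_per_pos,
    min_dist = config$control_min_dist, width = config$window,
    seed = derive_seed(config$seed, "intragenic_controls"))
  tab <- read_tsv(require_input(config, "features.tsv", "features"))
  trio <- c("n_mt", "l_at", "l_ntx")
  cv <- origin_cv(as.matrix(tab[, feature_names()]),
                  factor(tab$class, levels = c("neg", "pos")),
                  features = trio, k = config$cv_k,
                  rounds = config$cv_rounds, sigma = config$sigma,
                  C = config$C,
                  seed = derive_seed(config$seed, "train_eval"))
  prob <- score_heldout(cv, ids$X)
  res <- list(n_pos = sum(ids$y == "pos"), n_controls = sum(ids$y == "neg"),
              roc_auc = roc_auc(prob, ids$y), pr_auc = pr_auc(prob, ids$y))
  out <- stage_path(config, "intragenic_eval.json")
  jsonlite::write_json(res, out, auto_unbox = TRUE, digits = 10)
  write_manifest(config, "intragenic_eval",
                 config[c("n_controls_per_pos", "control_min_dist")],
                 stage_path(config, c("features.tsv", "sites.tsv")), out)
  invisible(res)
}

stage_montecarlo <- function(config) {
  st <- load_study(config)
  union <- read_tsv(require_input(config, "motif_union.tsv",
                                  "scan_motifs"))
  ss <- load_sites(config)
  igrs <- derive_igrs(st$genes, st$lens, st$mask)
  om_igr <- point_in_igr(igrs, ss$om$chrom, ss$om$orc_summit)
  om_lengths <- igrs$length[stats::na.omit(unique(om_igr))]
  obs <- mean(vapply(seq_len(nrow(ss$om)), function(i)
    count_motifs_near(union, ss$om$chrom[i], ss$om$orc_summit[i],
                      config$motif_radius) >= 1, logical(1)))
  mc <- random_site_motif_expectation(
    st$arms, union, n_sites = nrow(ss$om), radius = config$motif_radius,
    reps = config$mc_reps, seed = derive_seed(config$seed, "mc_motif"))
  rnd <- random_igr_orientation(
    igrs, n_sample = length(om_lengths), reps = config$mc_reps,
    seed = derive_seed(config$seed, "mc_orient"))
  lc <- length_matched_igr_sample(
    igrs, om_lengths, reps = config$mc_reps,
    seed = derive_seed(config$seed, "mc_length"))
  res <- list(observed_fraction_with_motif = obs,
              random_motif_ci = mc[c("estimate", "lower", "upper")],
              random_orientation = rnd,
              length_controlled_orientation =
                lc[c("divergent", "tandem", "convergent")])
  out <- stage_path(config, "montecarlo.json")
  jsonlite::write_json(res, out, auto_unbox = TRUE, digits = 10)
  write_manifest(config, "montecarlo",
                 config[c("mc_reps", "motif_radius")],
                 stage_path(config, c("motif_union.tsv", "sites.tsv")),
                 out)
  invisible(res)
}

stage_copy_number <- function(config) {
  genome <- read_genome(require_input(config, "genome.fa", "simulate"))
  lens <- chrom_lengths(genome)
  nb <- ceiling(as.numeric(lens) / config$cn_bin)
  read_bins <- function(file) {
    gr <- rtracklayer::import(stage_path(config, file),
                              format = "bedGraph")
    df <- gr2gi(gr); df$score <- gr$score
    lapply(seq_along(lens), function(i) {
      v <- numeric(nb[i])
      d <- df[df$chrom == names(lens)[i], , drop = FALSE]
      v[d$start / config$cn_bin + 1] <- d$score
      v
    })
  }
  require_input(config, "cn_sample.bedGraph", "copy_number")
  require_input(config, "cn_reference.bedGraph", "copy_number")
  smp <- read_bins("cn_sample.bedGraph")
  ref <- read_bins("cn_reference.bedGraph")
  ratio <- copy_number_ratio(unlist(smp), unlist(ref))
  sm <- loess_smooth(ratio, span = config$loess_span)
  scaled <- scale_quartile(sm)
  splits <- rep(names(lens), nb)
  prof <- split(scaled, factor(splits, levels = names(lens)))
  con <- file(stage_path(config, "copy_number.bedGraph"), "w")
  for (chr in names(lens)) {
    v <- prof[[chr]]
    starts <- (seq_along(v) - 1) * config$cn_bin
    ok <- !is.na(v)
    writeLines(sprintf("%s\t%d\t%d\t%.6g", chr, starts[ok],
                       starts[ok] + config$cn_bin, v[ok]), con)
  }
  close(con)
  write_manifest(config, "copy_number",
                 config[c("cn_bin", "loess_span")],
                 stage_path(config, c("cn_sample.bedGraph",
                                      "cn_reference.bedGraph")),
                 stage_path(config, "copy_number.bedGraph"))
  invisible(prof)
}

stage_report <- function(config) {
  st <- load_study(config)
  union <- read_tsv(require_input(config, "motif_union.tsv",
                                  "scan_motifs"))
  ss <- load_sites(config)
  igrs <- derive_igrs(st$genes, st$lens, st$mask)
  tab <- read_tsv(require_input(config, "features.tsv", "features"))
  venn <- venn_counts(ss)
  placement <- placement_table(ss, igrs)
  fat <- flank_asymmetry_table(ss, st$genome)
  feats <- data.frame(l_at = tab$l_at, n_mt = tab$n_mt, l_ntx = tab$l_ntx,
                      class = ifelse(tab$class == "pos", "OM", "other"))
  held_file <- stage_path(config, "features_heldout_o.tsv")
  if (file.exists(held_file)) {
    h <- read_tsv(held_file)
    feats <- rbind(feats, data.frame(l_at = h$l_at, n_mt = h$n_mt,
                                     l_ntx = h$l_ntx, class = "O"))
  }
  hist_nmt <- stratified_feature_histogram(feats, by = "n_mt")
  hist_ntx <- stratified_feature_histogram(feats, by = "l_ntx",
                                           by_breaks = c(200, 600))
  outs <- c(
    write_tsv(placement, stage_path(config, "placement.tsv")),
    write_tsv(fat, stage_path(config, "flank_asymmetry.tsv")),
    write_tsv(hist_nmt, stage_path(config, "hist_lat_nmt.tsv")),
    write_tsv(hist_ntx, stage_path(config, "hist_lat_lntx.tsv")))
  summ <- list(venn = as.list(venn),
               median_summit_offset =
                 stats::median(abs(summit_offsets(ss))),
               prop_om_intergenic =
                 placement$prop_intergenic[placement$class == "OM"])
  json <- stage_path(config, "report.json")
  jsonlite::write_json(summ, json, auto_unbox = TRUE, digits = 10)
  write_manifest(config, "report", list(),
                 stage_path(config, c("sites.tsv", "features.tsv",
                                      "motif_union.tsv")),
                 c(outs, json))
  invisible(summ)
}
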