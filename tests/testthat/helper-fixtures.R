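# Shared fixtures, built once per test run.

# Small synthetic study: ~0.5 Mb, 30/15/200 planted IGRs, 5 intragenic OM.
small_sim_config <- function() {
  sim_config(n_om = 30, n_o = 15, n_bg = 200, n_om_intragenic = 5,
             n_chroms = 2)
}

.fixture_env <- new.env()

small_study <- function() {
  if (is.null(.fixture_env$study)) {
    sim <- simulate_origin_study(small_sim_config(), seed = 42)
    lens <- chrom_lengths(sim$genome)
    orc_p <- apply_mask(call_peaks(sim$orc_fe, 6), sim$mask)
    mcm_p <- apply_mask(call_peaks(sim$mcm_fe, 2), sim$mask)
    ss <- classify_sites(orc_p, mcm_p)
    hits <- scan_pwm(sim$genome, default_polya_pwm(), fdr = 0.05)
    u <- union_motif_sites(hits)
    igrs <- derive_igrs(sim$genes, lens, sim$mask)
    .fixture_env$study <- list(sim = sim, lens = lens, orc_p = orc_p,
                               mcm_p = mcm_p, ss = ss, hits = hits,
                               union = u, igrs = igrs)
  }
  .fixture_env$study
}

# random DNA string at a given AT fraction
random_seq <- function(n, at = 0.5) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

# naive single-purpose oracles, kept deliberately independent of the
# package's vectorized implementations
naive_at_count <- function(seq) {
  sum(strsplit(seq, "")[[1]] %in% c("A", "T"))
}

naive_l_at <- function(seq, start, end, w = 101, threshold = 0.75) {
  n <- nchar(seq)
  bases <- strsplit(seq, "")[[1]]
  cnt <- 0
  for (i in (start + 1):end) {
    lo <- max(i - floor(w / 2), 1)
    hi <- min(i + floor(w / 2), n)
    frac <- sum(bases[lo:hi] %in% c("A", "T")) / (hi - lo + 1)
    if (frac >= threshold) cnt <- cnt + 1
  }
  cnt
}

naive_l_ntx <- function(cov, start, end, max_count = 1) {
  best <- 0; cur <- 0
  for (i in (start + 1):end) {
    if (cov[i] <= max_count) { cur <- cur + 1; best <- max(best, cur) }
    else cur <- 0
  }
  best
}

naive_dg_melt <- function(seq, center, window = 200, params = nn_dg37()) {
  # center is 1-based; returns NA outside valid range
  bases <- strsplit(seq, "")[[1]]
  lo <- center - floor(window / 2)
  hi <- center + ceiling(window / 2) - 1
  if (lo < 1 || hi > length(bases)) return(NA_real_)
  tot <- 0
  for (i in lo:(hi - 1)) {
    step <- paste0(bases[i], bases[i + 1])
    v <- params[step]
    if (is.na(v)) return(NA_real_)
    tot <- tot + v
  }
  -tot
}

naive_roc_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Small pipeline run shared across stage and determinism tests.
pipeline_fixture <- function() {
  if (is.null(.fixture_env$pipe)) {
    dir <- file.path(tempdir(), "oriscan_pipe")
    unlink(dir, recursive = TRUE)
    cfg <- pipeline_config(
      dir = dir, seed = 5, cv_rounds = 2, mc_reps = 20,
      sim = list(n_om = 12, n_o = 6, n_bg = 80, n_om_intragenic = 3,
                 n_chroms = 1))
    run_stage("simulate", cfg)
    run_stage("call_peaks", cfg)
    run_stage("classify_sites", cfg)
    run_stage("scan_motifs", cfg)
    run_stage("features", cfg)
    .fixture_env$pipe <- cfg
  }
  .fixture_env$pipe
}
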