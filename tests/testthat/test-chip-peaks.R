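fe1 <- function(v) fe_track(list(chr1 = v), bin_width = 10L)

test_that("fold enrichment is 1 for identical tracks and finite on degenerate input", {
  chip <- list(chr1 = c(5, 5, 5, 5))
  expect_equal(compute_fe(chip, chip)$values$chr1, rep(1, 4))

  # one bin 10x input, totals equal
  fe <- compute_fe(list(chr1 = c(10, 0, 5, 5)), list(chr1 = c(1, 9, 5, 5)))
  expect_equal(fe$values$chr1[1], 11 / 2)  # pseudocount-adjusted

  # all-zero input stays finite
  fe0 <- compute_fe(list(chr1 = c(3, 3)), list(chr1 = c(0, 0)))
  expect_true(all(is.finite(fe0$values$chr1)))

  expect_error(compute_fe(list(chr1 = 1:3), list(chr1 = 1:4)),
               "mismatched")
  expect_error(compute_fe(list(a = 1:3), list(b = 1:3)), "different")
})

test_that("peak calling applies the width filter, no-bridging and leftmost-summit rules", {
  # 30 bp candidate discarded (< 50 bp)
  expect_equal(nrow(call_peaks(fe1(c(1, 7, 8, 7, 1)), 6)), 0)

  # 6 consecutive bins >= 6, max in bin 4 -> one 60 bp peak
  p <- call_peaks(fe1(c(0, 6, 7, 9, 7, 6, 6, 0)), 6)
  expect_equal(nrow(p), 1)
  expect_equal(p$start, 10); expect_equal(p$end, 70)
  expect_equal(p$summit, 35)                  # centre of the max bin
  expect_equal(p$max_fe, 9)

  # one sub-threshold bin splits runs: two peaks, no bridging
  v <- c(rep(7, 6), 1, rep(7, 6))
  expect_equal(nrow(call_peaks(fe1(v), 6)), 2)

  # leftmost maximal bin wins ties
  p2 <- call_peaks(fe1(c(7, 9, 7, 9, 7)), 6)
  expect_equal(p2$summit, 15)
})

test_that("peak intervals are disjoint, sorted, and coverage is monotone in the threshold", {
  set.seed(11)
  v <- pmax(0, rnorm(500, 2, 3))
  fe <- fe1(v)
  p <- call_peaks(fe, 6, min_width = 50)
  if (nrow(p) > 1) expect_true(all(diff(p$start) > 0) &&
                                 all(p$start[-1] >= p$end[-nrow(p)]))
  cover <- function(th) sum(call_peaks(fe, th, min_width = 10)$end -
                              call_peaks(fe, th, min_width = 10)$start)
  expect_true(cover(4) >= cover(6))
  expect_true(cover(2) >= cover(4))

  # idempotence: re-calling on a track with sub-threshold bins zeroed
  v2 <- ifelse(v >= 6, v, 0)
  expect_equal(call_peaks(fe1(v2), 6), p)
})

test_that("mask removal drops >= 1 bp overlaps only", {
  peaks <- data.frame(chrom = "chr1", start = c(100, 300), end = c(200, 400),
                      summit = c(150, 350), max_fe = c(8, 9))
  mask <- gi("chr1", 150, 260)
  expect_equal(apply_mask(peaks, mask)$start, 300)
  # abutting (no shared bp) is kept
  mask2 <- gi("chr1", 200, 300)
  expect_equal(nrow(apply_mask(peaks, mask2)), 2)

  # random fixture vs brute-force overlap oracle
  set.seed(12)
  for (i in 1:5) {
    s <- sort(sample(0:1000, 20)) * 10
    pk <- data.frame(chrom = "chr1", start = s, end = s + 80,
                     summit = s + 40, max_fe = 7)
    ms <- sort(sample(0:1000, 5)) * 10
    mk <- gi("chr1", ms, ms + 150)
    keep <- sapply(seq_len(nrow(pk)), function(j)
      !any(pk$start[j] < mk$end & pk$end[j] > mk$start))
    expect_equal(apply_mask(pk, mk)$start, pk$start[keep])
  }
})

test_that("site classification honours the 1 bp overlap boundary", {
  orc <- data.frame(chrom = "chr1", start = 100, end = 200, summit = 150,
                    max_fe = 8)
  mcm1 <- data.frame(chrom = "chr1", start = 199, end = 300, summit = 250,
                     max_fe = 4)
  ss <- classify_sites(orc, mcm1)
  expect_equal(venn_counts(ss), c(n_o = 0, n_om = 1, n_m_only = 0))

  # half-open: [100,200) and [200,300) share nothing
  mcm2 <- data.frame(chrom = "chr1", start = 200, end = 300, summit = 250,
                     max_fe = 4)
  ss2 <- classify_sites(orc, mcm2)
  expect_equal(venn_counts(ss2), c(n_o = 1, n_om = 0, n_m_only = 1))
})

test_that("site partition matches a brute-force pairwise overlap check", {
  set.seed(13)
  for (i in 1:5) {
    so <- sort(sample(seq(0, 5000, 10), 5))
    sm <- sort(sample(seq(0, 5000, 10), 3))
    orc <- data.frame(chrom = "chr1", start = so, end = so + 300,
                      summit = so + 150, max_fe = 8)
    mcm <- data.frame(chrom = "chr1", start = sm, end = sm + 300,
                      summit = sm + 150, max_fe = 4)
    ss <- classify_sites(orc, mcm)
    ov <- outer(seq_len(5), seq_len(3), Vectorize(function(i, j)
      min(orc$end[i], mcm$end[j]) - max(orc$start[i], mcm$start[j]) > 0))
    expect_equal(nrow(ss$om), sum(rowSums(ov) > 0))
    expect_equal(nrow(ss$o), sum(rowSums(ov) == 0))
    expect_equal(nrow(ss$m_only), sum(colSums(ov) == 0))
    # partition: every orc peak is OM or O
    expect_equal(nrow(ss$om) + nrow(ss$o), nrow(orc))
  }
})

test_that("summit offsets are signed Mcm minus Orc distances", {
  orc <- data.frame(chrom = "chr1", start = c(0, 1000), end = c(400, 1400),
                    summit = c(200, 1200), max_fe = 8)
  mcm <- data.frame(chrom = "chr1", start = c(100, 1000),
                    end = c(500, 1400), summit = c(400, 1200), max_fe = 4)
  ss <- classify_sites(orc, mcm)
  expect_equal(sort(summit_offsets(ss)), c(0, 200))
  # empty OM set -> empty offsets
  ss0 <- classify_sites(orc[0, ], mcm)
  expect_length(summit_offsets(ss0), 0)
})

test_that("FE bedGraph round-trips through rtracklayer import", {
  set.seed(14)
  fe <- fe_track(list(chrI = round(runif(40, 0, 9), 3),
                      chrII = round(runif(25, 0, 9), 3)), 10L)
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_fe_bedgraph(fe, path)
  back <- read_fe_bedgraph(path, c(chrI = 400, chrII = 250), 10L)
  expect_equal(back$values, fe$values, tolerance = 1e-6)
})
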