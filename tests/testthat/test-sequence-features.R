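test_that("AT fraction and profile match direct counting", {
  expect_equal(at_fraction("ATGC"), 0.5)
  expect_equal(at_fraction("AAAA"), 1)
  expect_equal(at_fraction("ANNT"), 0.5)   # N is non-AT

  set.seed(21)
  s <- random_seq(60)
  expect_equal(at_fraction(s), naive_at_count(s) / 60)

  # constant sequence -> constant profile
  expect_equal(at_profile("AAAAAAAA", 4), rep(1, 8))

  # AT->GC step ramps monotonically over one window width
  step <- paste0(strrep("A", 100), strrep("G", 100))
  prof <- at_profile(step, 50)
  mid <- prof[75:125]
  expect_true(all(diff(mid) <= 0))
  expect_equal(prof[10], 1)
  expect_equal(prof[190], 0)

  # profile of the reverse complement is the reversed profile (odd window:
  # even windows are left-biased and reverse with a one-position shift)
  s2 <- random_seq(200)
  expect_equal(at_profile(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s2))), 101),
    rev(at_profile(s2, 101)))
})

test_that("L_AT saturates on poly(A), vanishes on GC-balanced DNA, and matches naive recomputation", {
  polyA <- strrep("A", 1400)
  expect_equal(l_at(polyA, 200, 1200), 1000)

  set.seed(22)
  gc50 <- random_seq(1400, at = 0.5)
  # P(Binom(101, 0.5) >= 76) ~ 3e-7 per position
  expect_equal(l_at(gc50, 200, 1200), 0)

  # planted 200 bp AT-rich segment in balanced context
  planted <- paste0(random_seq(500, 0.5), random_seq(200, 0.9),
                    random_seq(500, 0.5))
  v <- l_at(planted, 100, 1100)
  expect_gte(v, 150); expect_lte(v, 300)
  expect_equal(v, naive_l_at(planted, 100, 1100))

  # threshold relaxation is monotone
  expect_gte(l_at(planted, 100, 1100, threshold = 0.7), v)
})

test_that("flank AT contents behave symmetrically and flag out-of-range summits", {
  set.seed(23)
  half <- random_seq(500)
  sym <- paste0(half, paste(rev(strsplit(half, "")[[1]]), collapse = ""))
  f <- flank_at(sym, 500)
  expect_equal(unname(f["left_at"]), unname(f["right_at"]))

  asym <- paste0(random_seq(500, 0.3), random_seq(500, 0.9))
  f2 <- flank_at(asym, 500)
  expect_gt(f2["right_at"], f2["left_at"])

  expect_error(flank_at(random_seq(2000), 300), "outside")
})

test_that("melting-energy profile equals the hand-summed nearest-neighbour model", {
  # 4-mer window of AA steps: 3 steps x 1.00 kcal/mol
  prof <- delta_g_melt_profile("AAAAAA", window = 4)
  expect_equal(prof[3], 3)

  # reverse-complement symmetry of the parameter table and profile
  p <- nn_dg37()
  for (d in names(p)) {
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(d, "")[[1]]),
                                       collapse = ""))
    expect_equal(unname(p[d]), unname(p[rc]))
  }
  set.seed(24)
  s <- random_seq(400)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  a <- delta_g_melt_profile(s, 200)
  b <- delta_g_melt_profile(rc, 200)
  # even windows are left-biased, so reversal maps centre i to n + 2 - i
  i <- 102:300
  expect_equal(a[i], b[402 - i])

  # AT homoduplex melts more easily than GC homoduplex
  expect_lt(delta_g_melt_profile(strrep("AT", 150), 200)[150],
            delta_g_melt_profile(strrep("GC", 150), 200)[150])

  # windows containing N are undefined
  pn <- delta_g_melt_profile(paste0(strrep("A", 100), "N",
                                    strrep("A", 200)), 50)
  expect_true(is.na(pn[100]))
  expect_false(is.na(pn[200]))

  expect_error(delta_g_melt_profile("ACGT", 10), "wider")
})

test_that("melting profile anticorrelates with AT content on random sequence", {
  set.seed(25)
  s <- random_seq(2000, 0.5)
  dg <- delta_g_melt_profile(s, 200)
  at <- at_profile(s, 200)
  ok <- !is.na(dg)
  expect_lt(cor(dg[ok], at[ok], method = "spearman"), 0)
})

test_that("MEME motif files round-trip", {
  p1 <- default_polya_pwm()
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme_motifs(list(p1), path)
  back <- read_meme_motifs(path)
  expect_length(back, 1)
  expect_equal(back[[1]]$matrix, p1$matrix, tolerance = 1e-5)
  expect_equal(nrow(back[[1]]$matrix), 15)

  bad <- withr::local_tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "MOTIF broken",
               "letter-probability matrix: alength= 4 w= 2",
               "0.5 0.5", "0.25 0.25 0.25 0.25"), bad)
  expect_error(read_meme_motifs(bad), "malformed")
})

test_that("a degenerate single-base PWM scores in bits against the background", {
  p1 <- pwm(matrix(c(1, 0, 0, 0), nrow = 1), name = "A")
  hits <- scan_pwm(c(s = "AG"), p1, fdr = 0.5, both_strands = FALSE,
                   background = rep(0.25, 4))
  expect_equal(hits$start, 0)
  expect_equal(hits$score, 2)          # log2(1 / 0.25)
  expect_equal(hits$p_value, 0.25)
})

test_that("planted consensus motifs are recovered and p-values match an empirical null", {
  set.seed(26)
  pw <- default_polya_pwm()
  cons <- paste(c("A", "C", "G", "T")[apply(pw$matrix, 1, which.max)],
                collapse = "")
  bg <- strsplit(random_seq(50000, 0.5), "")[[1]]
  plant_at <- seq(1000, 49000, by = 2500)
  for (p0 in plant_at)
    bg[p0:(p0 + 14)] <- strsplit(cons, "")[[1]]
  seqs <- c(chr = paste(bg, collapse = ""))
  hits <- scan_pwm(seqs, pw, fdr = 0.05)
  u <- union_motif_sites(hits)
  rec <- vapply(plant_at, function(p0)
    any(u$start < p0 + 14 & u$end > p0 - 1), logical(1))
  expect_true(all(rec))

  # p-values vs empirical null from random L-mers
  lw <- log2(sweep(pmax(pw$matrix, 1e-6), 2, rep(0.25, 4), "/"))
  nmc <- 20000
  null_sc <- vapply(seq_len(nmc), function(i) {
    b <- sample.int(4, 15, replace = TRUE)
    sum(lw[cbind(1:15, b)])
  }, numeric(1))
  some <- scan_pwm(c(chr = random_seq(2000, 0.5)), pw, fdr = 1,
                   both_strands = FALSE, background = rep(0.25, 4))
  for (i in seq_len(min(5, nrow(some)))) {
    emp <- mean(null_sc >= some$score[i] - 1e-6)
    expect_lt(abs(emp - some$p_value[i]),
              3 * sqrt(some$p_value[i] * (1 - some$p_value[i]) / nmc) +
                0.002)
  }
})

test_that("hit count shrinks as the FDR level tightens", {
  set.seed(27)
  seqs <- c(chr = random_seq(20000, 0.64))
  n_at <- sapply(c(0.2, 0.05, 0.01), function(f)
    nrow(scan_pwm(seqs, default_polya_pwm(), fdr = f)))
  expect_true(all(diff(n_at) <= 0))
})

test_that("motif union merges >= 1 bp overlaps, is idempotent and order-invariant", {
  h <- function(s, e, sc = 1) data.frame(chrom = "c", start = s, end = e,
                                         strand = "+", score = sc,
                                         p_value = 0.01, q_value = 0.01)
  expect_equal(nrow(union_motif_sites(h(0, 15), h(0, 15))), 1)
  u <- union_motif_sites(h(0, 15, 1), h(10, 25, 3))
  expect_equal(u$start, 0); expect_equal(u$end, 25)
  expect_equal(u$score, 3)             # best member score kept
  # bookended intervals share no base: not merged
  expect_equal(nrow(union_motif_sites(h(0, 15), h(15, 30))), 2)

  set.seed(28)
  s <- sample(0:500, 30); a <- h(s, s + sample(5:20, 30, replace = TRUE))
  u1 <- union_motif_sites(a)
  u2 <- union_motif_sites(a[rev(seq_len(nrow(a))), ])
  expect_equal(u1, u2)
  expect_equal(union_motif_sites(cbind(u1, strand = "+", p_value = 0,
                                       q_value = 0)), u1)
  # sweep-line oracle
  o <- a[order(a$start), ]
  merged <- list(); cur <- c(o$start[1], o$end[1])
  for (i in 2:nrow(o)) {
    if (o$start[i] < cur[2]) cur[2] <- max(cur[2], o$end[i])
    else { merged[[length(merged) + 1]] <- cur; cur <- c(o$start[i], o$end[i]) }
  }
  merged[[length(merged) + 1]] <- cur
  mg <- do.call(rbind, merged)
  expect_equal(u1$start, mg[, 1])
  expect_equal(u1$end, mg[, 2])
})

test_that("motif counting near an anchor uses closed midpoint membership", {
  u <- data.frame(chrom = "c", start = c(0, 240, 600), end = c(20, 260, 620),
                  score = 1)
  expect_equal(count_motifs_near(u[0, ], "c", 100), 0L)
  # midpoint 250 at anchor 0 + radius 250: counted (closed interval)
  expect_equal(count_motifs_near(u, "c", 0, 250), 2L)
  expect_equal(count_motifs_near(u, "c", 1000, 250), 0L)
  expect_equal(count_motifs_near(u, "c", 400, 250), 2L)
})
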