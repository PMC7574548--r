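test_that("window construction centres the anchor and checks bounds", {
  expect_equal(build_window(5000, 1000, 1e5),
               c(start = 4500, end = 5500))
  expect_error(build_window(300, 1000, 1e5), "outside")
  # odd width: left-biased
  expect_equal(build_window(5000, 1001, 1e5),
               c(start = 4500, end = 5501))
})

test_that("a null window scores zero on every planted feature", {
  set.seed(41)
  genome <- c(chr = random_seq(3000, at = 0.5))
  cov <- list(chr = rep(9, 3000))
  u <- data.frame(chrom = character(0), start = numeric(0),
                  end = numeric(0), score = numeric(0))
  f <- extract_features(genome, u, cov, "chr", 1500)
  expect_equal(unname(f["n_mt"]), 0)
  expect_equal(unname(f["l_at"]), 0)
  expect_equal(unname(f["l_ntx"]), 0)
  expect_equal(unname(f["motif_dist_center"]), 500)
  expect_equal(unname(f["is_divergent"]), 0)
})

test_that("planted OM windows reach the expected trio levels", {
  st <- small_study()
  tr <- st$sim$truth$sites
  om <- tr[tr$class == "OM", ]
  ok_trio <- 0
  for (i in seq_len(nrow(om))) {
    f <- extract_features(st$sim$genome, st$union, st$sim$coverage,
                          om$chrom[i], om$orc_anchor[i])
    ok_trio <- ok_trio + (f["n_mt"] >= 1 && f["l_at"] >= 150 &&
                            f["l_ntx"] >= 600)
  }
  expect_gte(ok_trio / nrow(om), 0.9)
})

test_that("feature vectors agree with an independent naive recomputation", {
  st <- small_study()
  set.seed(42)
  chrs <- names(st$lens)
  for (r in 1:25) {
    chr <- sample(chrs, 1)
    anchor <- sample(seq(2000, st$lens[[chr]] - 2000), 1)
    f <- extract_features(st$sim$genome, st$union, st$sim$coverage, chr,
                          anchor)
    seq <- st$sim$genome[[chr]]
    expect_equal(unname(f["l_at"]),
                 naive_l_at(seq, anchor - 500, anchor + 500))
    expect_equal(unname(f["l_ntx"]),
                 naive_l_ntx(st$sim$coverage[[chr]], anchor - 500,
                             anchor + 500))
    u <- st$union[st$union$chrom == chr, ]
    mids <- (u$start + u$end) / 2
    expect_equal(unname(f["n_mt"]),
                 sum(mids >= anchor - 500 & mids <= anchor + 500))
    expect_equal(unname(f["at_mean"]),
                 naive_at_count(substr(seq, anchor - 499,
                                       anchor + 500)) / 1000)
  }
})

test_that("the IGR dataset separates positives, negatives and held-out O windows", {
  st <- small_study()
  ds <- build_igr_dataset(st$igrs, st$ss, st$sim$genome, st$union,
                          st$sim$coverage, st$sim$genes)
  expect_setequal(levels(ds$y), c("neg", "pos"))
  # positives anchored on intergenic OM summits
  n_om_igr <- sum(!is.na(
    oriscan:::point_in_igr(st$igrs, st$ss$om$chrom, st$ss$om$orc_summit)))
  expect_equal(sum(ds$y == "pos"), n_om_igr)
  # positives and negatives use disjoint IGR sets
  expect_length(intersect(ds$meta$igr_id[ds$y == "pos"],
                          ds$meta$igr_id[ds$y == "neg"]), 0)
  # held-out O IGRs neither positive nor negative
  expect_length(intersect(ds$heldout_meta$igr_id, ds$meta$igr_id), 0)
  expect_false(any(is.na(ds$X)))

  # under include_o the held-out windows move into the negatives
  ds2 <- build_igr_dataset(st$igrs, st$ss, st$sim$genome, st$union,
                           st$sim$coverage, st$sim$genes,
                           policy = "include_o")
  expect_equal(sum(ds2$y == "neg"),
               sum(ds$y == "neg") + nrow(ds$heldout_meta))

  # positives roughly match the generator's planted intergenic OM count
  n_planted <- sum(st$sim$truth$sites$class == "OM")
  expect_lte(abs(sum(ds$y == "pos") - n_planted), 3)
})

test_that("intragenic dataset keeps controls away from OM/O sites and is seed-stable", {
  st <- small_study()
  ds <- build_intragenic_dataset(st$ss, st$igrs, st$sim$genome, st$union,
                                 st$sim$coverage,
                                 genome_arms(st$lens, st$sim$mask),
                                 seed = 7)
  expect_equal(colnames(ds$X), c("n_mt", "l_at", "l_ntx"))
  expect_equal(sum(ds$y == "neg"), 5 * sum(ds$y == "pos"))
  # every control at distance > 1 kb from any OM/O interval
  occ <- rbind(data.frame(chrom = st$ss$om$chrom,
                          start = st$ss$om$orc_start,
                          end = st$ss$om$orc_end),
               data.frame(chrom = st$ss$o$chrom, start = st$ss$o$start,
                          end = st$ss$o$end))
  ctrl <- ds$meta[ds$meta$class == "neg", ]
  for (i in seq_len(nrow(ctrl))) {
    oc <- occ[occ$chrom == ctrl$chrom[i], ]
    d <- min(pmax(oc$start - ctrl$anchor[i],
                  ctrl$anchor[i] - oc$end + 1, 0))
    expect_gt(d, 1000)
  }
  ds2 <- build_intragenic_dataset(st$ss, st$igrs, st$sim$genome, st$union,
                                  st$sim$coverage,
                                  genome_arms(st$lens, st$sim$mask),
                                  seed = 7)
  expect_identical(ds$meta, ds2$meta)
})
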