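test_that("FASTA round-trip preserves sequences and rejects bad input", {
  set.seed(101)
  g <- c(chrA = random_seq(500), chrB = random_seq(300))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_genome(g, fa)
  back <- read_genome(fa)
  expect_identical(back, g)

  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_error(read_genome(empty), "no records")

  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGT", ">x", "TTTT"), dup)
  expect_error(read_genome(dup), "duplicate")
})

test_that("default UTR extension follows the 293/430 bp rule with strand mirroring and clamping", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=gplus",
               "chr1\tsrc\tgene\t1001\t2000\t.\t-\t.\tID=gminus",
               "chr1\tsrc\tgene\t101\t400\t.\t+\t.\tID=gclamp",
               "chr1\tsrc\tgene\t3001\t3600\t.\t+\t.\tID=gdub;note=dubious"),
             gff)
  genes <- read_genes(gff, chrom_lengths = c(chr1 = 5000))
  gp <- genes[genes$gene_id == "gplus", ]
  expect_equal(gp$tss, 707)    # 1000 - 293
  expect_equal(gp$tts, 2430)   # 2000 + 430
  gm <- genes[genes$gene_id == "gminus", ]
  expect_equal(gm$tss, 2293)   # 2000 + 293
  expect_equal(gm$tts, 570)    # 1000 - 430
  expect_equal(gm$span_start, 570)
  expect_equal(gm$span_end, 2293)
  gc <- genes[genes$gene_id == "gclamp", ]
  expect_equal(gc$tss, 0)      # clamped at the chromosome start
  expect_false("gdub" %in% genes$gene_id)  # dubious ORFs excluded
})

test_that("explicit UTR records override the defaults", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=g1",
               "chr1\tsrc\tfive_prime_UTR\t951\t1000\t.\t+\t.\tParent=g1",
               "chr1\tsrc\tthree_prime_UTR\t2001\t2080\t.\t+\t.\tParent=g1"),
             gff)
  g <- read_genes(gff)
  expect_equal(g$tss, 950)     # 50 bp 5' UTR
  expect_equal(g$tts, 2080)    # 80 bp 3' UTR
})

test_that("gene models without strand are rejected", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t100\t200\t.\t.\t.\tID=gx"), gff)
  expect_error(read_genes(gff), "strand")
})

test_that("IGR derivation complements gene spans and drops closed gaps", {
  genes <- data.frame(
    gene_id = c("a", "b"), chrom = "chr1",
    orf_start = c(0, 800), orf_end = c(500, 1200), strand = c("+", "+"),
    tss = c(0, 800), tts = c(500, 1200),
    span_start = c(0, 800), span_end = c(500, 1200), rpkm = NA_real_)
  igrs <- derive_igrs(genes, c(chr1 = 1500))
  expect_equal(igrs$start, c(500, 1200))
  expect_equal(igrs$end, c(800, 1500))

  # overlapping genes leave no IGR between them
  genes2 <- genes
  genes2$span_end[1] <- 900
  igrs2 <- derive_igrs(genes2, c(chr1 = 1500))
  expect_equal(nrow(igrs2), 1)
  expect_equal(igrs2$start, 1200)
})

test_that("gene spans and IGRs tile each arm without overlap or gap", {
  st <- small_study()
  genes <- st$sim$genes
  arms <- genome_arms(st$lens, st$sim$mask)
  for (chr in names(st$lens)) {
    cover <- rbind(
      data.frame(start = genes$span_start[genes$chrom == chr],
                 end = genes$span_end[genes$chrom == chr]),
      data.frame(start = st$igrs$start[st$igrs$chrom == chr],
                 end = st$igrs$end[st$igrs$chrom == chr]))
    cover <- cover[order(cover$start), ]
    # no overlap between consecutive pieces inside the arms
    expect_true(all(diff(cover$start) >= 0))
    a <- arms[arms$chrom == chr, ]
    covered <- sum(pmin(cover$end, max(a$end)) -
                     pmax(cover$start, min(a$start)))
    expect_equal(covered, sum(a$end - a$start))
  }
})

test_that("orientation classification matches the strand rules and is reflection-invariant", {
  expect_equal(classify_orientation("-", "+"), "divergent")
  expect_equal(classify_orientation("+", "-"), "convergent")
  expect_equal(classify_orientation("+", "+"), "tandem")
  expect_equal(classify_orientation("-", "-"), "tandem")
  expect_equal(classify_orientation(NA, "+"), "edge")

  flip <- function(s) ifelse(s == "+", "-", "+")
  set.seed(3)
  for (i in 1:20) {
    l <- sample(c("+", "-"), 1); r <- sample(c("+", "-"), 1)
    # reflecting the chromosome swaps the flanks and flips the strands
    expect_equal(classify_orientation(l, r),
                 classify_orientation(flip(r), flip(l)))
  }
})

test_that("second-flank orientation uses the genes one further out", {
  genes <- data.frame(
    gene_id = letters[1:4], chrom = "chr1",
    orf_start = c(0, 600, 2000, 2600),
    orf_end = c(500, 1100, 2500, 3100),
    strand = c("-", "+", "-", "+"),
    tss = 0, tts = 0,
    span_start = c(0, 600, 2000, 2600),
    span_end = c(500, 1100, 2500, 3100), rpkm = NA_real_)
  igrs <- derive_igrs(genes, c(chr1 = 3200))
  mid <- igrs[igrs$start == 1100, ]
  expect_equal(mid$orientation, "convergent")       # b(+) | c(-)
  expect_equal(mid$second_orientation, "divergent") # a(-) | d(+)
})

test_that("RPKM follows the per-kb per-million definition", {
  expect_equal(compute_rpkm(10, 1000, 1e6), 10)
  expect_equal(compute_rpkm(0, 1000, 1e6), 0)
  expect_equal(compute_rpkm(57, 2000, 5.7e6), 5)
  expect_error(compute_rpkm(1, 0, 1e6), "exon_length")
  expect_error(compute_rpkm(1, 100, 0), "total_mapped")
})

test_that("simulated annotation round-trips through GFF3 with identical spans", {
  st <- small_study()
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_genes_gff3(st$sim$genes, gff)
  back <- read_genes(gff, chrom_lengths = st$lens)
  orig <- st$sim$genes[order(st$sim$genes$chrom,
                             st$sim$genes$span_start), ]
  expect_equal(back$orf_start, orig$orf_start)
  expect_equal(back$orf_end, orig$orf_end)
  expect_equal(back$strand, orig$strand)
  # defaults re-derive the same UTR-extended extents (idempotence)
  expect_equal(back$span_start, pmax(orig$span_start, 0))
  expect_equal(back$span_end,
               unname(pmin(orig$span_end, st$lens[orig$chrom])))
})
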