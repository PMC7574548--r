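# Base encoding: A=1, C=2, G=3, T=4, anything else (incl. N) = NA.
seq_ints <- function(seq) {
  match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Sliding mean of x over centered windows of width w, truncated at the ends.
# Window at i covers [i - floor(w/2), i + ceiling(w/2) - 1] intersect [1, n].
centered_window_mean <- function(x, w) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - floor(w / 2), 1)
  hi <- pmin(seq_len(n) + ceiling(w / 2) - 1, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' AT fraction of a sequence
#'
#' `(#A + #T) / length`; N counts as non-AT.
#'
#' @param seq DNA string.
#' @param start,end optional 0-based half-open sub-interval.
#' @return Fraction in `[0, 1]`.
#' @export
at_fraction <- function(seq, start = NULL, end = NULL) {
  if (!is.null(start)) seq <- substr(seq, start + 1, end)
  b <- seq_ints(seq)
  sum(b %in% c(1, 4)) / length(b)
}

#' Sliding-window AT-content profile
#'
#' Per-position AT fraction over a centered window (truncated at sequence
#' ends), as used for origin AT-content profiles.
#'
#' @param seq DNA string.
#' @param window window width in bp.
#' @return Numeric vector, one value per position.
#' @export
at_profile <- function(seq, window = 100) {
  b <- seq_ints(seq)
  centered_window_mean(as.numeric(b %in% c(1, 4)), window)
}

#' Length of AT-rich regions in a window (L_AT)
#'
#' Number of positions inside `[start, end)` whose centered `w`-bp window has
#' AT fraction at or above `threshold`. The local windows may extend into the
#' flanking chromosome sequence (truncated only at chromosome ends).
#'
#' @param seq chromosome sequence.
#' @param start,end 0-based half-open analysis window (typically 1 kb).
#' @param w local AT window width (odd, default 101).
#' @param threshold AT fraction cutoff.
#' @return Length in bp.
#' @export
l_at <- function(seq, start, end, w = 101, threshold = 0.75) {
  n <- nchar(seq)
  stopifnot(start >= 0, end <= n, end > start)
  pad <- floor(w / 2)
  lo <- max(start - pad, 0)            # 0-based
  hi <- min(end + pad, n)
  b <- seq_ints(substr(seq, lo + 1, hi))
  prof <- centered_window_mean(as.numeric(b %in% c(1, 4)), w)
  # truncation at the excerpt boundary only valid where it matches the
  # chromosome boundary; interior excerpt edges carry full windows
  idx <- (start - lo + 1):(end - lo)
  sum(prof[idx] >= threshold)
}

#' AT fraction of the two 400 bp flanks of a summit
#'
#' Left flank `[summit - 500, summit - 100)`, right flank
#' `[summit + 100, summit + 500)`.
#'
#' @param seq chromosome sequence.
#' @param summit 0-based summit coordinate.
#' @return Named vector `c(left_at, right_at)`.
#' @export
flank_at <- function(seq, summit) {
  n <- nchar(seq)
  if (summit - 500 < 0 || summit + 500 > n)
    stop("summit flank extends outside the chromosome")
  c(left_at = at_fraction(seq, summit - 500, summit - 100),
    right_at = at_fraction(seq, summit + 100, summit + 500))
}

#' Longest run of consecutive A/T bases
#'
#' @param seq DNA string (or window excerpt).
#' @return Run length in bp.
#' @export
run_max_at <- function(seq) {
  b <- seq_ints(seq) %in% c(1, 4)
  r <- rle(b)
  m <- r$lengths[r$values]
  if (length(m) == 0) 0L else max(m)
}

#' Nearest-neighbour DNA melting free energies
#'
#' Unified duplex nearest-neighbour stacking free energies (delta-G at 37 C,
#' kcal/mol; SantaLucia 1998 unified table), expanded to all 16 dinucleotide
#' steps under reverse-complement symmetry. Duplex-initiation terms are
#' omitted: melting profiles are used comparatively, not as absolute duplex
#' stabilities.
#'
#' @return Named numeric vector of 16 dinucleotide step free energies.
#' @export
nn_dg37 <- function() {
  c(AA = -1.00, TT = -1.00, AT = -0.88, TA = -0.58,
    CA = -1.45, TG = -1.45, GT = -1.44, AC = -1.44,
    CT = -1.28, AG = -1.28, GA = -1.30, TC = -1.30,
    CG = -2.17, GC = -2.24, GG = -1.84, CC = -1.84)
}

#' Sliding-window DNA strand-separation energy profile
#'
#' For each position the free energy required to melt the centered
#' `window`-bp duplex, computed as minus the sum of the nearest-neighbour
#' stacking free energies over the `window - 1` dinucleotide steps. Higher
#' values mean more energy to separate the strands; AT-rich windows melt more
#' easily. Positions whose window leaves the sequence or contains N are `NA`.
#'
#' @param seq DNA string.
#' @param window window width in bp.
#' @param params dinucleotide step free-energy map, see [nn_dg37()].
#' @return Numeric vector of delta-G_melt (kcal/mol), one value per position.
#' @export
delta_g_melt_profile <- function(seq, window = 200, params = nn_dg37()) {
  n <- nchar(seq)
  if (window > n) stop("window wider than the sequence")
  bases <- strsplit(seq, "")[[1]]
  steps <- paste0(bases[-n], bases[-1])
  e <- unname(params[steps])          # NA for steps touching N
  k <- window - 1
  bad <- is.na(e); e[bad] <- 0
  cs <- c(0, cumsum(e)); cb <- c(0, cumsum(bad))
  # window centered at i covers bases [i - floor(w/2), i + ceil(w/2) - 1],
  # i.e. steps [i - floor(w/2), i + ceil(w/2) - 2] (1-based step index)
  out <- rep(NA_real_, n)
  first <- floor(window / 2) + 1
  last <- n - ceiling(window / 2) + 1
  if (last >= first) {
    i <- first:last
    s0 <- i - floor(window / 2)
    sums <- cs[s0 + k] - cs[s0]
    nbad <- cb[s0 + k] - cb[s0]
    vals <- -sums
    vals[nbad > 0] <- NA_real_
    out[i] <- vals
  }
  out
}

# ---- position weight matrices ------------------------------------------

#' Position weight matrix
#'
#' @param matrix numeric `L x 4` matrix of base probabilities, columns
#'   `A, C, G, T`; each row sums to 1.
#' @param background length-4 strictly positive base probabilities.
#' @param name motif name.
#' @return Object of class `pwm`.
#' @export
pwm <- function(matrix, background = rep(0.25, 4), name = "motif") {
  matrix <- as.matrix(matrix)
  stopifnot(ncol(matrix) == 4, nrow(matrix) >= 1)
  colnames(matrix) <- c("A", "C", "G", "T")
  if (any(abs(rowSums(matrix) - 1) > 1e-9))
    stop("PWM rows must sum to 1")
  background <- as.numeric(background)
  stopifnot(length(background) == 4, all(background > 0))
  structure(list(matrix = matrix, background = background / sum(background),
                 name = name), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cons <- paste(c("A", "C", "G", "T")[apply(x$matrix, 1, which.max)],
                collapse = "")
  cat(sprintf("PWM '%s': %d bp, consensus %s\n", x$name, nrow(x$matrix),
              cons))
  invisible(x)
}

#' Default A-rich test motif
#'
#' A synthetic 15 bp poly(dA)-like position weight matrix (strong-A columns
#' interleaved with A/T columns) used by the simulator and tests. It is
#' not a motif derived from real Orc4-binding data; supply discovered
#' motifs in MEME format for real analyses.
#'
#' @return A `pwm`.
#' @export
default_polya_pwm <- function() {
  strong_a <- c(0.88, 0.04, 0.04, 0.04)
  at_mix <- c(0.55, 0.04, 0.04, 0.37)
  rows <- lapply(1:15, function(j) if (j %% 4 == 0) at_mix else strong_a)
  pwm(do.call(rbind, rows), name = "polyA_synthetic")
}

#' Read and write motifs in minimal MEME format
#'
#' @param path file path.
#' @param pwms list of `pwm` objects (write direction).
#' @return `read_meme_motifs()` returns a list of `pwm`;
#'   `write_meme_motifs()` returns `path` invisibly.
#' @export
read_meme_motifs <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl) > 0 && bgl[1] < length(lines)) {
    tok <- strsplit(trimws(lines[bgl[1] + 1]), "\\s+")[[1]]
    freq <- suppressWarnings(as.numeric(tok[c(2, 4, 6, 8)]))
    if (!any(is.na(freq))) bg <- freq
  }
  starts <- grep("^MOTIF", lines)
  if (length(starts) == 0) stop("no MOTIF records in ", path)
  out <- list()
  for (s in starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    h <- grep("^letter-probability matrix", lines[s:length(lines)])[1] + s - 1
    wtok <- regmatches(lines[h], regexec("w=\\s*(\\d+)", lines[h]))[[1]][2]
    w <- as.integer(wtok)
    if (is.na(w)) stop("malformed letter-probability header in ", path)
    rows <- lines[(h + 1):(h + w)]
    vals <- lapply(rows, function(l) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
      if (length(v) != 4 || any(is.na(v)))
        stop("malformed probability row in ", path)
      v
    })
    out[[length(out) + 1]] <- pwm(do.call(rbind, vals), background = bg,
                                  name = name)
  }
  out
}

#' @rdname read_meme_motifs
#' @export
write_meme_motifs <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bg <- pwms[[1]]$background
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -",
               "", "Background letter frequencies",
               sprintf("A %.6f C %.6f G %.6f T %.6f", bg[1], bg[2], bg[3],
                       bg[4]), ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       nrow(p$matrix)), con)
    writeLines(apply(p$matrix, 1, function(r)
      sprintf("%.6f %.6f %.6f %.6f", r[1], r[2], r[3], r[4])), con)
    writeLines("", con)
  }
  invisible(path)
}

# reverse-complement of a PWM (reverse rows, swap A<->T and C<->G)
pwm_revcomp <- function(p) {
  m <- p$matrix[rev(seq_len(nrow(p$matrix))), c(4, 3, 2, 1), drop = FALSE]
  pwm(m, background = p$background, name = paste0(p$name, "_rc"))
}

# Exact null tail of the discretized log-likelihood-ratio score by dynamic
# programming over PWM columns under the background distribution.
# Returns list(tail = P(S >= s) indexed by integer score - offset + 1).
pwm_null_tail <- function(iw, q) {
  L <- nrow(iw)
  lo <- sum(apply(iw, 1, min)); hi <- sum(apply(iw, 1, max))
  probs <- numeric(hi - lo + 1)
  # DP: distribution over partial sums
  cur <- 1; cur_lo <- 0
  for (j in seq_len(L)) {
    w <- iw[j, ]
    new_lo <- cur_lo + min(w)
    new_hi <- cur_lo + length(cur) - 1 + max(w)
    nxt <- numeric(new_hi - new_lo + 1)
    for (b in 1:4) {
      sh <- cur_lo + w[b] - new_lo
      idx <- (sh + 1):(sh + length(cur))
      nxt[idx] <- nxt[idx] + cur * q[b]
    }
    cur <- nxt; cur_lo <- new_lo
  }
  tail <- rev(cumsum(rev(cur)))
  tail <- pmin(tail, 1)
  list(tail = tail, lo = cur_lo)
}

#' Scan sequences with a PWM at a given FDR
#'
#' Scores every position (both strands by default) with the
#' log2-likelihood-ratio of the PWM against the background, computes exact
#' p-values from the null score distribution (dynamic programming over
#' columns, scores discretized to a fixed grid), applies Benjamini-Hochberg
#' correction jointly across all scanned positions of all sequences, and
#' returns the hits with `q <= fdr`. Positions whose window contains N are
#' skipped.
#'
#' @param seqs named character vector of sequences.
#' @param pwm a [pwm()].
#' @param fdr false-discovery-rate threshold.
#' @param both_strands scan the reverse strand too.
#' @param background optional length-4 base probabilities; by default
#'   estimated from the scanned sequences.
#' @param grid_bits score discretization grid (bits).
#' @return `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `score` (bits), `p_value`, `q_value`.
#' @export
scan_pwm <- function(seqs, pwm, fdr = 0.05, both_strands = TRUE,
                     background = NULL, grid_bits = 1e-3) {
  stopifnot(inherits(pwm, "pwm"))
  L <- nrow(pwm$matrix)
  enc <- lapply(seqs, seq_ints)
  if (is.null(background)) {
    counts <- rep(1, 4)  # pseudocount keeps q strictly positive
    for (b in enc) {
      t <- tabulate(b[!is.na(b)], nbins = 4)
      counts <- counts + t
    }
    background <- counts / sum(counts)
  }
  q <- background / sum(background)

  scan_one_strand <- function(p, strand) {
    # floor zero probabilities so log-likelihood ratios stay finite
    lw <- log2(sweep(pmax(p$matrix, 1e-6), 2, q, "/"))
    iw <- round(lw / grid_bits)
    storage.mode(iw) <- "integer"
    null <- pwm_null_tail(iw, q)
    res <- list()
    for (chr in names(seqs)) {
      b <- enc[[chr]]
      n <- length(b)
      if (n < L) next
      np <- n - L + 1
      s <- integer(np); nas <- integer(np)
      bna <- is.na(b); b0 <- b; b0[bna] <- 1L
      for (j in seq_len(L)) {
        idx <- j:(j + np - 1)
        s <- s + iw[j, ][b0[idx]]
        nas <- nas + bna[idx]
      }
      valid <- nas == 0
      if (!any(valid)) next
      pos <- which(valid)
      sc <- s[valid]
      pv <- null$tail[pmax(sc - null$lo + 1, 1)]
      pv[sc - null$lo + 1 > length(null$tail)] <- 0
      res[[chr]] <- data.frame(chrom = chr, start = pos - 1,
                               end = pos - 1 + L, strand = strand,
                               score = sc * grid_bits, p_value = pv,
                               stringsAsFactors = FALSE)
    }
    if (length(res) == 0) NULL else do.call(rbind, res)
  }

  hits <- scan_one_strand(pwm, "+")
  if (both_strands)
    hits <- rbind(hits, scan_one_strand(pwm_revcomp(pwm), "-"))
  if (is.null(hits) || nrow(hits) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      score = numeric(0), p_value = numeric(0),
                      q_value = numeric(0), stringsAsFactors = FALSE))
  hits$p_value <- pmax(hits$p_value, .Machine$double.xmin)
  hits$q_value <- stats::p.adjust(hits$p_value, method = "BH")
  out <- hits[hits$q_value <= fdr, , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge motif hits into a union site list
#'
#' Combines hit lists from different motif discovery tools, drops strand and
#' merges locations sharing at least 1 bp into single larger sites. Each
#' union site carries the best (maximum) member score.
#'
#' @param ... motif hit `data.frame`s from [scan_pwm()].
#' @return `data.frame` with columns `chrom`, `start`, `end`, `score`,
#'   sorted and pairwise disjoint.
#' @export
union_motif_sites <- function(...) {
  hits <- do.call(rbind, lapply(list(...), function(h)
    h[, c("chrom", "start", "end", "score"), drop = FALSE]))
  if (is.null(hits) || nrow(hits) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  gr <- gi2gr(hits)
  BiocGenerics::strand(gr) <- "*"
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  ov <- GenomicRanges::findOverlaps(gr, red)
  score <- tapply(hits$score[S4Vectors::queryHits(ov)],
                  S4Vectors::subjectHits(ov), max)
  out <- gr2gi(red)
  out$score <- as.numeric(score[as.character(seq_along(red))])
  out$strand <- NULL
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count motif-union sites near an anchor
#'
#' Number of union sites whose midpoint falls in the closed interval
#' `[anchor - radius, anchor + radius]`.
#'
#' @param union_sites union site `data.frame` from [union_motif_sites()].
#' @param chrom chromosome of the anchor.
#' @param anchor 0-based coordinate (e.g. an Orc4 peak summit).
#' @param radius half-width in bp.
#' @return Integer count.
#' @export
count_motifs_near <- function(union_sites, chrom, anchor, radius = 250) {
  u <- union_sites[union_sites$chrom == chrom, , drop = FALSE]
  if (nrow(u) == 0) return(0L)
  mid <- (u$start + u$end) / 2
  sum(mid >= anchor - radius & mid <= anchor + radius)
}
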