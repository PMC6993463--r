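test_that("top_kmers counts canonical 12-mers exactly", {
  # one read of 20 A's: 9 sliding windows of the single k-mer AAAAAAAAAAAA,
  # whose canonical form is itself (A... < T...)
  prof <- top_kmers(strrep("A", 20), k = 12, top = 100)
  expect_equal(prof$kmer, strrep("A", 12))
  expect_equal(prof$count, 9L)

  # oracle: naive string counting on random reads with Ns
  set.seed(51)
  seqs <- c(replicate(20, rand_dna(60)), "ACGTNACGTACGTACGTN")
  prof2 <- top_kmers(seqs, k = 12, top = 1000)
  bf <- count_kmers_bf(seqs, 12)
  expect_equal(nrow(prof2), length(bf))
  got <- stats::setNames(prof2$count, prof2$kmer)
  expect_equal(got[sort(names(got))], bf[sort(names(bf))])
  # ordering: counts non-increasing, ties lexicographic
  expect_true(all(diff(prof2$count) <= 0))

  few <- top_kmers(rand_dna(30, seed = 52), k = 12, top = 100)
  expect_lte(nrow(few), 19)
  expect_error(top_kmers("ACGT", k = 12), "exceeds")
})

test_that("map_kmers finds every occurrence on both strands", {
  km <- "ACGGTTACCAGT"
  genome <- c(chr1 = paste0(rand_dna(40, seed = 53), km, rand_dna(30),
                            revcomp(km), rand_dna(20)))
  hits <- map_kmers(km, genome)
  expect_equal(hits$chr1, c(40L, 82L))

  # tandem array: overlapping occurrences all counted, oracle = naive scan
  array5k <- strrep("ACA", 1680)
  g2 <- c(chrA = paste0(rand_dna(100, seed = 54), array5k, rand_dna(100)))
  km2 <- "ACAACAACAACA"
  got <- map_kmers(km2, g2)$chrA
  naive <- integer(0)
  s <- g2[["chrA"]]
  for (i in seq_len(nchar(s) - 11)) {
    w <- substr(s, i, i + 11)
    if (w == km2 || w == revcomp(km2)) naive <- c(naive, i - 1L)
  }
  expect_equal(got, naive)
  # the 12-mer has period 3, so it matches at every third offset of the array
  expect_gt(length(got), 1500)

  none <- map_kmers("TTTTTTTTTTTA", c(chr1 = strrep("C", 5000)))
  expect_equal(none$chr1, integer(0))
})

test_that("make_windows matches the bedtools sliding-window rule", {
  w <- make_windows(500000, 200000, 100000)
  expect_equal(w$start, c(0, 100000, 200000, 300000, 400000))
  expect_equal(w$end, c(200000, 300000, 400000, 500000, 500000))

  short <- make_windows(150000, 200000, 100000)
  expect_equal(nrow(short), 2L)
  expect_equal(short$start, c(0, 100000))
  expect_equal(short$end, c(150000, 150000))

  exact <- make_windows(200000, 200000, 100000)
  expect_equal(exact$start, c(0, 100000))
  expect_equal(exact$end, c(200000, 200000))

  expect_error(make_windows(1000, 0, 100), "width")
  expect_error(make_windows(1000, 100, -1), "step")
})

test_that("window_counts assigns hits to every containing window", {
  w <- make_windows(500000, 200000, 100000)
  expect_equal(window_counts(150000L, w), c(1L, 1L, 0L, 0L, 0L))
  expect_equal(window_counts(integer(0), w), rep(0L, 5))

  # oracle: brute-force double loop; overlap-zone hits count exactly twice
  set.seed(55)
  pos <- sort(sample(0:499999, 300))
  got <- window_counts(pos, w)
  bf <- vapply(seq_len(nrow(w)), function(i)
    sum(vapply(pos, function(p) p >= w$start[i] && p < w$end[i], logical(1))),
    integer(1))
  expect_equal(got, bf)
  # positions >= 100 kb are covered by exactly two windows here (the
  # truncated last window doubles up with the one before it)
  in_overlap <- pos >= 100000
  expect_equal(sum(got), sum(in_overlap) * 2L + sum(!in_overlap))
})

test_that("min/max scaling and its degenerate case", {
  expect_equal(scale_track(c(0, 5, 10)), c(0, 0.5, 1))
  expect_equal(scale_track(c(4, 4, 4)), c(0, 0, 0))
  x <- c(3, 9, 1, 5)
  expect_equal(scale_track(2 * x + 7), scale_track(x))  # affine invariance
})

test_that("loess smoothing is exact on constants and lines", {
  expect_equal(loess_smooth(rep(3.5, 20)), rep(3.5, 20))
  x <- seq(0, 19)
  y <- 2 * x + 1
  expect_equal(loess_smooth(y, x, span = 0.3), y, tolerance = 1e-6)
  expect_equal(loess_smooth(c(1, 2), span = 0.5), c(1, 2))  # pass-through
  expect_error(loess_smooth(y, x, span = 0), "span")
  expect_error(loess_smooth(y, x, span = 1.5), "span")
})

test_that("loess smoothing equals brute-force tricube WLS at every point", {
  # independent oracle: solve the weighted normal equations explicitly
  loess_bf <- function(y, x, span) {
    n <- length(y)
    q <- max(2L, min(n, as.integer(ceiling(span * n))))
    vapply(seq_len(n), function(i) {
      d <- abs(x - x[i])
      dq <- sort(d)[q]
      w <- if (dq == 0) as.numeric(d == 0) else
        ifelse(d / dq < 1, (1 - (d / dq)^3)^3, 0)
      if (dq > 0) w[d == 0] <- 1
      X <- cbind(1, x)
      beta <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
      beta[1] + beta[2] * x[i]
    }, numeric(1))
  }
  set.seed(57)
  for (i in 1:5) {
    n <- sample(10:40, 1)
    x <- sort(runif(n, 0, 100))
    y <- sin(x / 10) + rnorm(n, sd = 0.2)
    span <- runif(1, 0.2, 0.9)
    expect_equal(loess_smooth(y, x, span), loess_bf(y, x, span),
                 tolerance = 1e-9)
  }
})

test_that("gene density is the covered fraction of each window", {
  w <- make_windows(400000, 200000, 100000)
  full <- data.frame(start = 0L, end = 200000L)
  expect_equal(gene_density(full, w)[1], 1.0)

  half <- data.frame(start = 0L, end = 100000L)
  expect_equal(gene_density(half, w), c(0.5, 0, 0, 0))

  # overlapping genes merge before coverage
  two <- data.frame(start = c(0L, 40000L), end = c(60000L, 100000L))
  expect_equal(gene_density(two, w)[1], 0.5)

  expect_equal(gene_density(half[0, ], w), rep(0, 4))
  expect_error(gene_density(data.frame(start = 0L, end = 500000L), w,
                            chrom_length = 400000L), "beyond")
  expect_error(gene_density(data.frame(start = 10L, end = 10L), w))
})

test_that("correlations match brute-force covariance and rank arithmetic", {
  x <- 1:10
  expect_equal(correlate_tracks(x, 2 * x + 1)$pearson_r, 1)
  neg <- correlate_tracks(x, -x)
  expect_equal(neg$pearson_r, -1)
  expect_equal(neg$spearman_rho, -1)

  set.seed(59)
  a <- runif(20); b <- runif(20)
  res <- correlate_tracks(a, b)
  r_bf <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(res$pearson_r, r_bf, tolerance = 1e-12)
  expect_equal(res$pearson_r, stats::cor(a, b), tolerance = 1e-12)
  expect_equal(res$spearman_rho, stats::cor(a, b, method = "spearman"),
               tolerance = 1e-12)
  ref <- stats::cor.test(a, b)
  expect_equal(res$pearson_p, ref$p.value, tolerance = 1e-12)

  flat <- correlate_tracks(rep(1, 10), runif(10))
  expect_false(flat$defined)
  expect_true(is.na(flat$pearson_r))
})

test_that("painting localizes a planted tandem array", {
  lib <- make_repeat_library(
    list(repeat_family_spec("tand", "tandem", monomer_length = 180L,
                            target_copy_number = 300L,
                            intra_family_divergence = 0.02)), seed = 61)
  g <- build_genome(lib, chrom_lengths = c(chr1 = 400000L, chr2 = 300000L),
                    seed = 62)
  reads <- shotgun_reads(g, 2500, 150, seed = 63)
  fam <- true_read_family(reads, g)
  res <- paint_cluster(reads[fam == "tand", , drop = FALSE], g, g$genes,
                       width = 20000L, step = 10000L)
  tr <- res$track
  peak <- tr[which.max(tr$smoothed), ]
  locus_chrom <- g$truth$chrom[1]
  locus <- range(c(g$truth$start, g$truth$end)[g$truth$chrom == locus_chrom])
  expect_equal(peak$chrom, locus_chrom)
  expect_true(peak$start < locus[2] && peak$end > locus[1])
  # localized: windows far from the locus carry almost no signal
  off <- tr$chrom != locus_chrom
  expect_lt(max(tr$scaled[off]), 0.2)
})
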