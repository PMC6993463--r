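#' Most abundant canonical k-mers of a cluster
#'
#' Exact canonical k-mer counts over all cluster reads (a k-mer and its
#' reverse complement are one species, lexicographic minimum reported;
#' windows containing N are skipped). The top `top` by count are returned,
#' ties broken lexicographically.
#'
#' @param reads a `ReadSet` data.frame or character vector of sequences.
#' @param k k-mer length (default 12).
#' @param top number of k-mers to keep (default 100).
#' @return a `kmer_profile` data.frame (kmer, count), counts non-increasing.
#' @export
top_kmers <- function(reads, k = 12L, top = 100L) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  stopifnot(length(seqs) >= 1L)
  if (all(nchar(seqs) < k)) stop("k = ", k, " exceeds every read length")
  counts <- .count_canonical_kmers(seqs, as.integer(k))
  if (!length(counts)) {
    out <- data.frame(kmer = character(0), count = integer(0))
  } else {
    ord <- order(-counts, names(counts))
    keep <- head(ord, top)
    out <- data.frame(kmer = names(counts)[keep],
                      count = as.integer(counts[keep]),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("kmer_profile", "data.frame")
  out
}

#' Exact genomic positions of profile k-mers
#'
#' Every exact occurrence of each profile k-mer or its reverse complement,
#' reported as the 0-based start of the match on the forward strand.
#' Overlapping occurrences all count; hits from different k-mers are pooled
#' (the painting track is per cluster, not per k-mer).
#'
#' @param profile a `kmer_profile` (or character vector of k-mers).
#' @param genome named character vector of chromosome sequences, a
#'   `synthetic_genome`, or a `Biostrings::DNAStringSet`.
#' @return list per chromosome of integer hit positions (0-based, sorted).
#' @export
map_kmers <- function(profile, genome) {
  kmers <- if (is.data.frame(profile)) profile$kmer else profile
  if (inherits(genome, "synthetic_genome")) genome <- genome$chromosomes
  subject <- if (inherits(genome, "DNAStringSet")) genome else
    Biostrings::DNAStringSet(toupper(genome))
  if (is.null(names(subject))) stop("genome sequences must be named")
  out <- stats::setNames(vector("list", length(subject)), names(subject))
  if (!length(kmers)) {
    out[] <- list(integer(0))
    return(out)
  }
  pats <- unique(unlist(lapply(kmers, function(m) {
    rc <- .revcomp_chr(m)
    if (rc == m) m else c(m, rc)
  })))
  pd <- Biostrings::PDict(pats)
  for (i in seq_along(subject)) {
    ml <- Biostrings::matchPDict(pd, subject[[i]])
    out[[i]] <- sort(unlist(lapply(ml, IRanges::start))) - 1L
  }
  out
}

#' Sliding windows over a chromosome
#'
#' Starts 0, step, 2*step, ... while start < length; ends truncated at the
#' chromosome end (bedtools-makewindows-compatible).
#'
#' @param length chromosome length in bp (> 0).
#' @param width window width (default 200 kb).
#' @param step window step (default 100 kb).
#' @return data.frame (start, end), 0-based half-open.
#' @export
make_windows <- function(length, width = 200000L, step = 100000L) {
  if (width <= 0 || step <= 0) stop("width and step must be > 0")
  stopifnot(length > 0)
  starts <- seq(0L, length - 1L, by = step)
  data.frame(start = starts, end = pmin(starts + width, length))
}

#' Count hit positions per window
#'
#' A hit is assigned to every window whose half-open interval contains its
#' start position (positions interior to the overlap zone of two windows
#' count in both).
#'
#' @param positions integer vector of 0-based hit positions.
#' @param windows data.frame from [make_windows()].
#' @return integer vector of counts, one per window.
#' @export
window_counts <- function(positions, windows) {
  vapply(seq_len(nrow(windows)), function(i)
    sum(positions >= windows$start[i] & positions < windows$end[i]),
    integer(1))
}

#' Min/max scale a track
#'
#' `(x - min) / (max - min)` over all supplied values (per cluster, pooled
#' across chromosomes); a constant track scales to all zeros.
#'
#' @param x numeric values.
#' @return values in [0, 1].
#' @export
scale_track <- function(x) {
  stopifnot(length(x) >= 1)
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Loess smoothing of a windowed track
#'
#' Local linear regression with tricube weights at each position: the
#' `ceiling(span * n)` nearest neighbours define the bandwidth, per
#' chromosome independently. Fewer than 3 points pass through unchanged.
#'
#' @param values numeric track values.
#' @param positions predictor (window midpoints); defaults to the index.
#' @param span neighbourhood fraction in (0, 1] (default 0.1, the visual
#'   scale of per-chromosome painting profiles).
#' @return smoothed values, same length.
#' @export
loess_smooth <- function(values, positions = seq_along(values), span = 0.1) {
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  n <- length(values)
  stopifnot(length(positions) == n)
  if (n < 3) return(values)
  q <- max(2L, min(n, as.integer(ceiling(span * n))))
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(positions - positions[i])
    dq <- sort(d, partial = q)[q]
    w <- numeric(n)
    if (dq == 0) {
      w[d == 0] <- 1
    } else {
      u <- d / dq
      w[u < 1] <- (1 - u[u < 1]^3)^3
      w[d == 0] <- 1
    }
    sw <- sum(w)
    xb <- sum(w * positions) / sw
    yb <- sum(w * values) / sw
    sxx <- sum(w * (positions - xb)^2)
    beta <- if (sxx > 0) sum(w * (positions - xb) * (values - yb)) / sxx else 0
    out[i] <- yb + beta * (positions[i] - xb)
  }
  out
}

#' Gene density per window
#'
#' Fraction of each window covered by the union of gene intervals
#' (overlapping genes are merged first), as bedtools coverage reports.
#'
#' @param genes data.frame (start, end), 0-based half-open, one chromosome.
#' @param windows data.frame from [make_windows()].
#' @param chrom_length chromosome length; intervals beyond it error.
#' @return numeric fractions in [0, 1].
#' @export
gene_density <- function(genes, windows, chrom_length = NULL) {
  stopifnot(all(genes$end > genes$start))
  if (!is.null(chrom_length) && nrow(genes) && any(genes$end > chrom_length))
    stop("gene interval beyond chromosome end")
  out <- numeric(nrow(windows))
  if (!nrow(genes)) return(out)
  merged <- IRanges::reduce(IRanges::IRanges(genes$start + 1L, genes$end))
  win <- IRanges::IRanges(windows$start + 1L, windows$end)
  ov <- IRanges::findOverlaps(win, merged)
  if (length(ov)) {
    w <- IRanges::width(IRanges::pintersect(win[S4Vectors::queryHits(ov)],
                                            merged[S4Vectors::subjectHits(ov)]))
    agg <- tapply(w, S4Vectors::queryHits(ov), sum)
    ix <- as.integer(names(agg))
    out[ix] <- as.numeric(agg) / (windows$end[ix] - windows$start[ix])
  }
  out
}

#' Correlate a k-mer track with gene density
#'
#' Pearson r with a two-sided p via the t transform, and Spearman rho on
#' average ranks through the same machinery. Zero variance in either track
#' makes the correlation undefined and is reported as such.
#'
#' @param kmer_track,gene_track equal-length numeric tracks over the same
#'   windows (pooled genome-wide; n >= 3).
#' @return data.frame (pearson_r, pearson_p, spearman_rho, spearman_p,
#'   n_windows, defined).
#' @export
correlate_tracks <- function(kmer_track, gene_track) {
  n <- length(kmer_track)
  stopifnot(length(gene_track) == n, n >= 3)
  undef <- data.frame(pearson_r = NA_real_, pearson_p = NA_real_,
                      spearman_rho = NA_real_, spearman_p = NA_real_,
                      n_windows = n, defined = FALSE)
  if (stats::sd(kmer_track) == 0 || stats::sd(gene_track) == 0) return(undef)
  pcor <- function(x, y) {
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    r <- max(-1, min(1, r))
    if (abs(r) == 1) return(c(r, 0))
    t <- r * sqrt((n - 2) / (1 - r^2))
    c(r, 2 * stats::pt(-abs(t), n - 2))
  }
  pe <- pcor(kmer_track, gene_track)
  sp <- pcor(rank(kmer_track), rank(gene_track))
  data.frame(pearson_r = pe[1], pearson_p = pe[2],
             spearman_rho = sp[1], spearman_p = sp[2],
             n_windows = n, defined = TRUE)
}

#' Paint a repeat cluster onto a genome
#'
#' The full in silico chromosome painting for one cluster: top k-mers from
#' the cluster's reads, exact both-strand mapping to the genome, windowed
#' hit counts, per-cluster genome-wide min/max scaling, per-chromosome
#' loess smoothing, gene-density tracks over the same windows, and the
#' pooled genome-wide correlation between (scaled, unsmoothed) k-mer
#' density and gene density.
#'
#' @param reads cluster reads (`ReadSet` or character sequences).
#' @param genome named character vector / `synthetic_genome`.
#' @param genes data.frame (chrom, start, end) of gene intervals.
#' @param k,top k-mer length and number of top k-mers.
#' @param width,step window geometry in bp.
#' @param span loess span.
#' @return list(track = data.frame(chrom, start, end, raw, scaled, smoothed,
#'   gene_density), correlation = data.frame from [correlate_tracks()],
#'   profile = the `kmer_profile`).
#' @export
paint_cluster <- function(reads, genome, genes, k = 12L, top = 100L,
                          width = 200000L, step = 100000L, span = 0.1) {
  if (inherits(genome, "synthetic_genome")) {
    if (missing(genes)) genes <- genome$genes
    genome <- genome$chromosomes
  }
  profile <- top_kmers(reads, k = k, top = top)
  hits <- map_kmers(profile, genome)
  per_chrom <- lapply(names(genome), function(ch) {
    win <- make_windows(nchar(genome[[ch]]), width, step)
    raw <- window_counts(hits[[ch]], win)
    gd <- gene_density(genes[genes$chrom == ch, , drop = FALSE], win,
                       nchar(genome[[ch]]))
    data.frame(chrom = ch, start = win$start, end = win$end, raw = raw,
               gene_density = gd, stringsAsFactors = FALSE)
  })
  track <- do.call(rbind, per_chrom)
  track$scaled <- scale_track(track$raw)
  # scaling is genome-wide per cluster; smoothing is per chromosome
  track$smoothed <- NA_real_
  for (ch in unique(track$chrom)) {
    ix <- track$chrom == ch
    track$smoothed[ix] <- loess_smooth(track$scaled[ix],
                                       (track$start[ix] + track$end[ix]) / 2,
                                       span)
  }
  corr <- correlate_tracks(track$scaled, track$gene_density)
  list(track = track, correlation = corr, profile = profile)
}
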