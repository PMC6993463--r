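# shared fixtures and independent oracles used across test files

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# small three-family world used by several end-to-end tests: short monomers
# keep each family's read-overlap graph dense enough to be one community
demo_specs <- function() {
  list(
    repeat_family_spec("GypsyA", "Gypsy-like", monomer_length = 500L,
                       target_copy_number = 150L,
                       intra_family_divergence = 0.05, placement_bias = -1),
    repeat_family_spec("CopiaB", "Copia-like", monomer_length = 450L,
                       target_copy_number = 120L,
                       intra_family_divergence = 0.05, placement_bias = 1),
    repeat_family_spec("TandemC", "tandem", monomer_length = 180L,
                       target_copy_number = 350L,
                       intra_family_divergence = 0.02, placement_bias = 0))
}

# brute-force weighted modularity from the adjacency matrix:
# Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) [c_i == c_j]
modularity_bf <- function(adj, membership) {
  m2 <- sum(adj)            # 2m for an undirected graph stored symmetrically
  if (m2 == 0) return(0)
  k <- rowSums(adj)
  same <- outer(membership, membership, "==")
  sum((adj - outer(k, k) / m2) * same) / m2
}

# all set partitions of 1..n as membership vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxblock) {
    i <- length(prefix) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (b in seq_len(maxblock + 1L))
      recurse(c(prefix, b), max(maxblock, b))
  }
  recurse(integer(0), 0L)
  out
}

# adjacency matrix of an igraph with weights
adj_of <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, attr = if ("weight" %in%
    igraph::edge_attr_names(g)) "weight" else NULL, sparse = FALSE))
}

# independent per-pair scorer oracle: returns best raw score via score_pair
brute_force_hits <- function(reads, params) {
  n <- nrow(reads)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      h <- score_pair(reads$sequence[i], reads$sequence[j], params,
                      id_a = reads$read_id[i], id_b = reads$read_id[j])
      if (!is.null(h)) rows[[length(rows) + 1L]] <- h
    }
  }
  if (!length(rows))
    return(data.frame(read_a = character(0), read_b = character(0),
                      bitscore = numeric(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$read_a, out$read_b), ]
  rownames(out) <- NULL
  out
}

# naive canonical k-mer counter (string ops only)
count_kmers_bf <- function(seqs, k) {
  counts <- new.env(parent = emptyenv())
  for (s in seqs) {
    if (nchar(s) < k) next
    for (i in seq_len(nchar(s) - k + 1)) {
      km <- substr(s, i, i + k - 1)
      if (grepl("[^ACGT]", km)) next
      canon <- min(km, revcomp(km))
      cur <- if (is.null(counts[[canon]])) 0L else counts[[canon]]
      counts[[canon]] <- cur + 1L
    }
  }
  nm <- ls(counts)
  stats::setNames(vapply(nm, function(x) counts[[x]], integer(1)), nm)
}

# mean realized gene density in a +/- flank around interval midpoints
density_at <- function(intervals, genes, flank = 25000L) {
  vapply(seq_len(nrow(intervals)), function(i) {
    mid <- (intervals$start[i] + intervals$end[i]) / 2
    lo <- max(0, mid - flank); hi <- mid + flank
    g <- genes[genes$chrom == intervals$chrom[i], , drop = FALSE]
    if (!nrow(g)) return(0)
    ov <- pmax(0, pmin(g$end, hi) - pmax(g$start, lo))
    sum(ov) / (hi - lo)
  }, numeric(1))
}
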