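#' Build the weighted read-similarity graph
#'
#' Vertices are reads, edges are similarity hits weighted by bit score.
#' Edges below `min_bits` are excluded; the threshold is inclusive (a weight
#' of exactly `min_bits` is kept). Isolated reads (no retained edge) are not
#' added as vertices: they are reported downstream as unclustered rather
#' than forced into clusters.
#'
#' @param hits data.frame (read_a, read_b, bitscore), canonical and
#'   deduplicated, e.g. from [all_vs_all()] or [import_hits()].
#' @param min_bits edge-weight threshold in bits (default 100).
#' @param read_labels optional data.frame (read_id, individual, population)
#'   attached as vertex attributes.
#' @return an undirected, simple igraph object with edge attribute `weight`.
#' @export
build_graph <- function(hits, min_bits = 100, read_labels = NULL) {
  keep <- hits$bitscore >= min_bits
  h <- hits[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = h$read_a, to = h$read_b, weight = h$bitscore),
    directed = FALSE)
  if (igraph::any_multiple(g) || any(igraph::which_loop(g)))
    stop("hits must be canonical and deduplicated (multi-edge or self-hit found)")
  if (!is.null(read_labels)) {
    ix <- match(igraph::V(g)$name, read_labels$read_id)
    if (anyNA(ix)) stop("read_labels missing for: ",
                        paste(head(igraph::V(g)$name[is.na(ix)]), collapse = ", "))
    igraph::V(g)$individual <- read_labels$individual[ix]
    igraph::V(g)$population <- read_labels$population[ix]
  }
  g
}

#' Mean degree of a graph
#'
#' `2 |E| / |V|`, the summary reported for the read-similarity graph.
#'
#' @param n_vertices,n_edges counts, or pass an igraph as `n_vertices`.
#' @return mean degree.
#' @export
mean_degree <- function(n_vertices, n_edges = NULL) {
  if (inherits(n_vertices, "igraph")) {
    g <- n_vertices
    n_edges <- igraph::ecount(g)
    n_vertices <- igraph::vcount(g)
  }
  if (n_vertices == 0) return(0)
  2 * n_edges / n_vertices
}

#' Reduce a graph to its largest connected component
#'
#' Ties on component size are broken toward the component containing the
#' lexicographically smallest read id.
#'
#' @param graph an igraph object.
#' @return the induced subgraph on the largest component.
#' @export
largest_component <- function(graph) {
  if (igraph::vcount(graph) == 0) return(graph)
  comp <- igraph::components(graph)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    firsts <- vapply(best, function(k)
      min(igraph::V(graph)$name[comp$membership == k]), character(1))
    best <- best[order(firsts)][1]
  }
  igraph::induced_subgraph(graph, which(comp$membership == best))
}

#' Detect repeat clusters by greedy modularity maximization
#'
#' Clauset-Newman-Moore agglomeration (igraph's `cluster_fast_greedy`) on
#' the edge-weighted graph, cut at the merge step whose partition maximizes
#' weighted modularity (the modularity along the full merge trajectory is
#' recomputed here, so the returned partition is the argmax even when a
#' zero-gain merge is involved). Clusters are renumbered by descending size,
#' ties broken by the smallest member read id; ids are `cluster_0`,
#' `cluster_1`, ... following the rank convention.
#'
#' @param graph an igraph object (typically from [largest_component()]).
#' @param weighted use edge weights (default TRUE).
#' @return a `cluster_assignment` data.frame (read_id, cluster_id) with
#'   attribute `modularity`.
#' @export
detect_communities <- function(graph, weighted = TRUE) {
  if (igraph::vcount(graph) == 0) {
    out <- data.frame(read_id = character(0), cluster_id = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("cluster_assignment", "data.frame")
    return(out)
  }
  w <- if (weighted) igraph::E(graph)$weight else NULL
  if (igraph::vcount(graph) == 1L) {
    memb <- stats::setNames(1L, igraph::V(graph)$name)
    mod <- 0
  } else {
    cfg <- igraph::cluster_fast_greedy(graph, weights = w)
    # cut the dendrogram at the argmax of the recorded (weighted) modularity
    # trajectory; igraph's own membership() can miss a zero-gain merge
    best <- which.max(cfg$modularity) - 1L
    memb <- stats::setNames(igraph::cut_at(cfg, steps = best),
                            igraph::V(graph)$name)
    mod <- cfg$modularity[best + 1L]
  }
  sizes <- table(memb)
  first_id <- tapply(names(memb), memb, min)
  ord <- order(-as.integer(sizes[names(first_id)]), first_id)
  rank_of <- stats::setNames(seq_along(ord) - 1L, names(first_id)[ord])
  out <- data.frame(read_id = names(memb),
                    cluster_id = sprintf("cluster_%d", rank_of[as.character(memb)]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$cluster_id, out$read_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "modularity") <- mod
  class(out) <- c("cluster_assignment", "data.frame")
  out
}

#' Quantify per-individual cluster abundance
#'
#' Counts reads contributed by each individual to each cluster. The grand
#' total equals the number of clustered reads.
#'
#' @param assignment a `cluster_assignment` from [detect_communities()].
#' @param read_labels data.frame (read_id, individual, population).
#' @return an integer matrix individuals x clusters, with attribute
#'   `populations` (population per row).
#' @export
abundance_matrix <- function(assignment, read_labels) {
  ix <- match(assignment$read_id, read_labels$read_id)
  if (anyNA(ix))
    stop("unlabeled reads: ",
         paste(head(assignment$read_id[is.na(ix)]), collapse = ", "))
  ind <- read_labels$individual[ix]
  clusters <- sort(unique(assignment$cluster_id))
  inds <- sort(unique(read_labels$individual))
  tab <- table(factor(ind, levels = inds),
               factor(assignment$cluster_id, levels = clusters))
  mat <- matrix(as.integer(tab), nrow = length(inds))
  dimnames(mat) <- list(inds, clusters)
  pops <- read_labels$population[match(inds, read_labels$individual)]
  attr(mat, "populations") <- stats::setNames(pops, inds)
  mat
}

#' Collapse the read graph to its cluster meta-graph
#'
#' Each cluster becomes one vertex; the edge between clusters i and j is
#' weighted by the sum of all read-graph edge weights crossing the two
#' clusters. Intra-cluster weight is kept as a vertex attribute so that
#' intra + inter weight equals the total edge weight of the read graph.
#'
#' @param graph the read-similarity igraph.
#' @param assignment a `cluster_assignment` covering the graph's vertices.
#' @return an igraph with vertex attributes `size`, `intra_weight` and edge
#'   attribute `weight`.
#' @export
cluster_metagraph <- function(graph, assignment) {
  memb <- stats::setNames(assignment$cluster_id, assignment$read_id)
  vnames <- igraph::V(graph)$name
  if (anyNA(memb[vnames]))
    stop("assignment does not cover all graph vertices")
  el <- igraph::as_data_frame(graph, what = "edges")
  ca <- memb[el$from]; cb <- memb[el$to]
  intra <- tapply(el$weight[ca == cb], ca[ca == cb], sum)
  cross <- ca != cb
  clusters <- sort(unique(memb[vnames]))
  if (any(cross)) {
    lo <- pmin(ca[cross], cb[cross]); hi <- pmax(ca[cross], cb[cross])
    key <- paste(lo, hi, sep = "\r")
    wsum <- tapply(el$weight[cross], key, sum)
    pair <- strsplit(names(wsum), "\r", fixed = TRUE)
    med <- data.frame(from = vapply(pair, `[[`, character(1), 1L),
                      to = vapply(pair, `[[`, character(1), 2L),
                      weight = as.numeric(wsum), stringsAsFactors = FALSE)
  } else {
    med <- data.frame(from = character(0), to = character(0),
                      weight = numeric(0))
  }
  mg <- igraph::graph_from_data_frame(med, directed = FALSE,
                                      vertices = data.frame(name = clusters))
  sz <- table(memb[vnames])
  igraph::V(mg)$size <- as.integer(sz[igraph::V(mg)$name])
  iw <- rep(0, length(clusters)); names(iw) <- clusters
  if (length(intra)) iw[names(intra)] <- intra
  igraph::V(mg)$intra_weight <- as.numeric(iw[igraph::V(mg)$name])
  mg
}

#' Force-directed 2D layout of one cluster's sub-graph
#'
#' Fruchterman-Reingold iteration on the induced sub-graph: attractive force
#' d^2/k on edges, repulsive k^2/d between all vertex pairs, displacement
#' capped by a linearly cooling temperature; k = sqrt(area / |V|) with unit
#' area, initial positions uniform in the unit square from the seed.
#' Coordinates are for visualization and property tests only.
#'
#' @param graph the read-similarity igraph.
#' @param assignment a `cluster_assignment`.
#' @param cluster_id which cluster to lay out.
#' @param seed integer seed.
#' @param iterations number of cooling steps.
#' @return data.frame (read_id, x, y) plus population if present.
#' @export
layout_cluster <- function(graph, assignment, cluster_id, seed = 1L,
                           iterations = 500L) {
  ids <- assignment$read_id[assignment$cluster_id == cluster_id]
  if (!length(ids)) stop("unknown cluster id: ", cluster_id)
  sub <- igraph::induced_subgraph(graph, ids)
  n <- igraph::vcount(sub)
  nm <- igraph::V(sub)$name
  if (n == 1L) {
    out <- data.frame(read_id = nm, x = 0, y = 0, stringsAsFactors = FALSE)
  } else {
    el <- igraph::as_edgelist(sub, names = FALSE)
    k <- sqrt(1 / n)
    pos <- with_seed(seed, matrix(runif(2 * n), ncol = 2))
    temp <- 0.1
    dt <- temp / iterations
    for (it in seq_len(iterations)) {
      dx <- outer(pos[, 1], pos[, 1], "-")
      dy <- outer(pos[, 2], pos[, 2], "-")
      d <- sqrt(dx^2 + dy^2)
      d[d < 1e-9] <- 1e-9
      # repulsion k^2/d along the unit separation vector
      f <- k^2 / d^2
      diag(f) <- 0
      disp <- cbind(rowSums(f * dx), rowSums(f * dy))
      # attraction on edges: d^2 / k toward the neighbour
      vx <- pos[el[, 1], 1] - pos[el[, 2], 1]
      vy <- pos[el[, 1], 2] - pos[el[, 2], 2]
      dd <- sqrt(vx^2 + vy^2); dd[dd < 1e-9] <- 1e-9
      fa <- dd^2 / k
      ax <- fa * vx / dd; ay <- fa * vy / dd
      for (e in seq_len(nrow(el))) {
        disp[el[e, 1], ] <- disp[el[e, 1], ] - c(ax[e], ay[e])
        disp[el[e, 2], ] <- disp[el[e, 2], ] + c(ax[e], ay[e])
      }
      dl <- sqrt(rowSums(disp^2)); dl[dl < 1e-9] <- 1e-9
      step <- pmin(dl, temp)
      pos <- pos + disp / dl * step
      temp <- max(temp - dt, 1e-4)
    }
    out <- data.frame(read_id = nm, x = pos[, 1], y = pos[, 2],
                      stringsAsFactors = FALSE)
  }
  if (!is.null(igraph::vertex_attr(graph, "population"))) {
    ix <- match(out$read_id, igraph::V(graph)$name)
    out$population <- igraph::V(graph)$population[ix]
  }
  out
}
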