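#' Best library hit per read
#'
#' Scores each read against every library record with the internal
#' seed-and-extend scorer and keeps the record with the maximal bit score at
#' or above `min_bits` (default 50: annotation tolerates weaker hits than
#' graph edges). Ties go to the lexicographically smallest record name.
#'
#' @param reads a `ReadSet` data.frame (read_id, sequence).
#' @param library a `repeat_library` (name, class_label, sequence).
#' @param min_bits minimum bit score to accept a hit.
#' @param params a [scoring_params()] (its `min_report_bits` is overridden
#'   by `min_bits`).
#' @return character vector of library record names, NA where no hit, named
#'   by read id.
#' @export
annotate_reads <- function(reads, library, min_bits = 50,
                           params = scoring_params()) {
  if (!nrow(library)) stop("empty library")
  lib <- library[order(library$name), , drop = FALSE]
  out <- rep(NA_character_, nrow(reads))
  for (i in seq_len(nrow(reads))) {
    best_bits <- -Inf; best_lab <- NA_character_
    for (j in seq_len(nrow(lib))) {
      raw <- .score_pair_raw(reads$sequence[i], lib$sequence[j],
                             params$seed_length, params$match,
                             params$mismatch, params$xdrop)
      if (raw < 0) next
      bits <- bitscore(raw, params)
      if (bits >= min_bits && bits > best_bits) { # ties keep the earlier
        best_bits <- bits                         # (lexicographically
        best_lab <- lib$name[j]                   # smaller) record name
      }
    }
    out[i] <- best_lab
  }
  stats::setNames(out, reads$read_id)
}

#' Annotate one cluster from its per-read hits
#'
#' Majority vote over hit reads only (reads without a library hit do not
#' dilute the mode). Zero hit reads yields "unknown"; a tied vote keeps the
#' lexicographically smaller label and sets `tie`.
#'
#' @param read_hits character vector of per-read labels (NA = no hit), as
#'   returned by [annotate_reads()].
#' @param library a `repeat_library` providing `class_label` per record.
#' @return one-row data.frame (best_label, class_label, n_hit_reads,
#'   n_reads, tie).
#' @export
annotate_cluster <- function(read_hits, library = NULL) {
  n_reads <- length(read_hits)
  hits <- read_hits[!is.na(read_hits)]
  if (!length(hits)) {
    return(data.frame(best_label = "unknown", class_label = "unknown",
                      n_hit_reads = 0L, n_reads = n_reads, tie = FALSE,
                      stringsAsFactors = FALSE))
  }
  tab <- table(hits)
  top <- names(tab)[tab == max(tab)]
  best <- sort(top)[1]
  cls <- if (!is.null(library) && best %in% library$name)
    library$class_label[library$name == best] else "unknown"
  data.frame(best_label = best, class_label = cls,
             n_hit_reads = length(hits), n_reads = n_reads,
             tie = length(top) > 1, stringsAsFactors = FALSE)
}

#' Annotate every cluster of an assignment
#'
#' @param reads a `ReadSet` covering the assigned reads.
#' @param assignment a `cluster_assignment`.
#' @param library a `repeat_library`.
#' @param min_bits minimum per-read hit bit score.
#' @param params a [scoring_params()].
#' @return an annotation table: one row per cluster (cluster_id, best_label,
#'   class_label, n_hit_reads, n_reads, tie).
#' @export
annotate_clusters <- function(reads, assignment, library, min_bits = 50,
                              params = scoring_params()) {
  clusters <- sort(unique(assignment$cluster_id))
  rows <- lapply(clusters, function(cl) {
    ids <- assignment$read_id[assignment$cluster_id == cl]
    sub <- reads[match(ids, reads$read_id), , drop = FALSE]
    hits <- annotate_reads(sub, library, min_bits, params)
    cbind(data.frame(cluster_id = cl, stringsAsFactors = FALSE),
          annotate_cluster(hits, library))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate cluster abundances by annotation class
#'
#' Sums cluster columns of an abundance matrix grouped by their annotation
#' class, preserving each individual's total read count.
#'
#' @param abundance individuals x clusters matrix from [abundance_matrix()].
#' @param annotations annotation table from [annotate_clusters()].
#' @param by group by "class_label" (default) or "best_label".
#' @return individuals x classes matrix, `populations` attribute preserved.
#' @export
aggregate_by_annotation <- function(abundance, annotations,
                                    by = c("class_label", "best_label")) {
  by <- match.arg(by)
  missing <- setdiff(colnames(abundance), annotations$cluster_id)
  if (length(missing))
    stop("clusters missing from annotations: ", paste(missing, collapse = ", "))
  grp <- annotations[[by]][match(colnames(abundance), annotations$cluster_id)]
  classes <- sort(unique(grp))
  out <- vapply(classes, function(cl)
    rowSums(abundance[, grp == cl, drop = FALSE]), numeric(nrow(abundance)))
  out <- matrix(out, nrow = nrow(abundance),
                dimnames = list(rownames(abundance), classes))
  attr(out, "populations") <- attr(abundance, "populations")
  out
}
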