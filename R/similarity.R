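#' Scoring parameters for the internal read scorer
#'
#' Megablast-like defaults: match +1, mismatch -2, exact seeds of 16 bp,
#' ungapped X-drop extension, and Karlin-Altschul conversion of raw scores
#' to bits with lambda = 1.28, K = 0.46. `min_report_bits = 100` keeps the
#' similarity stage and the graph stage on the same reporting threshold.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score (< 0).
#' @param seed_length exact-seed length in bp (>= 8).
#' @param lambda Karlin-Altschul lambda (> 0).
#' @param k_const Karlin-Altschul K in (0, 1).
#' @param xdrop stop extension when the running score falls this far below
#'   the best.
#' @param min_report_bits report a hit only at or above this bit score.
#' @return a `scoring_params` list.
#' @export
scoring_params <- function(match = 1L, mismatch = -2L, seed_length = 16L,
                           lambda = 1.28, k_const = 0.46, xdrop = 20L,
                           min_report_bits = 100) {
  stopifnot(match > 0, mismatch < 0, seed_length >= 8L,
            lambda > 0, k_const > 0, k_const < 1, xdrop > 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 seed_length = as.integer(seed_length), lambda = lambda,
                 k_const = k_const, xdrop = as.integer(xdrop),
                 min_report_bits = min_report_bits),
            class = "scoring_params")
}

#' Convert a raw alignment score to bits
#'
#' Karlin-Altschul normalization: `bits = (lambda * raw - ln K) / ln 2`.
#' Strictly increasing in the raw score.
#'
#' @param raw_score raw ungapped alignment score (>= 0).
#' @param params a [scoring_params()].
#' @return bit score(s).
#' @export
bitscore <- function(raw_score, params = scoring_params()) {
  stopifnot(all(raw_score >= 0))
  (params$lambda * raw_score - log(params$k_const)) / log(2)
}

# smallest raw score whose bit score reaches `bits`
.min_raw_for_bits <- function(bits, params) {
  as.integer(ceiling((bits * log(2) + log(params$k_const)) / params$lambda))
}

#' Score one read pair
#'
#' Finds exact shared seeds on either strand, runs ungapped X-drop extension
#' around each anchor, converts the best raw score to bits, and reports a
#' hit only at `min_report_bits` or above. Symmetric in its arguments.
#'
#' @param seq_a,seq_b sequences over A/C/G/T/N (N never matches or seeds).
#' @param params a [scoring_params()].
#' @param id_a,id_b read ids attached to the returned hit.
#' @return one-row data.frame (read_a, read_b, bitscore) in canonical order,
#'   or NULL when no hit reaches the threshold.
#' @export
score_pair <- function(seq_a, seq_b, params = scoring_params(),
                       id_a = "a", id_b = "b") {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  raw <- .score_pair_raw(seq_a, seq_b, params$seed_length, params$match,
                         params$mismatch, params$xdrop)
  if (raw < 0) return(NULL)
  bits <- bitscore(raw, params)
  if (bits < params$min_report_bits) return(NULL)
  ids <- sort(c(id_a, id_b))
  data.frame(read_a = ids[1], read_b = ids[2], bitscore = bits,
             stringsAsFactors = FALSE)
}

#' All-vs-all similarity over a pooled read set
#'
#' Candidate pairs come from a shared canonical-seed index; pairs sharing no
#' seed cannot reach the threshold and are skipped. Every candidate is then
#' scored with the same routine as [score_pair()], so the hit set equals
#' brute-force scoring of every unordered pair. Hits are canonical
#' (lexicographically smaller id first), deduplicated, and self-hit free.
#'
#' @param reads a `ReadSet` data.frame with `read_id` and `sequence`.
#' @param params a [scoring_params()].
#' @return data.frame (read_a, read_b, bitscore).
#' @export
all_vs_all <- function(reads, params = scoring_params()) {
  empty <- data.frame(read_a = character(0), read_b = character(0),
                      bitscore = numeric(0), stringsAsFactors = FALSE)
  if (nrow(reads) < 2) return(empty)
  if (anyDuplicated(reads$read_id)) stop("duplicate read ids")
  min_raw <- .min_raw_for_bits(params$min_report_bits, params)
  hits <- .all_vs_all_raw(reads$sequence, params$seed_length, params$match,
                          params$mismatch, params$xdrop, min_raw)
  if (!nrow(hits)) return(empty)
  a <- reads$read_id[hits$i]
  b <- reads$read_id[hits$j]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(read_a = a, read_b = b,
                    bitscore = bitscore(hits$raw, params),
                    stringsAsFactors = FALSE)
  out <- out[out$bitscore >= params$min_report_bits, , drop = FALSE]
  out <- out[order(out$read_a, out$read_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Import externally computed hits (BLAST tabular)
#'
#' Reads a BLAST outfmt-6-style TSV (qseqid, sseqid, ..., bitscore in column
#' 12), drops self-hits, canonicalizes pair order, and keeps the maximum
#' bit score per pair. Lets real megablast output replace the internal
#' scorer.
#'
#' @param path TSV file path.
#' @return data.frame (read_a, read_b, bitscore).
#' @export
import_hits <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(read_a = character(0), read_b = character(0),
                      bitscore = numeric(0), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- which(nfield < 12L)
  if (length(bad))
    stop("malformed hit row at line ", bad[1], ": expected >= 12 fields, got ",
         nfield[bad[1]])
  a <- vapply(parts, `[[`, character(1), 1L)
  b <- vapply(parts, `[[`, character(1), 2L)
  bits <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 12L)))
  if (anyNA(bits))
    stop("malformed bitscore at line ", which(is.na(bits))[1])
  keep <- a != b
  a <- a[keep]; b <- b[keep]; bits <- bits[keep]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  key <- paste(a, b, sep = "\r")
  best <- tapply(bits, key, max)
  ids <- strsplit(names(best), "\r", fixed = TRUE)
  out <- data.frame(read_a = vapply(ids, `[[`, character(1), 1L),
                    read_b = vapply(ids, `[[`, character(1), 2L),
                    bitscore = as.numeric(best), stringsAsFactors = FALSE)
  out <- out[order(out$read_a, out$read_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write hits as BLAST-style tabular TSV
#'
#' Emits the 12-column outfmt-6 layout with placeholder alignment columns
#' (only ids and the bit score are meaningful for internally computed hits).
#'
#' @param hits data.frame (read_a, read_b, bitscore).
#' @param path output path.
#' @export
write_hits <- function(hits, path) {
  tab <- data.frame(hits$read_a, hits$read_b, 100.0, 0L, 0L, 0L, 0L, 0L, 0L,
                    0L, 0.0, hits$bitscore)
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
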