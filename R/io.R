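#' Read and write FASTA
#'
#' Thin wrappers over Biostrings keeping names verbatim.
#'
#' @param path file path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a read set as labelled FASTA
#'
#' Headers follow the `<individual>|<population>|<read_id>` microformat so
#' pooled reads keep their provenance.
#'
#' @param reads a `ReadSet` data.frame.
#' @param path output path.
#' @export
write_reads_fasta <- function(reads, path) {
  seqs <- stats::setNames(
    reads$sequence,
    paste(reads$individual, reads$population, reads$read_id, sep = "|"))
  write_fasta(seqs, path)
}

#' Read labelled reads from FASTA
#'
#' @param path FASTA with `<individual>|<population>|<read_id>` headers.
#' @return a `ReadSet` data.frame (read_id, individual, population,
#'   sequence).
#' @export
read_reads_fasta <- function(path) {
  seqs <- read_fasta(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("malformed read header (expect individual|population|read_id) at record ",
         bad[1], " in ", path)
  out <- data.frame(read_id = vapply(parts, `[[`, character(1), 3L),
                    individual = vapply(parts, `[[`, character(1), 1L),
                    population = vapply(parts, `[[`, character(1), 2L),
                    sequence = unname(seqs), stringsAsFactors = FALSE)
  class(out) <- c("ReadSet", "data.frame")
  out
}

#' Write / read a repeat library FASTA
#'
#' Headers carry `family=` and `class=` tags:
#' `>GypsyA family=GypsyA class=Gypsy-like`.
#'
#' @param library a `repeat_library`.
#' @param path file path.
#' @export
write_library_fasta <- function(library, path) {
  seqs <- stats::setNames(
    library$sequence,
    sprintf("%s family=%s class=%s", library$name, library$name,
            library$class_label))
  write_fasta(seqs, path)
}

#' @rdname write_library_fasta
#' @export
read_library_fasta <- function(path) {
  seqs <- read_fasta(path)
  grab <- function(hdr, tag) {
    m <- regmatches(hdr, regexpr(paste0(tag, "=\\S+"), hdr))
    if (length(m)) sub(paste0(tag, "="), "", m) else NA_character_
  }
  name <- vapply(names(seqs), function(h) {
    fam <- grab(h, "family")
    if (is.na(fam)) strsplit(h, "\\s+")[[1]][1] else fam
  }, character(1))
  cls <- vapply(names(seqs), grab, character(1), tag = "class")
  cls[is.na(cls)] <- "other"
  out <- data.frame(name = unname(name), class_label = unname(cls),
                    monomer_length = unname(nchar(seqs)),
                    target_copy_number = NA_integer_,
                    intra_family_divergence = NA_real_,
                    placement_bias = NA_real_,
                    sequence = unname(seqs), stringsAsFactors = FALSE)
  class(out) <- c("repeat_library", "data.frame")
  out
}

#' Read / write BED intervals (0-based half-open)
#'
#' @param path BED file (3+ columns).
#' @return data.frame (chrom, start, end[, name, score, strand]).
#' @export
read_bed <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  comment.char = "#")
  if (ncol(x) < 3) stop("BED needs >= 3 columns: ", path)
  names(x)[1:3] <- c("chrom", "start", "end")
  if (ncol(x) >= 4) names(x)[4] <- "name"
  if (ncol(x) >= 5) names(x)[5] <- "score"
  if (ncol(x) >= 6) names(x)[6] <- "strand"
  bad <- which(x$start >= x$end)
  if (length(bad))
    stop("BED record with start >= end at line ", bad[1], " in ", path)
  x
}

#' @rdname read_bed
#' @param intervals data.frame with chrom, start, end and optional name,
#'   score, strand.
#' @export
write_bed <- function(intervals, path) {
  df <- data.frame(intervals$chrom, intervals$start, intervals$end,
                   if (!is.null(intervals$name)) intervals$name else ".",
                   if (!is.null(intervals$score)) intervals$score else 0L,
                   if (!is.null(intervals$strand)) intervals$strand else ".")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read GFF3 features as 0-based half-open intervals
#'
#' GFF3 is 1-based closed; `[start, end]` becomes `[start - 1, end)`.
#'
#' @param path GFF3 file.
#' @param feature keep only this feature type (e.g. "gene"); NULL = all.
#' @return data.frame (chrom, start, end, feature, strand).
#' @export
read_gff3 <- function(path, feature = "gene") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 8L)
  if (length(bad)) stop("malformed GFF3 row at line ", bad[1], " in ", path)
  df <- data.frame(chrom = vapply(parts, `[[`, character(1), 1L),
                   feature = vapply(parts, `[[`, character(1), 3L),
                   start = as.integer(vapply(parts, `[[`, character(1), 4L)) - 1L,
                   end = as.integer(vapply(parts, `[[`, character(1), 5L)),
                   strand = vapply(parts, `[[`, character(1), 7L),
                   stringsAsFactors = FALSE)
  if (!is.null(feature)) df <- df[df$feature %in% feature, , drop = FALSE]
  rownames(df) <- NULL
  df[, c("chrom", "start", "end", "feature", "strand")]
}

#' Read / write a numeric TSV matrix (row names in the first column)
#'
#' @param path TSV file.
#' @return numeric matrix.
#' @export
read_tsv_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_tsv_matrix
#' @param mat matrix with dimnames.
#' @param id_col header for the row-name column.
#' @export
write_tsv_matrix <- function(mat, path, id_col = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Minimal VCF reader for biallelic SNP genotypes
#'
#' Parses biallelic SNP records and the GT field only (other FORMAT fields
#' ignored), returning allele-pair calls compatible with
#' [encode_genotypes()]. Missing genotypes become "NN"; multiallelic or
#' indel records are dropped.
#'
#' @param path VCF file (uncompressed).
#' @return individuals x markers character matrix of calls.
#' @export
read_vcf_minimal <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("no #CHROM header line in ", path)
  cols <- strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10) stop("VCF has no sample columns: ", path)
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr[1])]
  body <- body[nzchar(body)]
  calls <- list()
  ids <- character(0)
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    ref <- f[4]; alt <- f[5]
    if (nchar(ref) != 1 || nchar(alt) != 1 || alt == ".") next
    gt_ix <- match("GT", strsplit(f[9], ":", fixed = TRUE)[[1]])
    if (is.na(gt_ix)) next
    al <- c(ref, alt)
    cal <- vapply(f[-(1:9)], function(s) {
      gt <- strsplit(s, ":", fixed = TRUE)[[1]][gt_ix]
      a <- strsplit(gt, "[/|]")[[1]]
      if (length(a) != 2 || any(a == ".")) return("NN")
      paste0(al[as.integer(a[1]) + 1L], al[as.integer(a[2]) + 1L])
    }, character(1))
    calls[[length(calls) + 1L]] <- cal
    ids <- c(ids, if (f[3] != ".") f[3] else paste0(f[1], ":", f[2]))
  }
  if (!length(calls))
    return(matrix(character(0), nrow = length(samples), ncol = 0,
                  dimnames = list(samples, NULL)))
  m <- do.call(cbind, calls)
  dimnames(m) <- list(samples, ids)
  m
}
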