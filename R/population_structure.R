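#' Min/max scale an abundance matrix column-wise
#'
#' Per cluster: `(x - min) / (max - min)` so every cluster's values span
#' [0, 1]; constant clusters scale to zeros. Idempotent.
#'
#' @param abundance individuals x clusters numeric matrix (>= 2 rows).
#' @return scaled matrix, `populations` attribute preserved.
#' @export
minmax_scale_matrix <- function(abundance) {
  stopifnot(nrow(abundance) >= 2)
  out <- apply(abundance, 2, scale_track)
  dimnames(out) <- dimnames(abundance)
  attr(out, "populations") <- attr(abundance, "populations")
  out
}

#' Encode allele-pair genotype calls for PCA
#'
#' Per biallelic marker the major allele is the one with the higher count
#' across homozygous calls (tie: the lexicographically smaller allele).
#' Homozygous major is 1, homozygous minor 0, heterozygous calls are masked.
#' Masked entries are imputed with the column mean of unmasked entries
#' (default) or the marker is dropped (`masked = "drop"`).
#'
#' @param calls individuals x markers character matrix of calls ("AA",
#'   "AG", ...).
#' @param masked "impute" (default) or "drop".
#' @return numeric matrix ready for [pca()], with attribute `masked`
#'   (logical matrix of masked positions, impute mode only).
#' @export
encode_genotypes <- function(calls, masked = c("impute", "drop")) {
  masked <- match.arg(masked)
  stopifnot(is.matrix(calls))
  enc <- matrix(NA_real_, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  msk <- matrix(FALSE, nrow(calls), ncol(calls))
  for (j in seq_len(ncol(calls))) {
    a1 <- substr(calls[, j], 1, 1)
    a2 <- substr(calls[, j], 2, 2)
    het <- a1 != a2
    hom <- !het
    alleles <- sort(unique(c(a1, a2)))
    if (length(alleles) > 2)
      stop("more than two alleles at marker ",
           if (!is.null(colnames(calls))) colnames(calls)[j] else j)
    cnt <- table(factor(a1[hom], levels = alleles))
    major <- if (length(alleles) == 1) alleles else
      names(cnt)[order(-cnt, names(cnt))][1]
    enc[hom, j] <- as.numeric(a1[hom] == major)
    msk[het, j] <- TRUE
  }
  if (masked == "drop") {
    keep <- colSums(msk) == 0
    out <- enc[, keep, drop = FALSE]
  } else {
    for (j in seq_len(ncol(enc))) {
      if (any(msk[, j])) {
        mu <- mean(enc[!msk[, j], j])
        if (is.nan(mu)) mu <- 0.5
        enc[msk[, j], j] <- mu
      }
    }
    out <- enc
    attr(out, "masked") <- msk
  }
  out
}

#' Principal component analysis (2 components)
#'
#' Column-mean centering followed by SVD. Sign convention: within each
#' component the loading of largest magnitude is made positive, so score
#' plots are reproducible run to run. Explained variance ratios are the
#' squared singular values over their total.
#'
#' @param x numeric matrix (>= 2 rows, >= 2 columns, complete).
#' @param n_components number of components (default 2).
#' @return list(scores, loadings, explained_variance_ratio).
#' @export
pca <- function(x, n_components = 2L) {
  stopifnot(is.matrix(x), nrow(x) >= 2, ncol(x) >= 2, !anyNA(x))
  if (n_components > min(dim(x)))
    stop("n_components (", n_components, ") exceeds min(dim(x))")
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)
  total <- sum(sv$d^2)
  evr <- if (total > 0) sv$d[seq_len(n_components)]^2 / total else
    rep(0, n_components)
  scores <- sv$u[, seq_len(n_components), drop = FALSE] %*%
    diag(sv$d[seq_len(n_components)], n_components)
  loadings <- sv$v[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(n_components)) {
    i <- which.max(abs(loadings[, k]))
    if (loadings[i, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  rownames(scores) <- rownames(x)
  rownames(loadings) <- colnames(x)
  colnames(scores) <- colnames(loadings) <-
    paste0("PC", seq_len(n_components))
  list(scores = scores, loadings = loadings,
       explained_variance_ratio = evr)
}

#' Mean silhouette of a two-group labelling in score space
#'
#' Euclidean-distance silhouette coefficient averaged over individuals:
#' near +1 means the two labelled groups are well separated in the score
#' plane, near 0 means intermixed.
#'
#' @param scores individuals x 2 numeric matrix (PCA scores).
#' @param labels group label per row (exactly two labels, each >= 2 rows).
#' @return mean silhouette value in [-1, 1].
#' @export
separation_score <- function(scores, labels) {
  stopifnot(nrow(scores) == length(labels))
  lv <- unique(labels)
  if (length(lv) != 2) stop("exactly two labels required")
  if (any(table(labels) < 2)) stop("each label needs >= 2 members")
  d <- as.matrix(stats::dist(scores))
  n <- nrow(scores)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- mean(d[i, !own])
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Contrast repeat-based and SNP-based population structure
#'
#' Runs the same 2-component PCA machinery on (i) the min/max-scaled repeat
#' abundance matrix and (ii) the encoded SNP genotype matrix, and reports
#' the silhouette separation of the two populations in each score plane.
#' With SNP allele-frequency divergence but no repeat-abundance divergence,
#' the SNP silhouette is high while the repeat silhouette stays near zero —
#' the two data types are uncoupled.
#'
#' @param abundance individuals x clusters matrix.
#' @param genotype_calls individuals x markers allele-pair call matrix (or
#'   an already-encoded numeric matrix).
#' @param populations population label per individual.
#' @param masked masked-genotype handling, see [encode_genotypes()].
#' @return list(repeat_pca, snp_pca, repeat_silhouette, snp_silhouette).
#' @export
structure_contrast <- function(abundance, genotype_calls, populations,
                               masked = "impute") {
  if (!identical(rownames(abundance), rownames(genotype_calls)))
    stop("individual sets differ between matrices: ",
         paste(head(c(setdiff(rownames(abundance), rownames(genotype_calls)),
                      setdiff(rownames(genotype_calls), rownames(abundance)))),
               collapse = ", "))
  stopifnot(length(populations) == nrow(abundance))
  geno <- if (is.character(genotype_calls))
    encode_genotypes(genotype_calls, masked) else genotype_calls
  rp <- pca(minmax_scale_matrix(abundance))
  sp <- pca(geno)
  list(repeat_pca = rp, snp_pca = sp,
       repeat_silhouette = separation_score(rp$scores, populations),
       snp_silhouette = separation_score(sp$scores, populations))
}
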