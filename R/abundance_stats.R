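#' Two-sample t-test
#'
#' Pooled-variance (Student) two-sample t by default, with two-sided p from
#' the t distribution on `n_a + n_b - 2` degrees of freedom; Welch
#' available behind `var_equal = FALSE`. Degenerate zero-variance input
#' with equal means returns t = 0, p = 1; with unequal means it errors.
#'
#' @param a,b numeric vectors (each length >= 2, finite).
#' @param var_equal pooled variance (TRUE, default) or Welch.
#' @return list(t, p, df).
#' @export
two_sample_ttest <- function(a, b, var_equal = TRUE) {
  stopifnot(length(a) >= 2, length(b) >= 2, all(is.finite(a)), all(is.finite(b)))
  na <- length(a); nb <- length(b)
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    if (sp2 == 0) {
      if (ma == mb) return(list(t = 0, p = 1, df = na + nb - 2))
      stop("zero pooled variance with unequal means: t undefined")
    }
    t <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se2 <- va / na + vb / nb
    if (se2 == 0) {
      if (ma == mb) return(list(t = 0, p = 1, df = na + nb - 2))
      stop("zero variance with unequal means: t undefined")
    }
    t <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up procedure: `q_(i) = min_{j >= i} ( m p_(j) / j )`, capped at 1,
#' computed directly from the definition with stable ranking.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p))
    stop("p-values must be in [0, 1]")
  m <- length(p)
  if (!m) return(numeric(0))
  ord <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[ord] * m / seq_len(m)))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Differential abundance between two populations
#'
#' Column-wise two-sided t-tests on an abundance matrix (clusters or
#' annotation classes), BH correction across all columns as one family,
#' significance flagged at `q < alpha`. Counts are tested raw by default;
#' `normalize = TRUE` divides each row by its total first (all individuals
#' contribute the same number of reads in the skim design, so the default
#' is off).
#'
#' @param abundance individuals x units numeric matrix.
#' @param populations population label per row (exactly two labels, each
#'   with >= 2 rows); defaults to the matrix's `populations` attribute.
#' @param alpha FDR threshold (default 0.05).
#' @param var_equal pooled-variance t (default) or Welch.
#' @param normalize divide rows by their totals before testing.
#' @return data.frame (unit, mean_1, mean_2, sd_1, sd_2, t, p, q,
#'   significant) with attribute `pop_levels`.
#' @export
differential_abundance <- function(abundance, populations = NULL, alpha = 0.05,
                                   var_equal = TRUE, normalize = FALSE) {
  if (is.null(populations)) populations <- attr(abundance, "populations")
  stopifnot(!is.null(populations), length(populations) == nrow(abundance))
  lv <- sort(unique(populations))
  if (length(lv) != 2) stop("exactly two population labels required, got ",
                            length(lv))
  if (any(table(populations) < 2)) stop("each population needs >= 2 rows")
  x <- abundance
  if (normalize) x <- x / rowSums(x)
  ia <- populations == lv[1]; ib <- populations == lv[2]
  res <- lapply(colnames(x), function(u) {
    a <- x[ia, u]; b <- x[ib, u]
    tt <- two_sample_ttest(a, b, var_equal = var_equal)
    data.frame(unit = u, mean_1 = mean(a), mean_2 = mean(b),
               sd_1 = stats::sd(a), sd_2 = stats::sd(b),
               t = tt$t, p = tt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < alpha
  attr(out, "pop_levels") <- lv
  out
}
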