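#' Absolute Spearman correlation over complete pairs
#'
#' Computes |Spearman rho| between two vectors using only the indices where
#' both are observed, with average (mid-) ranks for ties: rho is the Pearson
#' correlation of the midranks, so tie corrections are implicit. The value
#' is undefined (`NA`) when fewer than `min_pairs` complete pairs remain or
#' when either side is constant over the complete pairs.
#'
#' @param x,y Numeric vectors of equal length; `NA` marks missing.
#' @param min_pairs Minimum complete pairs required (default 3).
#' @return A one-row tibble with `abs_rho` and `n_pairs`.
#' @export
#' @examples
#' spearman_abs(c(1, 2, 3, 4), c(1, 3, 2, 4))
spearman_abs <- function(x, y, min_pairs = 3L) {
  if (length(x) != length(y))
    abort_stage("spearman", "vectors differ in length")
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  rho <- NA_real_
  if (n >= min_pairs) {
    xr <- rank(x[ok])
    yr <- rank(y[ok])
    if (stats::sd(xr) > 0 && stats::sd(yr) > 0)
      rho <- abs(stats::cor(xr, yr))
  }
  tibble::tibble(abs_rho = rho, n_pairs = as.integer(n))
}

#' Pearson chi-square test from a contingency table
#'
#' Plain Pearson chi-square without continuity correction, with
#' `df = (r - 1)(c - 1)` and the p-value from the upper chi-square tail.
#'
#' @param counts Non-negative integer matrix (r x c) of counts.
#' @return A one-row tibble with `statistic`, `df` and `p_value`.
#' @export
#' @examples
#' # female/male by clinical group
#' chisq_from_table(rbind(c(111, 126, 43), c(100, 102, 45)))
chisq_from_table <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || sum(counts) <= 0)
    abort_stage("chisq", "counts must be non-negative with positive total")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    abort_stage("chisq", "zero row or column margin")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble::tibble(statistic = unname(ht$statistic),
                 df = as.integer(unname(ht$parameter)),
                 p_value = unname(ht$p.value))
}

#' One-way ANOVA reconstructed from group summaries
#'
#' Rebuilds the one-way ANOVA F test from per-group means, sample standard
#' deviations and sizes: the between-group sum of squares is
#' \eqn{\sum n_i (m_i - \bar m)^2} and the within-group sum of squares is
#' \eqn{\sum (n_i - 1) s_i^2}. Equivalent to a full one-way ANOVA on the raw
#' data whose summaries these are.
#'
#' @param summary A data frame with columns `mean`, `sd` and `n` (one row
#'   per group, at least two groups, each `n >= 2`).
#' @return A one-row tibble with `statistic`, `df1`, `df2` and `p_value`.
#'   When the within-group variance is zero but means differ, the F
#'   statistic is `Inf` and the p-value 0.
#' @export
#' @examples
#' anova_from_summary(data.frame(mean = c(69.72, 71.67, 72.11),
#'                               sd = c(7.61, 6.53, 6.39),
#'                               n = c(211, 228, 88)))
anova_from_summary <- function(summary) {
  stopifnot(all(c("mean", "sd", "n") %in% names(summary)))
  m <- summary$mean; s <- summary$sd; n <- summary$n
  k <- length(m)
  if (k < 2 || any(n < 2))
    abort_stage("anova", "need >= 2 groups with n >= 2 each")
  N <- sum(n)
  gm <- sum(n * m) / N
  ssb <- sum(n * (m - gm)^2)
  ssw <- sum((n - 1) * s^2)
  df1 <- k - 1L; df2 <- N - k
  if (ssw <= 0) {
    if (ssb > 0)
      return(tibble::tibble(statistic = Inf, df1 = df1, df2 = as.integer(df2),
                            p_value = 0))
    return(tibble::tibble(statistic = 0, df1 = df1, df2 = as.integer(df2),
                          p_value = 1))
  }
  f <- (ssb / df1) / (ssw / df2)
  tibble::tibble(statistic = f, df1 = as.integer(df1), df2 = as.integer(df2),
                 p_value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Scree eigenvalues of the pairwise-complete correlation matrix
#'
#' Computes the Pearson correlation matrix of the marker columns over
#' pairwise-complete observations, takes its eigenvalues, clips any
#' negatives at zero (pairwise-complete correlation matrices need not be
#' positive semi-definite; only the decay shape matters for the elbow) and
#' returns them in descending order.
#'
#' @param data A data frame or numeric matrix of subjects x markers.
#' @param markers Marker columns to use when `data` is a data frame.
#' @param quiet Suppress the warning emitted when negative eigenvalues are
#'   clipped.
#' @return Numeric vector of eigenvalues, descending.
#' @export
pca_scree <- function(data, markers = NULL, quiet = FALSE) {
  x <- if (is.matrix(data)) data else {
    markers <- markers %||% panel_markers(data)
    as.matrix(data[, markers, drop = FALSE])
  }
  if (ncol(x) < 2) abort_stage("pca_scree", "need at least 2 markers")
  allmiss <- colSums(!is.na(x)) == 0
  if (any(allmiss))
    abort_stage("pca_scree", paste0("all-missing marker(s): ",
                                    paste(colnames(x)[allmiss], collapse = ", ")))
  cm <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  cm[is.na(cm)] <- 0
  diag(cm) <- 1
  ev <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8) && !quiet)
    warning("pairwise-complete correlation matrix is not PSD; negative eigenvalues clipped at 0",
            call. = FALSE)
  sort(pmax(ev, 0), decreasing = TRUE)
}

#' Rescale a vector to the unit interval
#'
#' `(v - min) / (max - min)`: the minimum maps to 0 and the maximum to 1.
#'
#' @param v Numeric vector of length >= 2, not all equal.
#' @return Rescaled vector in `[0, 1]`.
#' @export
minmax_rescale <- function(v) {
  if (length(v) < 2) abort_stage("rescale", "need at least 2 values")
  r <- range(v, na.rm = TRUE)
  if (r[2] - r[1] <= 0) abort_stage("rescale", "constant vector")
  (v - r[1]) / (r[2] - r[1])
}
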