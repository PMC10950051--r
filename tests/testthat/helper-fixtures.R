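# fixtures and independent oracles built in code

# small panel tibble with a handful of registry markers and label columns
toy_panel <- function(n = 30, markers = c("pt217", "pt111", "nfl_csf",
                                          "ykl40_csf", "mmse"),
                      seed = 1) {
  set.seed(seed)
  out <- tibble::tibble(
    subject_id = sprintf("T%03d", seq_len(n)),
    cdr_group = sample(c("CDR0", "CDRgt0"), n, replace = TRUE),
    centiloid = runif(n, -5, 100))
  out$amyloid_positive <- out$centiloid >= 16.4
  out$cdr_group[!out$amyloid_positive] <- "CDR0" # impaired must be A+
  for (m in markers) out[[m]] <- abs(rnorm(n)) + 0.5
  out
}

# brute-force pairwise-complete |spearman| matrix, no shared mask logic
oracle_similarity <- function(x) {
  p <- ncol(x)
  s <- diag(1, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      ok <- stats::complete.cases(x[, i], x[, j])
      s[i, j] <- s[j, i] <-
        abs(stats::cor(x[ok, i], x[ok, j], method = "spearman"))
    }
  }
  dimnames(s) <- list(colnames(x), colnames(x))
  s
}

# two-class fixture where one feature separates the classes perfectly and
# the rest are noise
separable_fixture <- function(n = 100, p_noise = 3, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("a", "b"), length.out = n))
  d <- tibble::tibble(y = y,
                      x1 = ifelse(y == "a", runif(n, 0, 1), runif(n, 2, 3)))
  for (j in seq_len(p_noise)) d[[paste0("noise", j)]] <- rnorm(n)
  d
}

forest_markers <- function(data) setdiff(names(data), "y")
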