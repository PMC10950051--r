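#' Published cohort demographic summary
#'
#' Reads the shipped (or a user-supplied) JSON file of per-group demographic
#' summaries for the three clinical groups: cognitively normal
#' amyloid-negative CN(A-), cognitively normal amyloid-positive CN(A+)
#' (preclinical Alzheimer's disease) and cognitively impaired CI. Continuous
#' variables carry group means and sample SDs; categorical variables carry
#' per-group counts.
#'
#' @param path Path to the JSON summary; default the shipped resource.
#' @return A list with `groups`, `n`, `continuous`, `categorical`.
#' @export
table1_summary <- function(path = system.file("extdata", "table1_summary.json",
                                              package = "admarkers")) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Recompute the demographic group comparisons
#'
#' Continuous variables are compared across the three groups with a one-way
#' ANOVA reconstructed from the published means, SDs and group sizes;
#' categorical variables with a Pearson chi-square (no continuity
#' correction) on the published counts.
#'
#' @param summary A summary list as returned by [table1_summary()].
#' @return A tibble with one row per variable: `variable`, `test`,
#'   `statistic`, `p_value`.
#' @export
#' @examples
#' demographic_tests(table1_summary())
demographic_tests <- function(summary = table1_summary()) {
  rows <- list()
  for (v in names(summary$continuous)) {
    s <- summary$continuous[[v]]
    a <- anova_from_summary(data.frame(mean = s$mean, sd = s$sd,
                                       n = summary$n))
    rows[[length(rows) + 1]] <- tibble::tibble(
      variable = v, test = "anova", statistic = a$statistic,
      p_value = a$p_value)
  }
  for (v in names(summary$categorical)) {
    cnt <- summary$categorical[[v]]$count
    tab <- rbind(cnt, summary$n - cnt)
    ch <- chisq_from_table(tab)
    rows[[length(rows) + 1]] <- tibble::tibble(
      variable = v, test = "chisq", statistic = ch$statistic,
      p_value = ch$p_value)
  }
  dplyr::bind_rows(rows)
}
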